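library	total_reads	mapped_reads	uniquely_mapped_reads
Hd-rR_blastulae	8841684	6461567	5486904
Hd-rR_testes	12007331	7422679	6682875
Hd-rR_liver	8284838	6206848	5766607
HNI_blastulae	11404141	10629048	8385917
HNI_testes	10419993	9442123	8585879
HNI_liver	10856232	9844800	9051809
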