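library	collected_reads	uniquely_mapped_reads
Hd-rR_blastulae	339407788	220270276
Hd-rR_testes	389257067	245192521
Hd-rR_liver	342386421	233904210
HNI_blastulae	391519667	291165889
HNI_testes	587561947	336898284
HNI_liver	467963072	343765549
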