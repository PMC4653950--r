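Package: nucleocyclic
Title: Nucleosome Phasing, Sequence Asymmetry and Mutational Flux Around
    Transcription Start Sites
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies promoters with strongly phased downstream nucleosome
    arrays ("nucleocyclic" transcription start sites) from 5'-end tag and
    MNase nucleosome-core read data, and characterises their sequence and
    evolutionary properties. Calls TSS clusters and representative TSSs from
    normalized 5'-tag counts, builds smoothed nucleosome dyad-score tracks,
    estimates the mean core fragment length from strand-specific A/T
    composition, selects stable dyads and first downstream dyads, quantifies
    nucleosome periodicity and consistency by autocorrelation, measures
    upstream/downstream base-composition asymmetry with a two-sample z-test,
    infers ancestral bases by outgroup parsimony and computes per-position
    mutational-flux profiles around TSSs and dyads, together with the rank
    correlation and rank-sum comparisons tying phasing to expression. A
    seeded synthetic-data generator produces genomes, tag libraries,
    nucleosome reads and substitution histories with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
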