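Package: zygosex
Title: Zygosity-Based Sex Determination: Simulation and Diversity Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying single-locus zygosity-based sex determination
    of the kind found in Bicyclus anynana (BaMasc) and honeybee csd:
    hemizygotes and heterozygotes are viable (female and male respectively)
    while homozygotes die, generating intense negative frequency-dependent
    balancing selection. Provides a forward population simulator with
    homozygote lethality and hypervariable-region (HVR) mutation; codon-aware
    Nei-Gojobori synonymous/nonsynonymous sliding-window diversity with
    triplet-indel statistics; codon-usage and HVR-length profiling; AMOVA
    Phi-ST; Chao1/iChao1 allele-richness extrapolation with the
    effective-wild-sample correction; a resampling null for heterozygote
    compatibility; Mendelian segregation, Hardy-Weinberg homozygote-deficit,
    Fisher-exact sex-linkage and knockdown contingency tests; and
    Z:autosome dosage-compensation ratio analysis with cutoff sweeps.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
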