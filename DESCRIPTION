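Package: synmut
Title: Where Synonymous Substitutions Accumulate in Experimentally Evolved Genomes
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for asking whether per-gene synonymous
    nucleotide diversity in natural bacterial isolates (theta_s) predicts
    where synonymous substitutions accumulate during laboratory evolution.
    Provides a codon-level engine for synonymous/nonsynonymous/nonsense
    classification and Nei-Gojobori synonymous-site counting; a
    Watterson-style estimator of per-gene synonymous diversity from codon
    alignments; codon- and strand-aware annotation of point mutations on an
    ancestral genome with core-genome filtering; gene-length and
    theta_s-proportional multinomial rate models compared to observed
    cumulative substitution distributions by Kolmogorov-Smirnov tests
    (asymptotic and Monte-Carlo); mutation-spectrum summaries for
    hypermutator lineages; association statistics (Welch's t, Wilcoxon
    rank-sum, Pearson r, Kendall's partial rank-correlation controlling for
    gene length); and a ground-truth-labeled synthetic-data generator so the
    whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
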