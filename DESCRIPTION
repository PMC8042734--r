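Package: teinvasion
Title: Detecting and Dating Transposable Element Invasions from Strain
    Resequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Profiles transposable-element (TE) abundance and internal
    diversity from short reads aligned to family consensus sequences,
    classifies strains as lacking a TE family, carrying only degraded
    copies, or carrying canonical copies, and dates TE invasions from
    strains sampled in known years.  Compares TE composition across
    strains through allele-frequency PCA, pairwise FST and
    neighbor-joining trees, and quantifies piRNA-based silencing
    evidence: miRNA-normalized piRNA abundance, sense/antisense position
    profiles, the ping-pong signature, and divergence-gated targeting.
    Ships a synthetic-data generator producing TE landscapes, short
    reads and small-RNA libraries with known ground truth, plus an
    internal micro-aligner, so the whole pipeline runs end to end
    without external tools.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
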