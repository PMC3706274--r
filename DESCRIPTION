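Package: repcons
Title: Replicate-Pair Consensus Differential Expression and
    Transcription-Factor Profiling
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Consensus calling of differentially expressed transcripts from
    FPKM expression tables by exhausting all control-replicate versus
    experiment-replicate pairwise comparisons and selecting features whose
    direction of change is consistent in at least n of the comparisons.
    Builds top-K transcription-factor profiles from documented TF-target
    regulation tables, normalizes them to unit length, compares them to
    reference profiles by Euclidean distance, intersects profiles across
    conditions to find conserved regulators, summarizes consensus gene sets
    by GO slim term, and computes percent- and fold-change arithmetic over
    strain physiology tables. Includes a seeded synthetic-data generator
    (lognormal replicate noise, planted differential genes, planted
    conserved regulators) so the whole pipeline is testable end to end
    without sequencing data, and readers for Cuffdiff-style .diff tables so
    real pairwise comparisons can be substituted for the built-in caller.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
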