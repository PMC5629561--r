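Package: splicemod
Title: Splicing-Centric Modulator Inference for Transcription Factor Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects whether the inclusion level (percent spliced in, PSI) of an
    alternatively spliced exon in a candidate modulator protein alters a
    transcription factor's regulatory effect on its target genes. For every
    (target, TF, splicing event) triplet an interaction-term linear model is
    fit on log-transformed expression and logit-like transformed PSI; the
    interaction coefficient is tested, Benjamini-Hochberg corrected across the
    scan, significant triplets are classified into Active/Repress/Inverts
    modes of action by comparing TF-target correlation between low- and
    high-PSI sample groups, and TF-modulator influence percentages are
    aggregated into thresholded bipartite networks, optionally restricted to
    pairs with protein-protein interaction support. Includes a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
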