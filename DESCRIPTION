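Package: repstruct
Title: Structural Profiling of Antibody Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts which antibody heavy and light variable-domain reads
    are structurally modellable by loop-template assignment, pairs them
    combinatorially into Fv regions with inherited VH-VL orientations,
    greedily clusters the predicted binding sites into distinct structures
    under orientation and length-weighted CDR RMSD gates, quantifies
    structures shared ('public') across individuals, and contrasts observed
    structural diversity against a random-repertoire null model. Includes
    sequence-based clonotyping as a comparator and a synthetic-data
    generator with planted geometric ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
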