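Package: ptmstruct
Title: Structural Characterisation of Post-Translational Modification Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to characterise the three-dimensional structural context of
    post-translational modification (PTM) sites such as O-GlcNAcylated
    serines/threonines. Builds modified and background site catalogs from
    sequence-level inputs, maps sites onto protein structures via residue-level
    tables or local alignment, annotates missing-residue (REM465) status,
    secondary structure, relative solvent accessibility and standardised
    B-factors, superimposes 7-residue site windows with the Kabsch algorithm
    and clusters them by complete-linkage RMSD against a bootstrap null, and
    computes positional sequence-entropy and intrinsic-disorder enrichment
    profiles versus background serine/threonine sets. A synthetic-data
    generator with planted ground truth makes the whole pipeline testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
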