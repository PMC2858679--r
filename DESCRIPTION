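Package: smotifr
Title: Supersecondary Structure Motif Decomposition and Fold Novelty Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes protein structures into strings of overlapping
    supersecondary structure motifs (Smotifs): pairs of consecutive helix or
    strand elements joined by a loop, characterized by four internal
    coordinates (distance D, hoist, packing and meridian angles) computed from
    the principal axes of the bracing elements. Provides geometry binning and
    classification schemes, construction of fold-non-redundant Smotif
    frequency libraries with randomized fold-representative selection,
    saturation curves over deposition time, length-normalized log-probability
    novelty scores and population Z-scores, strict flanking-element length
    comparison against reference sets, per-motif structural features (internal
    contacts, Shrake-Rupley solvent accessibility), and a synthetic-structure
    generator that places idealized helices and strands at prescribed internal
    coordinates for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
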