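Package: ovamat
Title: Ovarian Matrisome Mapping Toolkit: Raman Unmixing, AFM Roughness,
    Follicle Staging and Matrisome Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable implementations of the computational stages used to map
    extracellular-matrix (matrisome) dynamics in the developing ovary:
    hyperspectral Raman preprocessing (range truncation, cosmic-spike removal,
    SNIP baseline estimation, Savitzky-Golay smoothing, area normalization)
    and spectral unmixing by non-negative matrix factorization; atomic-force-
    microscopy surface-roughness (Sa) and Young's-modulus map summaries;
    rule-based follicle staging, immunofluorescence count arithmetic and the
    antral-diameter puberty score; and matrisome categorization with
    cross-species overlap, differential-expression filtering and nine-quadrant
    mRNA-protein concordance. A synthetic-data module generates every input
    with known ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    tiff
Config/testthat/edition: 3
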