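Package: mgpipe
Title: Microglomerular Activity and Connectivity Analysis for the Drosophila
    Mushroom Body Calyx
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for odour-evoked microglomerular (MG) activity
    in two-photon calcium-imaging movies of the Drosophila mushroom body
    calyx, together with a synthetic-data generator that makes every stage
    testable against known ground truth. Implements rigid translation-only
    motion correction, active-MG detection by minimum-image normalization,
    Otsu thresholding and size-gated connected components, per-ROI dF/F0
    trace extraction and peak statistics, normality-gated paired tests and
    two-sample Kolmogorov-Smirnov comparisons of peak distributions,
    volumetric z-slice ratio profiles with slope comparison by linear
    regression, and reciprocal-synapse analysis of hub-neuron (APL)
    connectivity from annotated synapse tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
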