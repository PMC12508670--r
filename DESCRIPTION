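Package: gonadotrace
Title: Calcium-Imaging Analysis of Pituitary Gonadotroph Signaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for analysing perifusion calcium-imaging recordings
    of anterior-pituitary gonadotrophs: dF/F normalization (F/Fmin) with
    photobleaching detrending, high-potassium viability gating, calcium-transient
    detection, classification of GnRH-evoked response patterns (oscillatory,
    biphasic, transitory, long-lasting), cross-correlation population synchrony,
    per-animal aggregation with nonparametric group statistics (Kruskal-Wallis,
    Dunn's post hoc with Holm adjustment, Wilcoxon signed-rank), and comparative
    2^-DDCt qPCR quantification. Includes a calibrated synthetic-recording
    generator with per-cell ground truth so every stage of the pipeline is
    testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
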