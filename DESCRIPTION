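Package: lfqa
Title: Log File Based Patient QA for Pencil Beam Scanning Proton Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for patient-specific quality assurance of pencil beam
    scanning (PBS) proton therapy from treatment delivery log files. Provides
    a synthetic delivery simulator with a configurable machine error model,
    readers and writers for per-fraction record and events log dialects
    (strip-chamber Gaussian centroid fitting, intercept-theorem projection to
    the isocenter plane, charge-to-MU conversion with air density correction),
    per-spot accuracy and reproducibility statistics across fractions, an
    analytic pencil-beam dose engine for log-file dose reconstruction in a
    water phantom, 3D global gamma index analysis with low-dose cutoff and
    sub-voxel interpolation, the MU-weighted spot-based pass rate Lambda(D)
    and its correlation with gamma pass rates, and delivery timing
    decomposition with interlock excision.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
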