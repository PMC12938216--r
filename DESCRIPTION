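Package: spiralflow
Title: Golden-Angle Spiral Real-Time Phase-Contrast MRI Simulation,
    Reconstruction and Flow Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for free-breathing real-time phase-contrast
    cardiovascular MRI with a dual-density golden-angle spiral readout, aimed at
    mid-field (0.55T) systems with moderate gradient performance. Designs
    slew-rate-limited dual-density spiral-out trajectories, schedules
    flow-compensated/flow-encoded golden-angle frames, simulates undersampled
    multi-coil acquisitions of a pulsatile two-vessel digital flow phantom,
    reconstructs the dynamic image series by SENSE-based compressed sensing with
    non-decimated spatiotemporal wavelet regularization (NUFFT forward model,
    ESPIRiT coil maps, Pipe-Menon density compensation), converts phase
    differences to velocity maps with concomitant-field (Maxwell) correction and
    temporal phase unwrapping, and quantifies beat-to-beat hemodynamics (net
    flow, peak flow rate, peak velocity, Qp/Qs, coefficient of variation)
    together with method-agreement statistics (Bland-Altman, ICC, MAE, paired
    t-test) and a no-reference blur metric.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    arrow,
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
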