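Package: mefc
Title: Multiband Multi-Echo Resting-State Functional Connectivity and
    Connectivity Density Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multiband (MB) and multiband multi-echo (MBME)
    resting-state BOLD fMRI: voxelwise T2*/S0 estimation by log-linear fit and
    T2*-weighted echo combination; a standard denoising chain (initial-volume
    discard, Legendre detrending, nuisance regression with degrees-of-freedom
    accounting, ideal bandpass filtering, mask-renormalised Gaussian smoothing);
    seed-based correlation maps and whole grey-matter ROI correlation matrices;
    local and global functional connectivity density (lFCD/gFCD) mapping; test-
    retest reproducibility metrics (Dice coefficient and voxelwise REP); and a
    group layer with covariate-adjusted paired tests, Benjamini-Hochberg FDR,
    and Monte-Carlo cluster-extent thresholding. A seeded multi-echo BOLD
    phantom generator emulates a two-session MB/MBME study design so every
    stage is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
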