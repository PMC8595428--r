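Package: dyadfmri
Title: Dual-Subject fMRI Hyperscanning: Simulation, Quality Control, and
    Inter-Brain Synchrony
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for simultaneously acquired ("hyperscanning")
    fMRI of two subjects sharing one scanner bore. Provides NIfTI volume
    handling with dual-field-of-view splitting and reorientation to a common
    radiological convention; a synthetic paired-BOLD generator with known
    inter-brain coupling, block-design task responses, polynomial drift,
    AR(1) noise, motion traces, and multi-channel receiver-noise samples;
    per-subject preprocessing (polynomial detrending, temporal band-pass,
    mask-renormalized Gaussian smoothing, voxel-wise normalization, nuisance
    regression, run concatenation); quality-control metrics (temporal SNR
    maps and summaries, coil noise-correlation matrices, motion summaries);
    the inter-brain voxel-wise synchrony statistic with variance-stabilized
    Fisher-Z transform and thresholding; and block-design GLM analysis with
    hemodynamic-response convolution, paired stimulus-versus-baseline and
    unpaired between-paradigm contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    MASS,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
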