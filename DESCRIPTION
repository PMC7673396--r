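Package: boldlag
Title: Time-Lag Mapping of BOLD fMRI Signals Against Global, Network,
    Task and Arterial References
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Voxelwise time-lag and magnitude mapping of BOLD fMRI
    time series by cross-correlation against a reference signal (global
    mean signal, temporal independent components, task-evoked responses,
    or an arterial inflow signal) on a sub-TR upsampled grid. Includes
    temporal preprocessing (linear detrending, zero-phase band-pass),
    two-stage temporal ICA with Icasso-style reproducibility clustering,
    block-design GLM activation mapping, extracranial artery ROI
    analysis, lag-map comparison and composite-map statistics, and a
    synthetic 4D BOLD generator with known ground-truth delay fields for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: FunctionalGenomics, Software
RoxygenNote: 7.3.3
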