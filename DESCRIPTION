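Package: rventropy
Title: Time-Resolved Rank Vector Entropy Mapping for MEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes rank vector entropy (RVE), a time-resolved,
    amplitude-invariant symbolic-dynamics entropy for sampled
    electrophysiological signals, and maps it over a source grid using a
    scalar linearly constrained minimum-variance (LCMV) beamformer with a
    homogeneous conducting-sphere head model.  Includes band-limited
    Hilbert-envelope power for comparison, event-locked averaging and
    baseline t-statistics, segment-integrated condition contrasts, and a
    synthetic MEG generator (dipole sources, helmet sensor arrays,
    Gaussian sensor noise, event markers) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
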