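Package: fnirsdot
Title: Diffuse Optical Tomography Analysis of Task-Related fNIRS Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-subject analysis of continuous-wave functional
    near-infrared spectroscopy (fNIRS) recordings by diffuse optical
    tomography (DOT). Builds layered voxel head models, co-registers
    optode arrays by three-point rigid fiducial alignment, solves the
    continuous-wave photon diffusion equation by finite differences to
    obtain channel-by-voxel sensitivity (Jacobian) matrices, converts
    dual-wavelength DC light intensities to optical density, performs
    motion correction and zero-lag band-pass filtering, reconstructs
    voxel absorption changes by Tikhonov-regularized minimum-norm
    inversion, unmixes oxy- and deoxyhemoglobin via the modified
    Beer-Lambert law, and maps task-related activation with either a
    general linear model (canonical hemodynamic response regressor) for
    block designs or a windowed signal-variability statistic for
    unstructured tasks, thresholded at t = +/-1.65. A seeded synthetic
    recording generator with known ground-truth activations makes every
    stage testable without patient data.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    signal,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests: testthat (>= 3.0.0), yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
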