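Package: cryoEP
Title: Temperature-Dependent Simulation of Ventricular Myocardium and the Pseudo-ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiscale simulator of hypothermic (27-37 degrees Celsius)
    ventricular electrophysiology. Extends the four-variable minimal
    ventricular action potential model with Q10 temperature scaling of
    ion-channel time constants for epicardial, midmyocardial and
    endocardial cells, solves the anisotropic monodomain equation on 1D
    strands, 2D transmural slices and 3D wedge geometries with helical
    fiber rotation and temperature-scaled gap-junction diffusion, computes
    transmural pseudo-ECGs via a lead-field dipole sum, and extracts
    action-potential and ECG features (APD90, Vmax, notch morphology, QT,
    QRS, J-wave amplitude, dispersion of repolarization, Tpeak-Tend).
    Includes conduction-velocity calibration protocols and Q10 estimation
    from temperature series of feature values by nonlinear least squares.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
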