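Package: festorque
Title: Evoked-EMG Based Estimation of Electrically Stimulated Joint Torque
Version: 0.1.0
Authors@R:
    person("festorque", "developers", email = "festorque@example.org",
           role = c("aut", "cre"))
Description: Offline-replayable implementation of a real-time functional
    electrical stimulation (FES) joint-torque estimation pipeline driven by
    evoked electromyography (eEMG). Provides stimulation-artifact blanking and
    residual-spike removal, per-stimulation-loop feature extraction (mean
    absolute value of the M-wave, mean torque), trapezoidal pulse-width
    stimulation protocols, a synthetic FES-session simulator with known ground
    truth, two online torque estimators (a forgetting-factor Kalman filter on
    a polynomial Hammerstein model, and a NARX model identified by
    pseudoinverse least squares with frozen-parameter free-run prediction),
    prediction-quality metrics (RMSE, NRMSE, VAF), and a session pipeline with
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
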