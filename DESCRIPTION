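Package: avdu
Title: Angular Velocity Detector Units for Insect Visual Motion
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates angular-velocity (AV) estimation in the bee visual
    system. Arrays of Reichardt-Hassenstein correlation detectors are built
    from rate-coded leaky-integrator neural units behind an adapting
    photoreceptor front end; a fast and a slow correlator subunit are summed
    across a retinotopic array and combined by a floored ratio to give a
    spatial-frequency- and contrast-invariant AV estimate. The package
    provides moving grating stimuli, a minimal patterned-corridor world
    sampled by a 32x32 ommatidial grid, a closed-loop corridor-centering
    flight controller, a visual-odometry metric, and protocols for response
    sweeps, rectification and delay-pair comparisons, and
    linear/logarithmic/exponential curve fitting with adjusted R-squared.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
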