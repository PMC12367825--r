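Package: avsim
Title: Virtual-Patient Simulation of Accelerometer-Based Atrial Sensing in
    Leadless Pacemakers
Version: 0.1.0
Authors@R:
    person("avsim", "maintainers", email = "avsim@example.org", role = c("aut", "cre"))
Description: A desk-scale virtual-patient bench for atrioventricular-synchrony
    (AVS) algorithms of accelerometer-sensing leadless pacemakers. Synthesizes
    rectified intracardiac accelerometer traces from Ricker-wavelet components
    (A1-A4, with binary A7 summation when A3 and A4 overlap), drives them with
    Monte Carlo virtual-patient scripts (amplitude distributions, hourly sinus
    profiles, ectopy), runs the device sensing/pacing state machine (PVAB, A3
    window, thresholds, VDD/VDI modes, upper tracking rate), implements two
    generations of automatic A3-threshold adaptation and the three-phase
    Atrial Sensing Setup, and scores atrioventricular synchrony with paired
    cohort statistics (McNemar) plus device-check survey arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
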