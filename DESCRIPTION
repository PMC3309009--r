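Package: armtf
Title: Single-Trial Time-Frequency Estimation of Multi-Joint Arm Stiffness and Damping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates time-varying joint stiffness and damping of a planar
    two-link arm from the free response to a single brief force perturbation.
    The free oscillation is analysed with a reassigned spectrogram, ridge
    extraction yields instantaneous resonant frequencies and amplitudes, and an
    instantaneous modal inverse problem reconstructs the 2x2 stiffness and
    damping matrices sample by sample, with no stationarity or trial-repetition
    assumption. Ships a two-link arm simulator with Kelvin-Voigt,
    Poynting-Thomson and Duffing viscoelastic force fields, time-varying gain
    profiles, impulse/pulse/servo perturbations and signal-dependent noise,
    together with three classical regressive baseline estimators (force-pulse
    full regression, servo-displacement full regression, steady-state
    displacement regression) and an experiment runner reporting percentage RMS
    errors against the imposed profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    signal,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
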