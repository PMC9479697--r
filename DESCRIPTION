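Package: psasim
Title: Personalized Speed Adaptation for Teleoperated Robots from EEG/EOG
    Mental-State Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, closed-loop simulator of personalized speed
    adaptation (PSA) for teleoperated robots. Multichannel EEG and EOG
    recordings are preprocessed (least-squares baseline removal, Butterworth
    band-pass filtering, downsampling, sliding-window sampling), reduced to
    mental-state features (wavelet rhythm bands, differential entropy, sample
    entropy, band power/energy, EOG low/high power ratio, mutual-information
    feature ranking), and fed to a tanh/softmax state-to-action policy
    network trained by REINFORCE with a reward baseline on two simulated
    teleoperation tasks (trajectory tracking and target positioning). A
    synthetic operator with latent arousal/valence/fatigue/stress dynamics
    stands in for human subjects, and a conventional warning-threshold
    controller provides the comparison arm for the three-session
    training/testing/control protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
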