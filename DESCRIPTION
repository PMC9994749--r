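Package: cimaloc
Title: Causal-Inference Observer Modeling of Audiovisual Spatial Localization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for audiovisual spatial localization
    experiments on a linear stimulus array, centered on the ventriloquist
    effect. Generates the three-task psychophysical design (auditory, visual,
    audiovisual localization on a 24-module array spanning +/- 36 degrees at
    180 cm of viewing distance), simulates Gaussian-noise observers and the
    reliability-weighted audiovisual fusion they imply, implements a
    causal-inference optimal observer with Monte-Carlo forward simulation and
    binned response distributions, fits Gaussian psychometric curves (peak,
    width, R-squared, fit-versus-constant F test), and evaluates model
    predictions against observers via range-normalized RMSE and Mann-Whitney
    tests with rank-biserial effect sizes. Also provides desk-scale
    implementations of the signal computations used by heatmap-based
    localization networks: two-microphone delay-and-sum beamforming with
    mel-cepstral compression, 2D Gaussian ground-truth heatmaps, soft-argmax
    decoding, Kullback-Leibler and squared-error map losses,
    intersection-over-union module assignment, and shift histograms.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
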