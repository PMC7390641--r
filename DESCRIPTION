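Package: tectodist
Title: Visual Detection Distance from Optic-Tectum Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline converting optic-tectum calcium-fluorescence
    recordings made during a moving-prey stimulus into a visual detection
    distance and three peak-shape response metrics (duration, full width at
    half maximum, inter-peak interval), together with the group-comparison
    statistics across temperature treatments (skewness screen, Levene's test,
    one-way ANOVA with Brown-Forsythe extension, Scheffe and Tamhane T2
    post-hocs, Kruskal-Wallis with Dunn's post-hoc). Models the stimulus
    kinematics on a miniature OLED screen and maps fluorescence-transient
    onsets back to eye-to-stimulus distances via the eye-screen right
    triangle. Ships a synthetic GCaMP-like trace and image-stack generator
    with known ground truth so the whole pipeline is testable end to end
    without any recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    e1071,
    car,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
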