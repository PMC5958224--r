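Package: fluorpheno
Title: Kinetic Chlorophyll Fluorescence and Multicolor Fluorescence Phenotyping
Version: 0.1.0
Authors@R:
    person("Maintainer", "Fluorpheno", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of pulse-amplitude-modulated (PAM)
    chlorophyll fluorescence quenching kinetics and UV-excited multicolor
    fluorescence imaging for rosette-plant drought phenotyping. Provides a
    timed quenching protocol (dark-adapted Fo/Fm, Kautsky induction under
    actinic light, saturating-flash series, dark relaxation), a forward
    simulator of per-pixel fluorescence image stacks with known physiological
    ground truth, background segmentation and kinetic trace extraction, the
    full quenching parameter catalogue (Fv/Fm, NPQ, Rfd, PhiPSII, qN, qP, qL
    at each flash stage; 89 chlorophyll plus 16 multicolor parameters),
    treatment-comparison statistics, a thresholded Pearson correlation
    network, Fisher-criterion sequential forward selection, and 10-fold
    cross-validated linear maximum-margin classification of control versus
    drought-stressed plants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
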