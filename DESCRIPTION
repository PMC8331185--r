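Package: ecdysim
Title: Muscle-Level Simulation and Analysis of Drosophila Pupal Ecdysis Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for describing behavior from single-muscle calcium imaging
    of the Drosophila pupal ecdysis sequence. Provides a ground-truthed
    synthetic recording generator (hemisegmental muscle map, phase/bout plans,
    a movement syllabary, GCaMP-like kinetics, rendered movies, and
    neuromodulator-suppression perturbations), fluorescence trace processing
    (dF/F, peak detection, rasters, peak-train correlation), bout segmentation
    and variability summaries, co-activation ensemble (PME) discovery,
    activation-order stereotypy scoring by gestalt sequence similarity with a
    shuffled-sequence permutation null, anterior-posterior wave directionality
    from intensity-projection modes, contraction mechanics, and a
    sliding-window frame-wise movement classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
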