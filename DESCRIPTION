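Package: bRGmap
Title: Correlative Live/Fixed Imaging and Fate Mapping of Basal Radial Glia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for semi-automated live/fixed correlative microscopy of
    cultured brain-tissue slices and for mapping division modes of basal
    radial glial (bRG) progenitors. Segments slice outlines from brightfield
    and tile-scan mosaics, pairs live and fixed slices by area and
    moment-invariant shape descriptors via optimal assignment, estimates
    flip-aware similarity transforms by iterative closest point refinement,
    and transfers live-imaging fields of view onto immunostained images.
    Classifies daughter-cell fates from SOX2/EOMES/NEUN marker calls,
    tabulates division modes, basal-process inheritance and HES1 assignment,
    and implements a multitype branching model of bRG output (recurrence,
    closed form, asymptotic ratio, stochastic simulation, perturbation and
    inversion). Includes deterministic fixtures of published cohort counts
    and synthetic generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
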