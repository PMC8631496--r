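Package: pnDisc
Title: Parallel-Networks Modelling of Nucleus Pulposus Cell Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-quantitative parallel-networks (PN) modelling of nucleus
    pulposus (NP) cell mRNA-expression activities (aggrecan, collagen types
    I and II, MMP3, ADAMTS4) under multifactorial glucose/pH/IL1b/TNF-a
    environments. Calibrates stimulus-to-cell-activity weighting factors
    from x-fold mRNA changes via the cellular-effort transform, fits
    monotone sigmoidal dose-response curves over physiological nutrient
    ranges, evaluates the PN equation for four pro-inflammatory cell
    states, runs an inflammation submodel (cytokine mRNA activity, protein
    synthesis/decay, immunopositivity percentages), and seeds and grows
    immunopositive cell clusters in a 3D agent-based model of a 1 mm^3 NP
    volume with replicate summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
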