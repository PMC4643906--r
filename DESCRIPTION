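Package: inhibkin
Title: Enzyme Inhibition Kinetics with Dixon Median-Intersection Ki Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of steady-state enzyme-inhibition assays of the kind
    used to characterise fatty acid amide hydrolase (FAAH) inhibitors in
    radiolabelled-substrate hydrolysis experiments. Provides closed-form
    Michaelis-Menten, linear mixed-inhibition and competitive-inhibition
    velocity models; four-parameter logistic concentration-response fitting
    with Akaike-based model selection; global nonlinear least-squares
    estimation of Ki and the cooperativity factor alpha; Dixon-plot
    construction with robust line fits, pairwise-intersection enumeration
    and a median-intersection Ki estimator; multiple-inhibitor
    mutual-exclusivity analysis (parallel lines versus converging
    Yonetani-Theorell families); a serum-albumin ligand-depletion model
    explaining apparent Hill slopes greater than one; and a deterministic
    synthetic-assay generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    minpack.lm,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
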