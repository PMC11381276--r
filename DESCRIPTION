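Package: degpk
Title: Preclinical Pharmacokinetics and PBPK Prediction for Deg-AZM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the preclinical pharmacokinetic
    characterization of deglycosylated azithromycin (Deg-AZM), a
    small-molecule transgelin agonist in clinical development for slow
    transit constipation. Provides non-compartmental analysis of
    concentration-time profiles (AUC, lambda-z, half-life, clearance,
    bioavailability, dose proportionality, accumulation), equilibrium
    dialysis plasma-protein binding summaries, microsomal stability with
    in vitro-in vivo extrapolation through the well-stirred liver model,
    excretion mass balance, tissue-to-plasma exposure ratios, and a
    minimal whole-body physiologically based pharmacokinetic (PBPK)
    simulator using Rodgers-Rowland tissue partition coefficients, with
    seeded synthetic-data generators for every assay the pipeline
    consumes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
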