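Package: vorimd
Title: Microdialysis Pharmacokinetics of Voriconazole and its N-Oxide
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for clinical microdialysis pharmacokinetic
    studies of voriconazole (VRC) and its N-oxide metabolite (NO):
    retrodialysis catheter calibration and reconstruction of interstitial
    space fluid (ISF) concentrations, noncompartmental exposure analysis
    with the linear-up/log-down trapezoidal rule, metabolic (NO/VRC) and
    tissue-penetration (ISF/plasma) ratio analyses stratified by CYP2C19
    phenotype, and a seedable synthetic trial simulator with saturable
    (Michaelis-Menten) N-oxidation that provides ground truth for every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
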