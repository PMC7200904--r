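Package: swinedigest
Title: Energy and Nutrient Digestibility Evaluation of Swine Feed Ingredients
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for evaluating the feeding value of ingredients for growing
    pigs: as-fed/dry-matter basis algebra for proximate composition tables,
    marker-ratio (titanium dioxide) and total-collection digestibility calculus
    for digestible and metabolizable energy, standardized total tract
    digestibility of phosphorus with a basal endogenous-loss correction,
    apparent and standardized ileal amino acid digestibility with
    nitrogen-free-diet endogenous flows, a three-step in vitro
    hydrolysis/fermentation digestibility assembly with volatile fatty acid
    energy stoichiometry, a registry of published digestible- and
    metabolizable-energy prediction equations, a confidence-interval accuracy
    rule for prediction verdicts, and a synthetic trial-data generator so every
    estimator has a parameter-recovery test without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
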