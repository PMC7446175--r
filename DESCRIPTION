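Package: dfurisk
Title: Bayesian Amputation-Risk Models for Diabetic Foot Ulcers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Bayesian logistic regression models of six-month lower-extremity
    amputation risk for patients with diabetic foot ulcers classified by the
    IWGDF PEDIS system (perfusion, extent, depth, infection, sensation).
    Provides cohort validation and input/output, a synthetic cohort generator
    for method evaluation, elicitation of informative Cauchy priors from
    published odds ratios, a self-contained Metropolis-Hastings sampler,
    convergence diagnostics (split R-hat, effective sample size,
    autocorrelation, collinearity), highest-density-interval inference,
    posterior AUC distributions, informed-versus-uninformed model comparison,
    and per-patient posterior risk prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
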