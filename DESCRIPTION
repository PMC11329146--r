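Package: huntcast
Title: Counterfactual Trend Models and Anomaly Detection for Hunting-License Count Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Fits Bayesian negative-binomial hierarchical trend models (random
    intercepts for regions and provinces, a linear year trend and a first-order
    random-walk year effect) to pre-period annual license-count panels, projects
    posterior-predictive counterfactuals into post-period seasons, flags
    observations falling outside the 95% predictive interval as anomalous,
    quantifies and regionally aggregates the anomalous decreases, and measures
    their tie-aware Spearman rank association with a provincial excess-mortality
    covariate. Includes a synthetic panel generator with full ground truth,
    leave-one-out predictive model selection (Pareto-smoothed importance
    sampling with an exact refit fallback), and an end-to-end pipeline driver.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
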