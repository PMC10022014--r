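Package: pqindex
Title: Perceived Quality of Healthcare Providers from Bypass Behaviour
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the perceived quality of healthcare providers in
    dense urban settlements from revealed-preference visit data. Computes
    generalized access costs (treatment cost, transport cost, and the
    value of travel and waiting time) over a road-and-footpath network,
    detects bypass events (visits made despite a cheaper alternative),
    and aggregates access-cost-weighted bypass contributions into a
    per-facility Perceived Quality Index (PQI). Includes a synthetic
    settlement generator with planted latent quality for end-to-end
    validation, data cleaning and facility-mean imputation utilities,
    and class-level summary reporting.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    dplyr,
    tibble,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
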