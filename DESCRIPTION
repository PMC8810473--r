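Package: wwcea
Title: Cost-Effectiveness Microsimulation of Watch-and-Wait Versus Radical
    Resection in Rectal Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Markov microsimulation cost-effectiveness analysis comparing
    nonoperative watch-and-wait management against abdominoperineal resection
    and low anterior resection for locally advanced rectal cancer patients
    with a complete clinical response after neoadjuvant chemoradiation.
    Provides a patient-level simulation engine over six health states with
    monthly cycles and a five-year horizon, a deterministic cohort
    expected-value evaluator, incremental cost-effectiveness and net monetary
    benefit arithmetic, one-way deterministic sensitivity analysis with
    threshold search, and probabilistic sensitivity analysis with beta/gamma
    parameter sampling. Base-case parameter sets (transition probabilities,
    health-state utilities, payer-perspective 2019 US$ costs) ship as editable
    YAML fixtures together with an abridged background-mortality life table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    tibble,
    dplyr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
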