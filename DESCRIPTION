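Package: tobaccoburden
Title: Markov Microsimulation of Tobacco-Attributable Disease and Economic Burden
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Individual-level first-order Markov microsimulation of the health
    and economic burden attributable to tobacco smoking. Simulates smoking
    state, disease events and death over the remaining lifetime of a
    population snapshot, contrasts factual and never-smoker counterfactual
    cohorts under common random numbers to obtain attributable deaths,
    events, years of life lost, years lived with disability and DALYs for
    sixteen smoking-related conditions, costs the attributable burden
    (direct medical, premature mortality via present value of labour income,
    disability/presenteeism, informal care), calibrates cause-specific
    mortality to registry-style reference tables, and projects ten-year
    benefits of tobacco-control policies (plain packaging, smoke-free
    enforcement, advertising bans, tax-driven price increases) through a
    prevalence-impact formula and price elasticity of demand. Ships a
    synthetic country-parameter generator including a Peru-like fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
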