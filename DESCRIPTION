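Package: ppdkit
Title: Premature Mortality Metrics, Life Expectancy Decomposition, and
    Pandemic Risk Valuation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for measuring survival progress from age-specific
    mortality rates: abridged period life tables and the probability of
    premature death (death before age 70), decline-rate trajectories with
    halving-time and target-year arithmetic, Arriaga decomposition of life
    expectancy differences by age and cause, Das Gupta decomposition of
    death-count changes into demographic and rate components, full-income
    valuation of mortality change using a value-per-statistical-life to
    income ratio, excess-mortality P-scores against projected baselines,
    and pandemic exceedance-probability and expected-loss calculations.
    Includes a synthetic demography generator (Gompertz-Makeham schedules
    with an infant hump, cause-of-death profiles, decline trajectories and
    mortality shocks) so every stage can be exercised with known ground
    truth, plus CSV readers and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
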