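Package: tpgg
Title: Threshold Public Goods Games with Stochastic Disaster Shocks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying human cooperation under recurring disaster risk
    in threshold public goods games. Implements the game mechanics of a
    collective-risk social dilemma with Bernoulli checks and account wipes,
    exhaustive pure-strategy Nash equilibrium enumeration over the integer
    strategy space, classification of players into unconditional cooperators,
    conditional cooperators and free-riders from linear conditional-contribution
    profiles, conformity diagnostics, cluster-robust treatment contrasts,
    responses-to-check trajectory summaries, a synthetic cohort generator with
    planted behavioural types, and a long-run agent-based simulation of group
    success as a function of the population's type composition.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ggplot2,
    knitr,
    readr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
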