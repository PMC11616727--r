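Package: basketssd
Title: Bayesian Sample Size Determination for Randomized Basket Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and analysis of randomized basket trials that borrow
    information between commensurate subtrials. Treatment effects in each
    patient subgroup receive collective commensurate priors built from the
    complementary subtrials via a two-component Gamma mixture prior on the
    between-subtrial precision, with synthesis weights transformed from
    prespecified pairwise incommensurability (optionally derived from the
    Hellinger distance between outcome distributions). Subtrial sample sizes
    are obtained in closed form when no borrowing is permitted, and by a
    Newton solve of coupled posterior-precision constraints when borrowing is
    enabled. Posterior efficacy/futility decision rules and a Monte Carlo
    simulator of operating characteristics (per-subtrial true/false positive
    rates and the familywise false positive rate) complete the design
    workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
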