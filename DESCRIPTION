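Package: kinloss
Title: Children Affected by Maternal Cancer: Demographic Estimation and Trends
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Model-based estimation of the number of children under 18 whose
    mother is diagnosed with cancer or dies of cancer, from national
    registry rate tables: a demographic convolution of age-specific
    fertility, maternal event rates, cohort child survival and parity
    relative risks yields expected new and prevalent affected children and
    maternal orphans by child age and calendar year. Includes direct age
    standardisation to the World Standard Population 2000, segmented Poisson
    trend estimation with BIC changepoint selection and annual percent
    changes, and a synthetic registry generator with an individual-level
    microsimulation oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
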