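Package: canestim
Title: National Cancer Incidence Estimation from Partial Registry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the nine estimation methods used by the GLOBOCAN
    project to derive national cancer incidence when complete national registry
    data are unavailable: projection of historical national rates with an
    age-period-cohort model using a power-5 link and drift attenuation,
    age-specific linear rate trends, rate transport from recent national,
    regional or neighbouring-country registries, inference from national
    mortality via mortality-to-incidence ratios or 5-year relative survival
    (M = I(1 - S)), and partitioning of all-sites rates by site frequencies.
    Provides the validation arithmetic used to benchmark such estimates
    against a recorded gold standard (separate under- and over-estimation
    totals and aggregate percentage differences), a synthetic multi-region
    registry generator with known ground truth for end-to-end testing, and a
    bundled reference table of observed and estimated case counts for Norway
    in 2010.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
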