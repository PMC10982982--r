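Package: lhonva
Title: Externally Controlled Visual-Acuity Analyses for Leber Hereditary
    Optic Neuropathy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for externally controlled analyses of visual acuity (VA)
    in Leber hereditary optic neuropathy (LHON). Converts heterogeneous VA
    records (Snellen fractions, decimal acuities, logMAR, off-chart
    categories) to a canonical logMAR scale, applies treated-arm and
    natural-history eligibility rules with an auditable exclusion ledger,
    selects matched baselines from an untreated natural-history cohort via
    time-since-onset matching (subacute/dynamic and chronic algorithms),
    classifies eyes into four responder outcomes (clinically relevant
    benefit, recovery, stabilization, worsening), and runs the comparative
    statistics: logistic regression, analysis of covariance on VA change,
    Kaplan-Meier time to first recovery, and the two-proportion sample-size
    calculation. A longitudinal cohort simulator generates synthetic treated
    and natural-history cohorts so the full pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
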