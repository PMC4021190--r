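Package: crcscreen
Title: Markov Microsimulation of Family-History-Targeted Colorectal Cancer Screening
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An annual-cycle Markov microsimulation of colorectal cancer
    natural history (adenoma-carcinoma sequence with Dukes' staging) for an
    Australian cohort at moderately increased familial risk, aged 50 to 90.
    Superimposes four screening strategies (one-off iFOBT at ages 50/55/60/65,
    biennial iFOBT, five- and ten-yearly colonoscopy), accrues discounted
    costs and life-years, and computes clinical event tables, incremental
    cost-effectiveness ratios with dominance/frontier analysis, and one-way
    sensitivity sweeps over screening participation and familial relative
    risk. Includes a deterministic cohort-matrix oracle and closed-form toy
    models for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
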