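# crcscreen

A Markov microsimulation of colorectal cancer (CRC) natural history and
family-history-targeted screening for an Australian cohort at "moderately
increased risk" (NHMRC category 2: one first-degree relative diagnosed
before 55, or two first-degree / one first- plus one second-degree relatives
diagnosed at any age; relative risk ≈ 3–6, base case 4).

The package is for health-economic modellers and screening-policy analysts.
It simulates 10,000-person cohorts from age 50 to 90 through a 14-state
adenoma–carcinoma model (normal → small adenoma → large adenoma → Dukes'
A–D cancer → treatment → death), superimposes four screening strategies, and
evaluates them in incremental cost per life-year gained (LYG):

| strategy | programme |
|---|---|
| `usual_care` | one-off iFOBT invitations at ages 50, 55, 60, 65 (NBCSP baseline) |
| `ifobt2` | biennial iFOBT from age 50 |
| `colo5` | colonoscopy every 5 years from 50 (NHMRC recommendation for this risk group) |
| `colo10` | colonoscopy every 10 years from 50 |

Costs and life-years are discounted at 5%/year; the incremental
cost-effectiveness ratio between strategies is
ICER = Δcost / ΔLYG along the efficiency frontier after removing strongly
and extendedly dominated options. All published model inputs (age-band
incidences, stage-specific mortality and diagnosis probabilities, test
characteristics, uptake, unit and treatment costs, age-50 prevalences) ship
as the bundled default profile; see the methods vignette
(`vignettes/crc-screening-model.Rmd`) for the model's assumptions, the
interpretation decisions, and the single documented calibration of the two
unpublished rates (`stage_progression`, `cure_rate`).

## Worked example

```r
library(crcscreen)

p   <- crc_parameters()                       # published defaults, RR = 4
res <- run_all_strategies(p, n = 10000, seed = 1)

res$usual_care
#> <cohort_result> strategy: usual_care  n: 10000  seed: 1
#>   CRC cases: 6275 (A/B/C/D = 3008/1553/1308/406)
#>   CRC deaths: 883 | colonoscopies: 2623
#>   mean discounted cost: 3773.22 AU$ | mean discounted LY: 15.178

icer_table(res)[, c("strategy", "cost", "effect", "icer", "status")]
#>     strategy    cost  effect    icer               status
#> 1     ifobt2 3945.79 15.1739      NA            dominated
#> 2 usual_care 3773.22 15.1782      NA             baseline
#> 3     colo10 4266.93 15.1970      NA extendedly_dominated
#> 4      colo5 4682.96 15.2215 21017.8             frontier
```

Under the usual-care baseline, 6,275 of 10,000 simulated persons develop
CRC over 40 years and 883 die of it, at a mean discounted lifetime cost of
AU$3,773 per person — within ±15% of the published anchors (6,491 / 983 /
AU$3,441). Biennial iFOBT is dominated (costlier, no more effective than the
frontier), ten-yearly colonoscopy is extendedly dominated, and five-yearly
colonoscopy is the non-dominated intensive option at about AU$21,000 per
LYG — well under the AU$50,000/LYG acceptability threshold, reproducing the
published qualitative conclusion (five-yearly colonoscopy cost-effective;
biennial iFOBT dominated). Absolute incidence/mortality *reductions* are
smaller than the published ones because screener status is a persistent
once-per-lifetime draw at 40% uptake (see the vignette's discussion).

Other entry points:

```r
cohort_matrix_oracle(p)            # deterministic expected-value twin (no screening)
sweep_participation(p, n = 10000)  # one-way uptake sweep, LYG/1000 + ICER vs usual care
sweep_relative_risk(p, 3:6)        # RR sweep re-deriving parameters per value
clinical_events_table(res)         # published-style event table
write_parameters(p, "params.json") # editable full profile; load_parameters() reloads
```

A small CLI wrapper is included:

```sh
Rscript inst/cli/crcsim.R simulate --strategy colo5 --n 10000 --seed 1 --out results/
Rscript inst/cli/crcsim.R sweep --param participation --n 10000 --seed 1 --out results/
```

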