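# appendcea

Lifetime cost-effectiveness modeling of treatment strategies for acute
uncomplicated appendicitis, from a US third-party-payer perspective
(2017 US$).

## The problem

Antibiotic-only (nonoperative) management of uncomplicated appendicitis
avoids the cost and perioperative risk of surgery, but leaves the appendix
in situ: the patient keeps a lifetime potential for recurrent
appendicitis, for complicated (perforated) recurrence, and for delayed
presentation of an unrecognized appendiceal tumor. Randomized trials stop
after a year or two, so the question of which strategy wins *over a
lifetime* is a modeling question. `appendcea` is for health-economics and
surgical-outcomes researchers who want that model as tested, reusable
code rather than a black box: a 30-day decision tree feeding a
monthly-cycle Markov cohort model (half-cycle corrected, 3%/yr
discounting, horizon to age 110), with full deterministic and
probabilistic sensitivity-analysis machinery and an individual-level
microsimulation that serves as an independent validation oracle.

Three strategies are compared:

| Strategy | Definition |
|---|---|
| `LAP_APPY` | immediate laparoscopic appendectomy |
| `INPATIENT_NOM` | 3-day IV-antibiotic admission + 7-day oral course |
| `OUTPATIENT_NOM` | 7-day outpatient oral antibiotics only |

Outcomes are lifetime discounted cost, quality-adjusted life-years
(QALYs, accrued as quality-adjusted life-months / 12) and life-years.
Strategies are compared by incremental cost-effectiveness ratios
(ICER = Δcost/ΔQALY against the next-best non-dominated comparator) at a
willingness-to-pay of $50,000/QALY, with strict and extended dominance
handled on the cost-effectiveness frontier; net monetary benefit
(NMB = WTP × QALY − cost) drives the probabilistic analysis.

## Worked example

```r
library(appendcea)

params <- load_parameters()
demo   <- load_demographics()
cfg    <- model_config()        # age 20, 3%/yr, WTP $50,000/QALY

res <- run_model(params, demo, cfg)
incremental_analysis(res, cfg$wtp)
```

```
Incremental cost-effectiveness analysis (WTP $50,000/QALY)
       strategy   cost    qaly    status   icer
 OUTPATIENT_NOM 233700 24.9270  frontier      -
       LAP_APPY 236911 25.0000  frontier 44,000
  INPATIENT_NOM 241093 24.9273 dominated      -
Preferred: LAP_APPY
```

Outpatient NOM is the cheapest strategy ($233,700 over a lifetime) but
yields the fewest QALYs; laparoscopic appendectomy buys 0.073 extra QALYs
for $3,211 more (ICER ≈ $44,000/QALY, on the frontier and preferred at
the $50,000 threshold); inpatient NOM costs the most while adding
essentially nothing over outpatient NOM and is dominated.

Sensitivity machinery, scenarios, and the microsimulation oracle:

```r
# decision threshold: appendectomy cost at which outpatient NOM takes over
find_threshold(params, demo, cfg, "cost_laparoscopic_appendectomy",
               c(0.5, 1.5) * 7606, pred_preferred("OUTPATIENT_NOM"))
#> [1] 8457.172

# scenario: no appendiceal-cancer risk after nonoperative management
run_scenario(packaged_scenarios()$no_cancer_after_NOM, params, demo, cfg)

# probabilistic sensitivity analysis with acceptability curves
psa <- run_psa(params, demo, cfg, n = 2000, seed = 1)
psa_acceptability(psa, "LAP_APPY", 50000)

# 200,000 simulated patients agree with the cohort engine within 3 SE
simulate_patients("OUTPATIENT_NOM", params, demo, cfg,
                  n = 200000, seed = 42)
```

`run_analysis("base")`, `run_analysis("scenarios")`, `run_analysis("psa")`
etc. write tabular artifacts plus a full parameter-provenance log to an
output directory.

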