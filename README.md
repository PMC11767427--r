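# osteowarn

Early-warning analysis of osteopenia from targeted metabolomic profiles.

Osteoporosis develops silently: by the time bone mineral density (BMD)
crosses the diagnostic threshold, much of the damage is done. The
dynamic-network-biomarker (DNB) view of disease progression predicts that
just before such a transition there exists a *critical state* in which a
small group of molecules — the "domain" — becomes strongly coupled and
highly variable while decoupling from the rest of the system. `osteowarn`
implements a reference-anchored, single-sample version of this analysis
for three-stage bone-loss cohorts (control → osteopenia → osteoporosis),
together with the surrounding statistical stages a full study needs:
differential-metabolite screening, random-forest biomarker selection,
module–trait correlation, and causal mediation. Because patient-level
metabolomic cohorts are rarely shareable, the package also ships a
synthetic cohort generator with planted ground truth, so every stage is
testable end to end.

## The core method

All single-sample quantities are anchored to the healthy (control)
reference. For metabolite *x* with reference mean μ<sub>x</sub> and SD
σ<sub>x</sub>, a sample's standardized deviation is
z<sub>x</sub> = (x − μ<sub>x</sub>)/σ<sub>x</sub>, and

- **sPCC** (single-sample Pearson correlation score) of a pair (x, y) is
  z<sub>x</sub>·z<sub>y</sub> — the sample's additive contribution to the
  reference Pearson correlation;
- **shPCC** standardizes two edges' sPCC scores by their reference
  distribution and multiplies them — a fourth-order coupling score of two
  metabolite pairs in one sample;
- **sCI**, the per-sample composite early-warning index of a candidate
  domain module *D*, is

  sCI = ( mean<sub>x,y∈D</sub> |sPCC(x,y)| / mean<sub>x∈D,y∉D</sub> |sPCC(x,y)| ) × mean<sub>x∈D</sub> |x − μ<sub>x</sub>|

  i.e. intra-domain coupling, over out-of-domain coupling, times the
  domain's deviation magnitude — the three DNB signatures in one number.

`detect_critical_stage()` clusters metabolites into candidate modules,
scores every out-of-reference sample's sCI for each candidate, and calls
the stage at which the best module's aggregate sCI peaks the *critical
stage*. On cohorts with a planted transition at the middle stage this
recovers osteopenia in ≥95% of runs; on flat (null) cohorts each stage is
named about a third of the time.

## Worked example

```r
library(osteowarn)

sim <- generate_cohort(sim_config(), seed = 1)   # 150 samples x 60 metabolites
coh <- filter_missing(sim$cohort)                # 20% rule + median imputation
dom <- detect_critical_stage(coh)
dom
#> Domain module: 10 metabolites
#> Stage mean sCI:
#>      control   osteopenia osteoporosis
#>       3.9370      40.0499       6.4776
#> Critical stage: osteopenia
intersect(dom$members, sim$truth$domain_members) # all 10 planted members
```

The stage trajectory is the early-warning signal: the index is several
times larger at the middle (osteopenia-analog) stage than in either the
control or the disease stage, flagging it as the tipping point. The other
stages follow the same pattern:

```r
dma <- run_dma(coh)                      # trend + pairwise rank tests
pan <- train_select_retrain(coh, dma$significant_pairwise[["ctrl-vs-open"]],
                            seed = 1)    # RF biomarkers, held-out AUC
med <- mediate_screen(coh, "TFFM", pan$selected, seed = 1)
```

or run everything at once with `run_pipeline(run_config(seed = 1), "out/")`,
which writes per-stage tables and a reproducibility manifest.

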