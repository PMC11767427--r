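---
title: "Methods: single-sample edge networks and the sCI early-warning index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-sample edge networks and the sCI early-warning index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteowarn)
```

## The problem and the model

Bone loss progresses through an ordered sequence of states — normal bone
mass, osteopenia, osteoporosis — defined operationally by dual-energy
X-ray absorptiometry T-scores: `(measured BMD − young-adult mean) /
young-adult SD`, with osteoporosis called when any skeletal site falls
below −2.5 and, in this package's default convention, normal bone mass
when every site is at or above −1.0 (the threshold is configurable, and
the convention is logged, because "above −2.5 everywhere" alone would
leave no room for an osteopenia group).

Dynamic-network-biomarker (DNB) theory predicts that immediately before a
state transition a subset of variables — the *domain* — shows three
simultaneous signatures: rising intra-domain correlation, rising
intra-domain variance, and falling correlation with everything outside
the domain. The package looks for these signatures per sample, anchored
to a healthy reference, so that a warning index exists for an individual
rather than only for a group.

With reference mean $\mu_x$ and SD $\sigma_x$ per metabolite, and
$z_x(s) = (x(s) - \mu_x)/\sigma_x$:

* $\mathrm{sPCC}_s(x,y) = z_x(s)\,z_y(s)$. Averaged over the reference
  samples themselves this recovers $(n-1)/n$ times their Pearson
  correlation, which is why we read it as the sample's additive
  contribution to the reference correlation. An alternative
  "perturbation" form (correlation with the sample appended minus the
  reference correlation) is available via `spcc(form = "delta")` for
  sensitivity analysis; the product form is the default because it is
  exactly decomposable across samples and fast enough to evaluate for
  every pair.
* $\mathrm{shPCC}_s(e_1,e_2) = Z_{e_1}(s)\,Z_{e_2}(s)$, where $Z_e(s)$
  standardizes the sample's edge score by the mean and SD of that edge's
  scores over the reference. Four metabolite values enter, hence a
  fourth-order score. Edges come from `select_top_edges()`: metabolites
  have no curated background interaction network, so the top
  mean-$|\mathrm{sPCC}|$ pairs across non-reference samples (default top
  1% of all pairs, or a fixed `top_k`) serve as the background edge set,
  with lexicographic pair-id tie-breaking for determinism.
* The composite index of a candidate domain $D$ in sample $s$ is
  $$\mathrm{sCI}(s, D) =
  \frac{\overline{|\mathrm{sPCC}_{in}|}}{\overline{|\mathrm{sPCC}_{out}|}}
  \times \overline{|x - \mu_x|},$$
  the three DNB signatures multiplied. The deviation factor is kept
  un-normalized by $\sigma$, exactly as displayed above; because that
  makes it scale-dependent across panels with heterogeneous units, a
  σ-standardized variant can be obtained by rescaling inputs beforehand.

Because $|z_x z_y| = |z_x||z_y|$ factorizes, all pair means reduce to row
sums, so per-sample sCI costs $O(p)$ rather than $O(p^2)$; the test suite
checks the vectorized path against explicit four-nested-loop oracles at
$10^{-10}$.

## Critical-stage detection: design choices that matter

`detect_critical_stage()` proceeds: reference → candidate modules →
per-sample sCI → stage aggregates → argmax. Three choices deserve
explanation because the obvious alternatives are miscalibrated.

**Held-out reference.** If the whole control group defines the reference
*and* is scored against it, control samples lack the reference-estimation
noise that every other sample carries, and a maximum taken over (module,
stage) aggregates almost never lands on the control stage even when
nothing is happening. The package therefore anchors the reference on a
held-out subset of controls (`reference_fraction = 0.5`, deterministic
first-in-row-order split) and stages the decision on out-of-reference
samples only. Reference samples still receive sCI values for trajectory
plots, computed against the leave-one-out reference (exact mean/SD
downdates), which removes their in-sample attenuation.

**Balanced stage aggregates.** The scored control group is half the size
of the other stages, hence its mean sCI is noisier, and an argmax over
stages systematically favours noisier groups for a right-skewed index.
Stage aggregates are therefore computed over equally many samples per
stage (the first `n_min` in row order). Under a flat cohort the three
aggregates are then exchangeable, and the null calibration acceptance
test (each stage named critical in 33% ± 10 points over 100 cohorts)
passes across seed sets rather than by luck.

**Module search.** Exhaustive subset search over domains is
combinatorially infeasible; candidates come from average-linkage
clustering on $1 - |r|$ with a static cut (`cut_height = 0.8`), keeping
clusters within `min_size = 3` to `max_size = 30`. When no cluster at
that height fits the bounds (typical for null data), the cut count that
maximizes the number of in-bounds clusters is used instead, with a
warning — so the procedure always produces candidates and its null
behaviour is testable. The aggregator over samples is the arithmetic
mean (`aggregate = "median"` available); the sCI denominator is floored
at $\varepsilon = 10^{-8}$ with a flag, so a fully decoupled module
yields a large finite value, never NaN/Inf.

## The surrounding stages

*Differential metabolite analysis* (`run_dma`): Jonckheere–Terpstra
trend test across the three ordered stages (hand-implemented: Mann–
Whitney kernel sums with ties counted ½; tie-corrected normal
approximation, exact enumeration for pooled $n \le 12$) plus Wilcoxon
rank-sum tests for the three stage pairs via `stats::wilcox.test`.
Significance uses raw $p < 0.05$ by default — the conventional screening
practice this pipeline mirrors — with Benjamini–Hochberg available via
`p_adjust = "BH"`. Ordination standardizes metabolites to zero mean/unit
SD (log transform optional, off by default since the rank tests are
transform-invariant anyway) and uses `prcomp` for PCA and
`mixOmics::plsda` (two components, one-hot stages) for the supervised
view.

*Random-forest biomarkers* (`train_select_retrain`): 70/30 stratified
split, a 500-tree `randomForest` with $\sqrt{p}$ features per split and
no depth limit (conventional defaults, fixed and recorded), Gini
importances normalized to percent, selection at a 5% share (falling back
to the top 3 with a warning), retrain on the selection, and held-out ROC
with a DeLong 95% CI via pROC. Selection sees training data only.
`compare_auc()` is DeLong's paired test (pROC), the standard choice for
two correlated ROC curves scored on the same test samples; the baseline
comparator is the same forest on the three bone-turnover markers.
Whether importance should be Gini- or permutation-based is not
determined by the problem; Gini is used because it is the package
default and the planted-recovery tests validate it; the 5% cut is taken
over all candidate features.

*Module–trait analysis* (`wgcna_modules`, `trait_correlations`): a
compact weighted-correlation-network implementation — unsigned adjacency
$|r|^\beta$ with soft power $\beta = 6$, topological overlap, average
linkage on $1-\mathrm{TOM}$, static cut at 0.9 with `min_size = 5`, grey
pool for the unassigned, deterministic color labels by size rank. A
static cut replaces dynamic hybrid tree cutting deliberately: it is a
few lines, tunable, and sufficient for planted-block recovery; the
divergence from canonical WGCNA is intentional and documented here.
Eigen-metabolites are first principal components, sign-oriented to
correlate non-negatively with mean module abundance; trait cells use
pairwise-complete Pearson correlation with a 3-pair floor.

*Mediation* (`mediate`): mediator model `lm(M ~ X)`, outcome model
`glm(Y ~ X + M, binomial)`, quasi-Bayesian potential-outcome draws
(default 1000 parameter draws × 200 shared mediator simulations), effects
on the risk-difference scale, continuous exposure contrasted at mean ± 1
SD. The four potential-outcome means are combined so that ACME + ADE
equals the total effect exactly within each draw. Percentile 95%
intervals do not shrink with more draws (they converge to the parameter
distribution's quantile spread); the Monte-Carlo SE of the point
estimate, which does shrink at $1/\sqrt{\text{draws}}$, is reported
separately. Proportion mediated is reported only when the total-effect
CI excludes zero. Separation in the logistic fit is detected and
reported as an error rather than silently producing absurd draws.

## The synthetic cohort generator

`generate_cohort()` draws each stage from a multivariate normal on the
log scale and exponentiates (log-mean 3, log-SD 0.25, i.e. ~20 µM with
~25% CV — typical for a targeted serum panel), so abundances are positive
and approximately log-normal; at this SD the planted correlations survive
exponentiation essentially unchanged. The planted structure follows the
DNB premise that the *critical* state, not the end state, is maximally
coupled and variable: intra-domain correlation 0.2 → 0.7 → 0.35, domain
SD multiplier 1.0 → 2.0 → 1.3, domain-to-background correlation
0.15 → 0.05 → 0.10 against a constant 0.1 background. (A larger control
value of the domain–background correlation would be incompatible with
positive definiteness at these block sizes — 10 domain, 50 background —
which the constructor checks and reports by stage.) Eight background
metabolites carry a monotone mean trend of 0.5 log-SD per stage for the
trend-test stages; 5% of cells go missing at random by default, with a
left-censoring mode as a detection-limit analog. Mediation data follow
X → M → binary Y with logistic outcome; the true ACME is computed by
numeric integration over the mediator distribution and stored as the
oracle for coverage tests.

What the generator does *not* emulate: real panel class structure
(acylcarnitines vs lipids vs amino acids), inter-class covariance,
batch effects, skewed or heavy-tailed measurement error, and
missingness that depends on disease stage. Passing tests therefore show
that the machinery is correct and calibrated under a faithful DNB-style
generative model — not that any particular real cohort contains a
detectable tipping point.

## Problem sizes and run times

The suite and the acceptance script size their simulations to run on one
CPU in a few minutes total: 100 cohorts of 150 × 60 for stage-recovery
and null calibration; 10,000 trend-test null replicates (3 × 20); 20
planted-selection and 100 null-AUC forests (160 × 20); 5,000 DeLong
null comparisons (30/class); 200 mediation replicates at n = 2000;
32-metabolite planted-block recovery at n = 300. These sizes keep
Monte-Carlo error comfortably inside the asserted bands (e.g. a
proportion over 100 seeds has SE ≈ 5 points at worst).

## Known limitations

* sCI's deviation factor is scale-dependent by construction; comparing
  sCI across panels with heterogeneous units requires prior rescaling.
* The static module cuts (both the $1-|r|$ cut and the WGCNA-style TOM
  cut) trade the adaptivity of dynamic tree cutting for simplicity;
  strongly nested module structure may be merged or split.
* The mediation estimator assumes sequential ignorability and no
  exposure–mediator interaction; no sensitivity analysis is provided.
* With real (non-synthetic) cohorts the gender strata should be analysed
  separately (`run_config(gender = ...)`); the pooled default exists for
  synthetic calibration work.
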