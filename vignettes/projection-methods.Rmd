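---
title: "Sequential multiple-imputation projections of mobility limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential multiple-imputation projections of mobility limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobproj)
```

## The problem and the method

Policy planning for ageing populations needs projections of the prevalence
of functional limitations — here, self-reported difficulty climbing one
flight of stairs and difficulty walking across a room — and, ideally, of how
that prevalence would respond to population-level interventions. mobproj
implements a non-parametric projection method for harmonised multi-study
longitudinal survey panels observed on a common biennial wave grid
(2000–2012 in the reference design, three studies with different baseline
waves and structurally missing variables).

Write the completed individual-level panel as $I = (I^1, \dots, I^t)$,
one block per wave, with vital status $d_{i,t}$. The method has four layers:

1. **Chained-equations imputation with CART conditional models.** Every
   incomplete variable is imputed by a classification or regression tree fit
   on the rows where it is observed; a row with a missing value is routed to
   its terminal node and receives one *observed donor value drawn uniformly*
   from that node. Donor draws guarantee imputed values stay in the
   observed support (scores stay in $\{0,\dots,6\}$, binaries stay binary).
   To keep models small, a *selection tree* per target first reduces the
   candidate predictors to those appearing in at least one split; age, sex
   and education at the anchor wave are forced into every model.

2. **Sequential wave-advancing projection.** The projection step $s$ stacks
   the trailing $t$-wave window over a survivor copy shifted forward one
   wave: $R_1 = (I^\top, A_1^\top)^\top$ with
   $A_1 = (I^2,\dots,I^{t+1})_{i: d_{i,t}=1}$, where wave $t{+}1$ is wholly
   missing except age (incremented by 2) and sex (constant). Imputing the
   missing wave from the stacked frame embodies the *stationarity
   assumption*: the variables change between waves $2$ and $t{+}1$ with the
   same transition probabilities as between waves $1$ and $t$. Subsequent
   steps advance the window ($R_2 = (A_1^\top, A_2^\top)^\top$, restricted
   to survivors of wave $t{+}1$), so the horizon is limited to $t{-}1$
   steps beyond the observed grid — 2026 for a 2000–2012 panel.

3. **Intervention scenarios.** Scenario 0 projects with no modification.
   Scenarios 1 and 2 emulate a physical-activity intervention at the first
   projected wave: the IADL (scenario 1) or IADL and ADL (scenario 2) sum
   score of each individual *without vigorous physical activity* is replaced
   by a draw from $N(y + \mathrm{SMD}\cdot\sigma,\ \sigma)$, where
   $\mathrm{SMD} = 1.12$ is a meta-analytic standardised mean difference for
   physical-activity interventions on self-reported ADL/IADL measures and
   $\sigma$ is the study-specific standard deviation of the score at
   baseline. Shifted scores are truncated to $[0, 6]$. The step-1 frame is
   imputed in two phases — everything except outcomes and vital status
   first, then (after the shift) outcomes and vital status — so the
   modified scores act as predictors of the outcomes and of death.

4. **Rao–Wu bootstrap.** Sampling uncertainty is propagated by resampling
   $n-1$ individuals with replacement within each study stratum; each
   replicate re-runs imputation, scenarios and projection, and every
   statistic is summarised by the mean, variance and 95% credible interval
   (percentile, by default) of its replicate ensemble. One imputation is
   drawn per replicate: the bootstrap supplies the "multiple" of multiple
   imputation.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_leaf` | 5 | minimum donors per terminal node; the donor pool of any imputed cell |
| `complexity` | 1e-4 | minimum complexity decrease to split (rpart `cp`) |
| `max_depth` | 30 | tree depth cap |
| `n_chained_iters` | 5 | sweeps of the chained-equations loop |
| `n_bootstrap` | 120 | bootstrap replicates |
| `horizon_year` | 2026 | last projected year (window-limited) |
| `min_age` | 76 | reporting restriction; 76 is the minimum attainable age at 2026 for a cohort aged ≥ 50 in 2000 |
| `smd` | 1.12 | intervention effect size on the standardised score scale |

The CART controls mirror the conventional defaults of CART-based chained
equations; the reference methodology states no hyperparameters, so they are
declared, configurable choices rather than inferred ones. Analyses at
reduced problem sizes (the test suite, examples) use coarser trees
(`min_leaf = 10`, `complexity = 1e-3`) and 2 sweeps, which keeps conditional
distributions well estimated at $n$ of a few thousand while keeping tree
size proportionate.

## The synthetic cohort generator

Real harmonised panels of this kind are access-controlled, so the package
ships a generator (`cohort_config()`, `generate_cohort()`) that emulates the
statistical structure the method relies on, with closed-form oracles:

- individual disability evolves as a first-order latent Markov chain
  (default three states: good, limited, severe); the twelve ADL/IADL items
  (coded 1 = no difficulty) and the two mobility outcomes are drawn
  conditionally on the current state (outcomes also on age band), which
  induces the item–score–outcome correlation the scenarios exploit;
- five binary risk factors follow first-order transitions; vigorous
  physical activity is one of them and defines scenario eligibility;
- death is a per-wave logistic hazard in age and latent state, absorbing;
  ages increment deterministically by 2;
- missingness comprises per-study structural rules (a study missing its
  first wave; a study observed only at baseline and a single follow-up
  randomly assigned to one of the two final waves; items never fielded in a
  study), wave non-response (blanking substantive variables but not age,
  sex or vital status), and independent cell-level missingness.

Because the chain is time-homogeneous, `analytic_prevalence()` computes the
exact outcome prevalence among survivors at any wave — including projected
ones — by forward recursion over (latent state × survival) jointly with the
deterministic age process. This is the central recovery target: a
scenario-0 projection of such a cohort must track the recursion.

Default sizes, age range (uniform 50–85 at baseline), item/outcome
probabilities and risk-factor dynamics were chosen once to give realistic
mid-life-to-old-age prevalence levels and ~17% twelve-year mortality; they
are study conditions, not tuning knobs. What the generator deliberately does
*not* emulate: refreshment samples, survey design weights, informative
(MNAR) non-response, age top-coding (available as an off-by-default flag),
and calendar-time trends in transition probabilities. Passing tests
therefore certify the machinery under first-order-Markov, MAR-style
conditions — not that any real cohort satisfies those conditions.

## Numerical and design choices

- **Visit order.** Chained sweeps visit variables in order of increasing
  missingness fraction, ties broken by column order — deterministic, so a
  run is bit-identical under a repeated seed. Projected waves always use
  the two-phase order (risk factors and scores, then outcomes and vital
  status) for *all* scenarios: a common order is what makes scenario copies
  coupled, so a null intervention (SMD = 0, which skips the shift) yields
  frames identical to scenario 0 under the same seed.
- **RNG streams.** Every stage derives a named 31-bit stream from the
  master seed and its path (replicate, step, phase), so any single
  replicate is independently reproducible and per-step streams are shared
  across scenarios. Donor draws consume one uniform per imputed row, so
  rows whose donor pool is unchanged between scenarios receive identical
  draws — scenario contrasts are then driven by the intervention, not by
  re-randomisation.
- **Vital status.** Death is completed deterministically where implied
  (absorbing downward; observed survey content implies being alive) before
  any model-based imputation; substantive cells at dead waves are never
  imputed, and rows imputed dead at a projected wave leave the survivor
  chain at the next step.
- **Selection on incomplete candidates.** During predictor selection only,
  missing categorical candidates become their own category and missing
  numeric candidates are median-filled; imputation draws never use these
  fills, so selection cannot leak imputed values.
- **Structurally missing items** (an item never fielded in one study) are
  imputed in the pooled chained pass like any other missing cell, then
  summed into the 0–6 score: the only reading consistent with deriving
  scores after imputation that keeps all studies on one score scale.
- **Scenario-2 ADL scale.** The ADL shift is scaled by the ADL score's own
  baseline SD (`sd_source = "matched"`); scaling both shifts by the IADL SD
  is exposed as `sd_source = "iadl"`. The reference description labels the
  ADL scale factor ambiguously; matching each score to its own SD is the
  coherent default.
- **Eligibility wave.** "No vigorous physical activity" is evaluated at the
  intervention wave, using the phase-1 imputation (the intervention is
  applied *at* that wave); `eligibility_wave = "observed"` anchors it at
  the last observed wave instead.
- **Predictor selection frequency.** Selection runs once per replicate on
  the imputed observed data, and the resulting specs are reused (window
  positions fixed) at every projection step — the stationarity assumption
  implies the same conditional models apply at each step, and re-selecting
  per step would break the comparability of selection proportions across
  replicates.
- **Intervention persistence.** The shift is applied once, at step 1;
  whatever persistence the transition models encode carries it forward.
- **Failures.** A failed replicate aborts the run with its index attached;
  silent skipping would bias the ensemble.
- **Credible intervals.** Percentile intervals of the replicate ensemble by
  default (assumption-free for the predictive distribution); a normal
  approximation is available by flag.

## What the tests demonstrate, and at what sizes

The suite generates all fixtures in code. The heavier checks run at sizes
chosen to balance statistical resolution against runtime on one core: the
latent-chain recovery at $n = 50{,}000$; chained-imputation marginal
preservation at $n = 5{,}000$ under 20% MCAR; the scenario operator's SMD
recovery at $n = 100{,}000$ draws; the scenario-0 Markov recovery at
$n = 5{,}000$, 30 replicates, 3 projection steps; the planted-intervention
direction at $n = 3{,}000$, 30 replicates; bit-reproducibility of a full
run at $n = 2{,}000$, 10 replicates, 2 scenarios.

Two tolerances deserve note. The pre-truncation SMD recovery uses the exact
Monte-Carlo SE $1/\sqrt{n}$ of a standardised mean. The Markov recovery
compares the replicate-mean projection with the *true* chain's recursion,
while the projection by construction targets the *base sample's* empirical
chain, whose deviation from the truth compounds over steps; the
between-replicate SD — the Rao–Wu bootstrap's own estimate of exactly that
sampling variability — is therefore the appropriate Monte-Carlo SE, floored
at the binomial SE of the base sample.

## Known limitations

- The horizon is structurally limited to $t - 1$ biennial steps past the
  observed grid; the method needs equally spaced waves.
- Transition stationarity is assumed, not tested; secular trends in
  disability dynamics would be projected as absent.
- One imputation per bootstrap replicate means within-imputation and
  between-sample variability are not separated, only their total is
  propagated.
- The SMD is treated as a known constant; its confidence interval is not
  propagated.
- Associations exploited by the imputation models are observational; the
  scenario contrasts are what-if statements under the fitted transition
  structure, not causal effects.
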