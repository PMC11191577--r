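---
title: "Modelling occult nodal spread in oral tongue cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling occult nodal spread in oral tongue cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lymphmm)
```

## The clinical problem

In oral tongue squamous cell carcinoma, a substantial fraction of patients
harbour *occult* nodal metastases: lymph node levels (LNLs) that look
healthy on MRI but contain microscopic tumor. Elective neck dissection and
nodal target-volume definition therefore have to reason about unseen
disease. The quantity this package estimates is

> the probability that LNL *v* is truly involved, given which levels were
> read positive on imaging and the patient's T-stage.

Prevalence tables answer this only on average. The model here instead
treats metastatic spread as a stochastic *process* on the lymphatic
drainage graph, so that the observed pattern of macroscopic disease and the
tumor's stage both reshape the estimate patient by patient.

## The model

### Hidden states and the drainage graph

The true involvement of the $V$ modelled levels (I–IV by default) is a
hidden binary vector $X = (X_1, \dots, X_V)$, one of $2^V$ states. Spread
follows a directed acyclic graph: the primary tumor seeds each level $v$
directly with *base probability* $b_v$ per time step, and an involved
level $r$ seeds its downstream neighbour $s$ with *transition probability*
$t_{rs}$ per step. The default graph is the cervical drainage chain
I $\to$ II $\to$ III $\to$ IV, giving parameters
$b_1, \dots, b_4, t_{12}, t_{23}, t_{34}$.

### Dynamics

Time is discrete. A healthy level becomes involved in one step unless
every incoming route fails independently (a noisy-OR):

$$P(X_v^{(\tau+1)} = 1 \mid X^{(\tau)} = x,\ x_v = 0)
  \;=\; 1 - (1 - b_v) \prod_{r \in \mathrm{pa}(v),\ x_r = 1} (1 - t_{rv}),$$

and involvement never reverts (there is no healing), so the
$2^V \times 2^V$ transition matrix is upper-triangular in the subset order
and the all-involved state is absorbing. `transition_matrix()` builds this
kernel; rows sum to one to machine precision and every "healing" entry is
exactly zero by construction, not by rounding.

### Observation model

Each level is read on MRI independently: a truly involved level is
positive with sensitivity 0.81, a truly healthy one negative with
specificity 0.63 (literature values for MRI in head and neck cancer; they
are fixed, not learned, and configurable in `observation_model()`). Levels
whose status is unknown are marginalised out, never imputed negative.

### Time prior and stage

The number of elapsed progression steps at diagnosis is unobserved. It is
given a binomial prior $T \sim \mathrm{Bin}(t_{\max}, p)$, chosen for its
simple unimodal shape. At $t = 0$ the patient is healthy with probability
one. Early (T1–T2) and late (T3–T4) patients share the spread parameters
but differ in the time prior: `p_early` is held fixed (default 0.3) to
anchor the otherwise unidentifiable time scale, and only `p_late` is
learned. The state distribution at diagnosis is
$\pi = \sum_t P(T = t)\, e_\emptyset A^t$.

`t_max` defaults to 10 steps. The value is a resolution choice, not a
clinical quantity: enough steps for smooth occupancy curves and a
late-stage prior that can sit well to the right of the early one, while
keeping the likelihood a short sum of matrix powers.

### Inference

The likelihood of a patient is
$\sum_x \pi_x \, P(\text{diagnosis} \mid x)$ and patients are independent.
With a uniform prior on $[0,1]^d$, the posterior over
$\theta = (b, t, p_{\text{late}})$ is sampled with an affine-invariant
ensemble ("stretch move") sampler written for this package: ensembles need
no proposal-scale tuning, and the corner-plot workflow (marginals plus
pairwise correlations, `parameter_correlations()`) falls out naturally.
Defaults are $6d$ walkers, 300 burn-in and 600 retained ensemble steps —
with a ~1 ms likelihood and a unimodal posterior this yields tens of
thousands of draws with Monte Carlo error far below posterior widths at
cohort sizes of order $10^2$–$10^3$. Acceptance fraction and integrated
autocorrelation time per parameter are reported in
`fit$samples$meta`; they are diagnostics, not gates, because weakly
identified parameters (e.g. $t_{12}$ in a ~100-patient cohort) can have
autocorrelation times of the order of the chain itself while the
identified parameters mix quickly. Parameters the data carry no
information about simply revert to the uniform prior — documented
behaviour, not an error.

### Risk

Given a diagnosis $\zeta$, Bayes inversion
$P(x \mid \zeta) \propto P(\zeta \mid x)\, \pi_x$ (`state_posterior()`)
yields the occult-involvement risk of any level or set of levels
(`microscopic_risk()`, `predict()`). Risks are reported per posterior draw
(histograms) and as posterior means, mirroring the conventional
risk-table layout via `canonical_queries()` and `risk_table()`; the four
canonical conditioning patterns interpret "II only" etc. as full
four-level diagnoses with the unlisted levels observed negative.

## The Bayesian-network comparison

The one-pass Bayesian network (BN) predecessor model assigns
$P(x) = \prod_v \big[p_v(x)\big]^{x_v}\big[1 - p_v(x)\big]^{1-x_v}$ with
$p_v(x) = 1 - (1 - b_v)\prod_{r \in \mathrm{pa}(v), x_r=1}(1 - t_{rv})$,
then conditions on the diagnosis exactly as above (`bn_risk()`).

The exact relationship to the time-resolved model deserves care. One
*parallel* step of the transition kernel from the healthy state gives
independent Bernoulli($b_v$) involvement — the inter-level terms cannot
act, because parents were all healthy when the step began. The BN joint is
instead reproduced, exactly, by a single step in which levels update *one
at a time in topological order*, so that spread acquired earlier in the
sweep cascades onward within the same step. Both kernels are available
(`transition_matrix(..., order = "parallel")`, the default dynamics, vs
`"topological"`), and the package's equivalence tests assert the identity
`BN == one topological step` to $10^{-10}$ — and that the parallel
one-step kernel does *not* reproduce the BN once inter-level spread is
active (the difference is of order $b_r t_{rv}$, about 0.07 at the default
parameters). Over many steps the two schedules converge to the same
absorbing behaviour; the parallel schedule is kept as the model's dynamics
because it treats a time step as a synchronous epoch rather than an
ordered sweep.

## The synthetic-data generator

No patient-level cohort is distributed with the package, so
`simulate_cohort()` generates cohorts with exactly the statistical
structure the model assumes: draw $T$ from the stage's binomial prior,
evolve the hidden state $T$ parallel steps, then corrupt each level's
read through the sensitivity/specificity model. The default conditions
emulate a ~108-patient oral tongue cohort: 66 early / 42 late (the
published stage mix, with the late count chosen so the total is 108), and
generating parameters $b = (0.39, 0.53, 0.03, 0.01)$,
$t = (0.5, 0.3, 0.2)$, $p_{\text{late}} = 0.6$, $p_{\text{early}} = 0.3$.
The $b$ values for levels I–III are the posterior point estimates reported
for this disease site; level IV uses 0.01 instead of the reported 0.00 so
that the level-IV arc remains statistically identifiable in simulation
(the degenerate preset is `default_generator_theta(b4 = 0)`). The $t$
values and time parameters are not published and are synthetic choices
that reproduce the published qualitative orderings (II the most involved
level, III and IV progressively rarer, downstream risk rising sharply when
the upstream level is seen positive).

What the generator does **not** emulate: radiological reading criteria and
reader disagreement, correlated observation errors between adjacent
levels, covariates (HPV status, areca-nut history, age), levels V–VII, and
contralateral spread. Passing recovery and calibration tests therefore
demonstrate internal consistency of the method under its own assumptions,
not fidelity of those assumptions to clinical data.

## Numerical choices

* All probability arithmetic is linear-space; logs are taken only at the
  cohort-likelihood level. With at most 16 states and probabilities
  bounded away from the denormal range this is exact enough that matrix
  rows sum to 1 within $10^{-12}$.
* Patients are aggregated into unique (stage, diagnosis-pattern) cells
  before MCMC, so the likelihood cost is independent of cohort size.
* Zero-probability diagnoses make a cohort log-likelihood $-\infty$
  (a rejected MCMC proposal), while a *conditioning* query on such a
  diagnosis raises an error: the posterior is genuinely undefined there.
* Walkers initialise uniformly in $[0.1, 0.9]^d$ to avoid boundary-stuck
  starts; every run is reproducible from a single integer seed, and the
  sampler restores the caller's RNG state.
* Cross-validation folds are stratified by stage class, so each third of a
  108-patient cohort keeps the 22/14 early/late mix; totals differ by at
  most one patient even when the per-stage counts do not divide by three.
* The predicted-risk-versus-prevalence comparison is made on *observable*
  pattern probabilities (per posterior draw) against the
  $\mathrm{Beta}(k+1, n-k+1)$ posterior of the pattern's cohort frequency,
  so model and data are compared on the same scale; the overlap
  coefficient integrates the pointwise minimum of the two normalised
  histograms on a fixed 100-bin grid.

## Problem sizes used in the tests

The test suite works at desk scale by design: exhaustive trajectory
enumeration oracles run on graphs of up to 3 levels and at most 4 time
steps (monotone paths only, a few hundred per case); parameter recovery
uses a 2000-patient cohort (1000 early / 1000 late) and verifies posterior
means within 0.1 of the generating values with 95% intervals covering at
least 6 of 8 parameters; the calibration and ordering checks use a
108-patient cohort with shortened but converged chains. The acceptance
script refits a fresh 108-patient cohort end to end, including threefold
cross-validation.

## A worked example

```{r, eval = FALSE}
cohort <- simulate_cohort(n_early = 66, n_late = 42, seed = 7)
fit <- lymph_hmm(cohort, seed = 7)
summary(fit)

# risk of occult level-III disease after a positive level-II read
predict(fit, diagnosis = c(I = 0, II = 1, III = 0, IV = 0),
        stage = "early", level = "III")

# the canonical risk-table layout
rt <- risk_table(fit$samples$draws[seq(1, 28800, by = 72), ],
                 canonical_queries(stage = "early"))
print(rt)
```

## Known limitations

* Unilateral, levels I–IV only; no skip arcs (e.g. II $\to$ IV) are in the
  default graph because the drainage chain is the evidenced topology —
  alternative graphs can be supplied but are not model-selected.
* The imaging operating point is a fixed literature value; institutional
  variation in MRI reading directly shifts the occult-risk estimates.
* `p_early` is fixed by convention; only the ratio of time scales between
  stages is learned. Absolute "time steps" have no clock interpretation.
* Posterior summaries assume a unimodal posterior (true for this
  likelihood in all conditions exercised here); multimodal targets would
  need tempering the sampler does not implement.
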