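---
title: "Slice-Gibbs estimation of testlet response models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slice-Gibbs estimation of testlet response models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The models

A test of `J` dichotomous items is partitioned into `K` mutually exclusive
and exhaustive testlets; `d(j)` is the testlet of item `j`, `S_d` its item
set and `n_d = |S_d|`.  For person `i` with ability `θ_i ~ N(0,1)` the
package fits three logistic models for `p_ij = P(y_ij = 1)`:

* **2PL**: `logit(p_ij) = a_j (θ_i − b_j)` — local independence.
* **T2PLTM**: `logit(p_ij) = a_j (θ_i − b_j + η_{i d(j)})` — the classical
  random-effects testlet model; item `j`'s own slope loads the testlet
  effect.
* **N2PLTM**: `logit(p_ij) = a_j (θ_i − b_j) + α_{d(j)} η_{i d(j)}` with the
  *testlet discrimination* `α_d = (1/n_d) Σ_{j∈S_d} a_j`.  The loading on
  the testlet effect is shared by the whole bundle: how strongly the common
  stimulus expresses itself in a response depends on the average
  discriminating power of its items, not on one item alone.

`η_{ik} ~ N(0, σ²_{ηk})` is a person-by-testlet random effect; its variance
is the amount of local dependence in testlet `k` (zero restores conditional
independence).  When every item of a testlet has the same slope `c`, then
`α_d = c` and the N2PLTM coincides cellwise with the T2PLTM; with all
`η = 0` both collapse to the 2PL.  These reductions are asserted in the
test suite.

**Identification.**  Location and scale trade-offs among `θ`, `b`, `a` and
`η` are removed by fixing the ability distribution to `N(0,1)` and pinning
`a_1 = 1`, `b_1 = 0`.  The pinned parameters are never updated, and the
truth generator pins them too, so recovery error for item 1 is exactly
zero.

**Priors.**  Slopes: `N(μ_a, σ²_a) I(0, ∞)`; difficulties: `N(μ_b, σ²_b)`
(all prior means 0); or, alternatively, uniform priors `a ~ U(0, 100)`,
`b ~ U(−100, 100)`.  The variances `σ²_a`, `σ²_b`, `σ²_{ηk}` carry
`IG(0.001, 0.001)` hyperpriors and are updated by their conjugate full
conditionals.  Because `μ_a = 0`, the positive truncation costs a constant
factor `1/2` that does not involve `σ²_a`, so the untruncated conjugate
update for `σ²_a` is exact.

A note on the uniform difficulty support: a `U(0, 100)` difficulty prior
would exclude the negative difficulties that realistic generating processes
produce, so the package uses the symmetric `U(−100, 100)` for `b` and keeps
`U(0, 100)` for slopes.

## The sampler

Each observed cell is augmented with one uniform slice variable:
`λ_ij ~ U(0, p_ij)` where `y_ij = 1` and `φ_ij ~ U(0, q_ij)`,
`q_ij = 1 − p_ij`, where `y_ij = 0`.  The augmented joint density replaces
each Bernoulli factor by an indicator (`λ_ij ≤ p_ij`, resp.
`φ_ij ≤ q_ij`); integrating the slice variables back out recovers the
original posterior.  Conditional on the slice variables each indicator is a
linear inequality in any single parameter of the linear predictor, so every
full conditional is the prior truncated to an interval:

* `b_j`: upper bounds from `y = 1` cells, lower bounds from `y = 0` cells of
  item `j`;
* `θ_i`: bounds from person `i`'s row;
* `η_ik`: bounds from all items of testlet `k` in person `i`'s row, taking
  the max of the `y = 1` candidates and the min of the `y = 0` candidates —
  all of the testlet's indicators constrain the effect simultaneously;
* `a_j`: under the N2PLTM, writing the linear part of cell `(i, j)` as
  `a_j (θ_i − b_j + η_{id}/n_d) + Σ_{k≠j} (a_k/n_d) η_{id}` shows that `a_j`
  also enters every *sibling* cell `(i, j′)`, `j′ ∈ S_d − {j}`, through
  `α_d`.  The sampler therefore intersects the bounds from item `j`'s own
  cells with those contributed by the sibling cells (coefficient
  `η_{id}/n_d`).  Omitting the sibling constraints — as a reading of the
  update that tracks only item `j`'s cells would — leaves indicators
  violated after the draw and breaks the invariance of the augmented
  posterior; with them, a debug mode verifies every indicator after every
  single draw.  Cells whose coefficient is exactly zero contribute no
  constraint (a measure-zero event).

One sweep runs: slice variables → slopes → difficulties → abilities →
testlet effects → the three variance groups (conjugate inverse-gamma).
Every draw is from a truncated normal, a truncated uniform or an
inverse-gamma, so the acceptance probability is one by construction; there
is no proposal tuning.  The y = 0 inequalities are used in the direction
`linear predictor ≤ log((1−φ)/φ)` — the direction forced by
`φ ≤ q ⇔ logit(p) ≤ log((1−φ)/φ)` — which is also the direction the bound
definitions require.

**Numerics.**  Slice thresholds are kept on the logit scale and computed in
log space (`log(u p) − log(q + p(1 − u))` and its mirror), which keeps the
indicator system exactly satisfiable without clamping probabilities.
Likelihood, deviance and predictive-density evaluations floor each cell
likelihood at `1e-12` so logs and harmonic means stay finite.  Truncated
normals use inverse-CDF sampling on the normal-CDF scale with an
exponential-rejection fallback once the whole interval lies beyond six
standard deviations, where the naive inverse CDF underflows.  If a
truncation interval ever inverts by more than floating-point slack the
chain aborts with the iteration and parameter context (this indicates a
corrupted state and is exercised only artificially in tests).

**Initialisation.**  The neutral start is `a = 1`, `b = 0`, `θ = 0`,
`η = 0`, variances 1.  In multi-chain runs, chains after the first jitter
every free parameter by `±2` prior standard deviations (uniformly), giving
the overdispersed starts that the Gelman–Rubin diagnostic assumes;
identification-pinned and user-clamped parameters are never jittered.
Thinning defaults to 1 and burn-in to half the chain.

## Validation strategy

The sampler is checked along three independent routes, all in the test
suite: (i) on a two-person toy with a single free difficulty, 50,000 draws
match a fine-grid numerical integration of the joint density to
Kolmogorov–Smirnov distance < 0.02; (ii) with all location parameters
clamped, the variance draws are i.i.d. from closed-form inverse-gammas and
their means match to within three Monte-Carlo standard errors; (iii) a
debug mode re-audits every slice indicator after every individual draw of a
toy fit.  During development the testlet-effect block was additionally
cross-checked against an independent griddy-Gibbs sampler and a quadrature
marginal-likelihood profile on small problems.

## Model assessment

`dic()` reports the conditional deviance information criterion
`DIC = D̄ + p_D`, `p_D = D̄ − D(Ξ̂)`, where `Ξ̂` collects the posterior
means of **all** sampled quantities — item parameters, abilities and
testlet effects.  The person-level latents are sampled parameters in this
framework, so the conditional form is the coherent choice; it makes `p_D`
large (hundreds) because each person contributes effective parameters.
`cvpd_matrix()` estimates each cell's leave-that-cell-out predictive
density with the harmonic-mean identity
`[mean_m 1/p(y_ij | Ξ^(m))]^{-1}`; the per-draw cell likelihood floor
bounds the inverse terms, so the running mean cannot overflow (this
replaces an explicit log-sum-exp accumulation).  `log_psbf()` is the
difference of summed log predictive densities of two fits of the same data;
reports also quote each model's own sum, the convention used in
model-assessment tables.  Quartiles across study replications use the
default inclusive empirical-quantile convention (R type 7).

## The synthetic-data generator and the study harnesses

`sim_true_params()` emulates the simulation conditions: slopes half-normal
(`|N(0,1)|`, with `a_1 = 1`), difficulties and abilities standard normal,
testlet effects `N(0, σ²_η)` with `σ²_η ∈ {0.25, 1}` as the designs
prescribe; `sim_responses()` draws independent Bernoulli cells.  The
harnesses redraw the truth each replication by default (`redraw_truth =
FALSE` shares one draw) and derive every replication's seed
deterministically from the base seed, so entire studies are reproducible
end to end; a replication whose fit fails numerically is retried on a
deterministic sub-seed and logged.

Desk scales, chosen once for all reported runs: recovery `S = 25`
replications of `N = 500`, `J = 20` (4 testlets of 5) with 5,000-iteration
chains (2,500 burn-in); prior sensitivity `S = 20` (Type II) with the three
prior types compared on shared datasets so the comparison isolates the
prior; model selection `S = 10` with the competing models fitted to the
same data; the convergence check uses the full published scale of four
overdispersed 20,000-iteration chains.  Recovery fits use a single chain:
the estimand is the posterior mean, and auditing a convergence diagnostic
in every replication of a replicated design is impractical.

Bias and MSE follow their elementary definitions over replications;
identification-fixed parameters are excluded from item averages (they are
exactly zero and would dilute them).  Averages are taken over replications
per item first, then over the non-fixed items.

## What passing tests do and do not show — known limitations

The generator reproduces the *stated* truth distributions, and that choice
has consequences worth stating plainly.  A half-normal slope distribution
makes weak items common: about 16% of slopes fall below 0.2 and a third
below 0.42.  The Fisher information for a difficulty is roughly
`N a² E[pq]`, so at `N = 500` such items carry almost no information about
`b_j`; their posteriors are dominated by the (hierarchically shrunk) prior,
their recovery error is bounded away from zero no matter how long the
chains run, their near-flat conditionals slow the mixing that the
Gelman–Rubin diagnostic measures, and testlets whose mean slope is small
produce weakly identified testlet effects whose variance posterior
concentrates near the inverse-gamma spike at zero.  For the same reason the
three fitted models separate only mildly in DIC when the generating
testlet discriminations are small.  Per-item difficulty MSEs that never
exceed ~0.06, model-assessment gaps of hundreds of DIC units, and
convergence diagnostics uniformly below 1.1 would all require truth sets
whose slopes concentrate around 1–1.3 with none weak — and such sets are
vanishingly unlikely under the half-normal law.  The package reports what
the stated generating process actually yields rather than calibrating the
generator to flattering truth sets; `scripts/acceptance.R` recomputes those
honest values.

Further limitations: responses must be complete (no missing-data model);
testlet membership is single and fixed; the models are dichotomous only;
and the harmonic-mean predictive-density estimator, while the standard
choice for this design, is known to have heavy-tailed weights — the cell
likelihood floor bounds but does not eliminate that variance.

## Tunable parameters at a glance

| Parameter | Default | Meaning |
|---|---|---|
| `iter`, `burnin`, `thin` | 20000 / 10000 / 1 | chain length (sweeps), discarded prefix, storage stride |
| `chains` | 1 | independent chains; ≥ 2 enables the PSRF diagnostic |
| `sigma2_a`, `sigma2_b` | 100 | initial (or fixed) prior variances of the item parameters |
| `v`, `tau` | 0.001 | inverse-gamma hyperparameters of all variance parameters |
| `sigma2_eta` (generator) | 0.25 | true testlet-effect variance per testlet |
| `level` | 0.95 | HPDI coverage in summaries |
| PSRF threshold | 1.1 | working convergence rule, `max Rhat < 1.1` |
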