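---
title: "Twin generative models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Twin generative models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinmodels)
```

## What the package computes

`twinmodels` implements three pairs of generative models for longitudinal
data in which a *heterogeneity* model (observations conditionally i.i.d.
given a fixed latent unit trait) and a *reinforcement* model (observations
driven by the unit's own past observations, no latent variable) have
identical joint distributions over entire trajectories. Each pair comes
with an exact simulator and an exact log-likelihood per side, computed by
deliberately different routes, so that their agreement is a meaningful
numerical verification rather than a tautology. Around the pairs sit a
model-equivalence suite, hybrid mixtures, and a permutation runs test of
exchangeability.

## The binary pair

The urn starts with one black and one red ball; each draw is returned with
an extra ball of its colour. As a reinforcement rule: `Y_n = 1` iff
`X_n < (1 + Σ_{k<n} Y_k)/(n + 1)` with `X_n` i.i.d. uniform. The twin
draws `p ~ U[0,1]` once per unit, then i.i.d. Bernoulli(`p`).

* `polya_log_prob()` multiplies the sequential conditional probabilities —
  it never uses the closed form `k!(n−k)!/(n+1)!`.
* `mixture_log_prob()` evaluates `log B(k+1, n−k+1)` via `lbeta()`.

Both are computed in log space throughout; at length 200 the sequence
probability is of order `10^-61`, far below where a raw product loses
precision. A generalized initial composition (`n_black`, `n_red` balls,
twin prior `Beta(n_black, n_red)`) is available but defaults to the
`(1, 1)` case, which is the one the equivalence statement is about.

A consequence worth noting because the test suite relies on it: urn draws
are exchangeable, so conditional on a sequence's counts every ordering is
equally likely. The runs test below therefore has *no power* against urn
data — reinforcement acting through the cumulative average leaves no
streak signature a within-unit shuffle could detect. The suite asserts
this calibration property empirically rather than a (nonexistent) power
target.

## The Gaussian pair

Heterogeneity side (`q_simulate`): `Y_n = T + X_n`, `T ~ N(μ_T, σ_T²)`
drawn once per unit, `X_n ~ N(0, σ_X²)` i.i.d. All quantities are on the
log scale of the underlying outcome (e.g. log citation counts); converting
raw positive counts happens only in the I/O layer (`log_transform`), which
refuses zeros rather than silently adding a pseudo-count, because a +1
would change the law being tested.

Reinforcement side (`q_twin_simulate`): given history of length `n`,

\[ Y'_{n+1} \sim N\!\left(\frac{c\,a + \sum_k Y'_k}{n + c},\;
   b\left(1 + \frac{1}{n + c}\right)\right), \]

with the first observation drawn from the `n = 0` boundary `N(a, b + b/c)`
directly — no special-casing of an empty-history mean. The map
`a = μ_T`, `b = σ_X²`, `c = σ_X²/σ_T²` is an exact bijection
(`map_q_to_twin` / `map_twin_to_q`).

Interpretation of the twin parameters: `a` is the long-run mean, `b` the
limiting innovation variance, and `c` acts as a number of
pseudo-observations anchoring the mean at `a` — exactly the prior weight
in the conjugate-normal posterior predictive of the heterogeneity side.
That identity (checked in the tests against an independently coded
conjugate update) is the constructive reason the twins coincide: under the
latent-trait model every past observation is equally informative about the
trait, so the predictive mean weights all past values equally and the
predictive variance falls at the specific rate `1/(n + c)`.

Density evaluation: `q_log_pdf()` is a multivariate normal with
compound-symmetric covariance `σ_T² J + σ_X² I`, evaluated via Cholesky;
`q_twin_log_pdf()` sums the chain of conditional normal log-densities.
No shared code between the two routes.

The attitude-panel special case (`sdm_twin_step`) fixes `a = 0`,
`b = c = 1`, giving `y'_n = ((n−1)/n)·ȳ'_{n−1} + √(1 + 1/n)·v_n`. The
noise coefficient is `sqrt(1 + 1/n)`: this is forced by consistency with
the general conditional variance at `b = c = 1` (history length `n − 1`
gives `1 + 1/n`), and the package verifies the step function against the
general recursion exactly for shared innovations. Innovations are
caller-supplied precisely so that this check is deterministic.

## The event-history pair

Heterogeneity side (`snm_simulate`): frailty
`κ ~ Gamma(shape = α, scale = 1/α)` once per unit — mean 1, variance
`1/α`, the standard identifiable convention for a multiplicative frailty
(under a rate-`1/α` reading the mean would be `α²` and would not be
separable from the scale of the `π_j`) — then conditionally a pure-birth
process with rates `κ·π_j`. The default state-rate family is `π_0 = 0.25`,
`π_j = 0.25·j^{0.5}`: sublinear reinforcement on the event count. Any
positive rule `pi_fun(j)` may be supplied.

Reinforcement side: conditional intensity

\[ \lambda_{m+1}(t \mid t_1..t_m) =
   \frac{\pi_m\,(m+\alpha)}{\pi_m t - \sum_{j=1}^m (\pi_j - \pi_{j-1})\,t_j
   + \alpha}. \]

The denominator telescopes to
`A_m + π_m (t − t_m)` with `A_m = α + Σ_{j<m} π_j (t_{j+1} − t_j)`, which
is how the simulator tracks it; it is provably positive along any history
the process itself generates, and the code asserts this invariant rather
than clamping.

Simulation is by time change: the integrated intensity over
`(t_k, t_k + τ)` is `(k+α)·log(1 + π_k τ / A_k)`, whose inverse is
`s_{k+1}(z) = A_k (e^{z/(k+α)} − 1)/π_k`; mapping i.i.d. unit-rate
exponentials through `s` produces the waiting times. Two independent
validations are built in: numeric quadrature of the intensity confirms
`Λ(s(z)) = z` to near machine precision, and an Ogata thinning sampler
(`contact_twin_first_event_thinning`, valid because the intensity decays
between events) reproduces the first-event-time distribution.

Likelihoods: the frailty side integrates `κ` out analytically against the
Gamma density, giving
`Σ log π_j + α log α − log Γ(α) + log Γ(m+α) − (m+α) log D` with
`D = α + Σ π_j τ_{j+1} + π_m (T − t_m)`; the form was re-derived by hand
and is additionally checked against adaptive quadrature over `κ`
(`snm_log_lik_quadrature`, relative tolerance `1e-10`, integrand scaled at
its mode to avoid underflow). The twin side uses the generic point-process
likelihood `Σ log λ(t_i) − ∫_0^T λ`, with the integral in closed form per
inter-event interval, every term evaluated through the history-weighted
denominator — not through the `A_k` recursion — keeping the routes
independent. Right-censoring at the horizon is always included; event
trajectories carry their horizon explicitly, and tied event times are
rejected (they have probability zero under either model and usually
indicate aggregated data).

## Hybrid mixtures and the equivalence suite

`mixture_model(A, B, q)` draws each unit's whole trajectory from `A` with
probability `q`, else `B`, and scores by log-sum-exp of the two component
log-likelihoods. Mixing a model with its twin at any `q` leaves the law
unchanged, which the suite checks.

The equivalence suite has three layers, in decreasing strictness:

1. `likelihood_equality_check()` — pointwise equality of log-likelihoods on
   supplied trajectories (exact; default tolerance `1e-8` relative).
2. `marginal_compare()` — per-index two-sample KS (real) or chi-square
   (binary) on simulated panels, Holm-adjusted at family level 1%.
3. `cross_moment_compare()` — means and all cross-time covariances within
   3 combined Monte-Carlo standard errors (entry-wise SEs from the spread
   of the per-unit products).

Each stochastic check records its seed and sample sizes in the report's
metadata so failures are reproducible, and the suite's tests include
deliberate perturbations (`c` off by 10%, `b` doubled, shifted `α`) to
guard against vacuously passing checks.

## The runs test

`permutation_runs_test()` follows the pooled-runs permutation design:
dichotomize each unit's record at its own median, drop records with fewer
than `min_len = 3` retained observations (below three, a reshuffle cannot
change the run count), sum runs across records, and compare with `n_perm`
datasets in which each record is independently reshuffled. With `x` the
proportion of permuted sums strictly below the observed sum, the two-sided
p-value is `2·min{x, 1−x}`; when `x` is 0 or 1 the result is reported as
the bound `p ≤ 2/n_perm` with `p_is_bound` set, since the permutation
resolution is exhausted. An add-one-smoothed `x` is available but
non-default.

Values exactly at the median are dropped by default — the only policy that
uses strictly the two categories "above" and "below"; `assign_low` /
`assign_high` are available as alternatives, and the length filter is
applied after dropping. The tie policy is a genuine judgment call, not a
settled convention, which is why it is a documented enum rather than a
hard-coded rule.

Implementation: permutations are vectorized — each unit's shuffle keys for
all replicates come from that unit's own RNG substream, a chunk of
replicates is shuffled with a single grouped `order()` call, and runs are
counted from adjacent-difference indicators. `chunk_size` trades memory
for nothing else; results are bit-identical across chunkings (tested).

The companion diagnostic `conditional_variance_profile()` estimates, per
history length `n`, the across-unit variance of the one-step-ahead
residual against the predicted `b·(1 + 1/(n + c))` decay — the specific
quantitative prediction that both twins share and that flat-variance data
contradict.

## Randomness contract

All simulators draw through a `twin_rng` handle: a L'Ecuyer-CMRG seed plus
deterministic per-unit substreams derived with `parallel::nextRNGStream()`.
Unit `i`'s trajectory depends only on the seed and `i` — never on how many
units are simulated or in what order (tested by extending a panel and
comparing prefixes). No global RNG state is consumed; the global seed is
saved and restored around every draw. For the permutation test, one
substream per unit supplies that unit's keys for all replicates; a
per-(unit, replicate) substream grid would be statistically equivalent and
three orders of magnitude more stream derivations.

## Reference scenarios and what they do (not) emulate

`generate_fixtures()` pins the package's reference settings: Gaussian
careers at `μ_T = 0, σ_T² = 0.2, σ_X² = 1` (30 units × 10 observations),
the attitude case at unit variances (10 units; 20 waves — the span is the
package's choice, representative of a long-running household panel),
binary urn/mixture panels of 30 units × 20 draws for runs-test
calibration, and the contact process at `α = 1, π_0 = 0.25,
π_j = 0.25·j^{0.5}`, horizon 10, 30 units.

These synthetic panels are clean by construction: no missingness beyond
raggedness, no measurement error beyond the models' own noise, no
cross-unit dependence, stationary conditions throughout. Passing tests on
them demonstrates the mathematical twin structure and the calibration of
the test machinery — it does not certify behaviour on real panels, where
attrition, discreteness (small count scales produce heavy median ties),
and nonstationary environments all matter. In particular the runs test's
power against *non*-exchangeable alternatives depends entirely on the
alternative; the package measures its size, not a universal power.

## Numerical choices

* All probabilities in log space via `lgamma`/`lbeta`; no raw products.
* MVN density via Cholesky (`O(n³)`, exact up to rounding); trajectories
  of length 50 are far from any conditioning trouble since the covariance
  has eigenvalues `≥ σ_X²`.
* Quadrature tolerances: `1e-10` relative for the frailty integral and the
  compensator checks, an order tighter than the `1e-6`/`1e-8` agreement
  asserted on top of them.
* Test problem sizes: `10^5` units for moment checks (3-SE bands),
  `2·10^4` draws for the KS comparison at the 1% level, 500 panels ×
  1000 permutations for the size experiment — sizes at which the bands
  are decisive for the effects the perturbation tests inject.
* Degenerate inputs: empty histories use the model's unconditional law;
  empty event trajectories score the pure survival term; constant panels
  yield the bounded p-value path rather than a division by zero.

## Command-line interface

The CLI (`inst/cli/twinmodels.R`, logic in `cli_main()`) exposes
`simulate`, `loglik`, `map-params`, `compare`, `runs-test` and `fixtures`
over long-format CSV, with exit codes 2/1/0 for usage/data/success and all
parameters and seeds logged to stderr. Configuration is by flags only;
every scenario and test option is a flag, so a logged command line is a
complete run record. Long (tidy) CSV is the only panel format — ragged and
multi-item panels do not fit a wide layout without loss.

## Known limitations

* No fitting of model parameters to data (by design: the twins make the
  point that fits cannot separate the mechanisms); only
  method-of-moments-style comparisons used by the test machinery.
* The existence theorems behind general twin constructions are
  non-constructive and have no executable counterpart here; the package
  implements the three concrete pairs and the hybrid mixture.
* Multi-colour or innovation urn schemes and network-based preferential
  attachment are out of scope.
* `marginal_compare()` requires equal unit counts and the cross-moment
  check rectangular panels; ragged real data need pre-alignment.
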