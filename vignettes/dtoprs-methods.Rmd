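---
title: "Methods: the DTO + PRS hybrid, wrapper selection and RBFN tuning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the DTO + PRS hybrid, wrapper selection and RBFN tuning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtoprs)
```

This vignette is the package's own account of its models and the design
choices behind them: what the algorithms compute, which parameters matter
and why their defaults are what they are, what the synthetic generator
does and does not emulate, and where the genuinely open design decisions
were settled.

## The optimizer contract

Every optimizer minimizes a scalar objective over a box (default the unit
box), with population size `n` (default 30), an iteration budget (default
100), and a single integer seed controlling all randomness. Positions are
clamped to the bounds after every update — the simplest rule consistent
with a fixed unit-box domain; reflection or wrapping would change no
contract but add a parameter nobody sets. Velocities start at zero (a
uniform random velocity would overshoot immediately in a unit box) and are
clamped to the per-dimension domain width to prevent divergence. An agent
whose objective comes back non-finite is assigned `+Inf` fitness with a
warning rather than aborting the run; a stochastic search should survive a
pathological corner of the space. The best-ever solution is tracked
separately from the population, so the reported convergence trace is
non-increasing by construction, and two runs with the same seed and
configuration are bit-identical.

## Dipper-throated optimization

Each agent flips a fair coin (a uniform draw `R`, threshold 0.5) between
two moves. The *swimming* move

$$x' = x_\mathrm{best} - C_1\,\lvert C_2\,x_\mathrm{best} - x\rvert,
\qquad C_1 = 2cr_1 - c,\; C_2 = 2r_1,\;
c = 2\bigl(1 - (t/T_\mathrm{max})^2\bigr)$$

is a folded attraction toward the best-known position whose step length
anneals quadratically: `c` falls from 2 at the start to 0 at the end, so
late iterations collapse onto the incumbent. The *flying* move is the
classical velocity rule with inertia `C3` and accelerations `C4`, `C5`
toward the population best and the best-ever position. The defaults
`C3 = 0.7`, `C4 = C5 = 2.0` mirror the inertia/acceleration roles these
constants play in standard swarm practice; all three are exposed. Two
readings of "best" are possible in the swimming equation — per-agent
personal best or population best; the population best is implemented (the
flying move already distinguishes the population best from the incumbent,
and a per-agent memory would add state the update equations never
reference).

## Polar rose search and the hybrid

The rose (rhodonea) curve $r(\theta) = a\cos(k\theta)$ traces petals
through the origin: `k` petals for odd integer `k`, `2k` for even. PRS
uses it as a structured perturbation: take a coordinate pair of a
solution, convert to polar form, replace the radius by
$r' = a\cos(k\theta + \Delta\theta)$, convert back. Because the petals
sweep the full angular domain, repeated perturbations sample
geometrically diverse directions rather than isotropic noise. One
geometric fact worth recording: a point whose polar radius is negative is
represented by `atan2` at the antipodal angle, so the "already on the
curve, unchanged under zero offset" identity holds on the non-negative
part of each petal for any `k`, and globally for odd `k` (where
$\cos(k(\theta+\pi)) = -\cos(k\theta)$ cancels the flip). The perturbation
itself is well-defined everywhere.

The hybrid interleaves the two: every iteration runs a DTO step, then a
PRS phase fires if either trigger says so:

- **entropy trigger** — population entropy, defined here as the mean over
  dimensions of the per-dimension population standard deviation normalized
  by that dimension's range (0 iff all agents coincide; 0.5 for two agents
  at opposite corners), drops below `entropy_threshold` (default 0.05,
  i.e. the population has collapsed to ~5% of the box);
- **annealed schedule** — a Bernoulli draw with probability
  `0.3·(1 − t/T)`, front-loading diversification when it is cheap.

Either mechanism can be disabled (`threshold = 0`, probability 0), and a
fully disabled PRS phase consumes no random numbers, so the hybrid then
reproduces plain DTO bit for bit under the same seed — a property the
tests assert.

In a PRS phase the top `ceiling(0.2·n)` agents by fitness are perturbed on
a deterministically cycling coordinate plane ((1,2), (2,3), ..., restart),
which guarantees coverage and reproducibility where a random plane would
need another draw. The amplitude anneals linearly from half the mean
dimension width to 5% of it (wide exploration early, local nudges late);
`k` cycles through {2, 3, 5, 7} across invocations to avoid pattern
saturation; the rotational offset advances as `Δθ = 2πt/T` (one full
rotation per run). Perturbed agents replace their originals only when not
worse — greedy acceptance is what preserves the monotone-trace contract;
unconditional replacement would occasionally discard the population best.

## Binary encoding and wrapper feature selection

A continuous position in the unit box becomes a feature mask through the
steep logistic $S(x) = 1/(1 + e^{-10(x - 0.5)})$ and thresholding at 0.5
(a tie at exactly 0.5 selects the feature — any fixed rule works, but a
rule there must be, for determinism). An all-zero mask never reaches the
learner: the bit with the largest underlying position value is switched
on. The wrapper fitness is

$$f = \alpha\,\mathrm{error}_{CV} + (1-\alpha)\,\frac{\lvert \mathrm{mask}\rvert}{d},
\qquad \alpha = 0.99,$$

the dominant convention in wrapper selection: classification error is
primary and the subset-size term breaks ties toward compact subsets.
Cross-validation is stratified 5-fold, frozen at objective construction,
so the fitness is a deterministic function of the mask; results are cached
per mask (at most `2^d − 1` distinct masks), which changes no value but
avoids refitting when the search revisits a subset.

The wrapper's internal learner is deliberately a *fast* RBFN
configuration: k-means centers capped at `min(30, n)`, `γ = 5`,
`λ = 0.001`. Two notes on that choice. First, the wrapper needs thousands
of fits, so the learner must be cheap. Second, on min-max normalized
features the full-model default width (`γ = 1`, i.e. σ ≈ 0.71 on a unit
box) over-smooths local class structure; σ ≈ 0.32 resolves it, which
materially sharpens the contrast between informative and noise features in
the CV error — exactly the signal the wrapper selects on. The learner is
pluggable for users who want a different inner model.

## The RBFN classifier

Hidden units are Gaussian kernels $\phi_i(x) = e^{-\gamma\|x - c_i\|^2}$
(the width parameterization is $\sigma^2 = 1/(2\gamma)$, so `gamma = 1`
means σ ≈ 0.71); the output $f(x) = \sum_i w_i\phi_i(x)$ is thresholded at
0.5 against 0/1 targets. A single shared `γ` is used rather than
per-neuron widths: the tuning surface exposes one width parameter, and
per-neuron spreads would make the closed-form fit a heuristic two-stage
estimate. Output weights solve the ridge problem
$\min_w \|\Phi w - y\|^2 + \lambda\|w\|^2$ in closed form; with
`λ = 0` the minimum-norm least-squares solution is returned (warning on
rank deficiency). There is no learning rate anywhere — a closed-form fit
has no gradient loop, so a configured learning rate is accepted in spirit
but has no role, and none is invented.

Defaults: 100 centers (capped at the number of training samples, and for
k-means at the number of distinct rows), `γ = 1`, `λ = 0.001`, k-means
centers. The tuning encoder maps the unit cube log-uniformly onto
centers ∈ [10, 500] (rounded), γ ∈ [0.01, 10], λ ∈ [1e-4, 1] — log-uniform
because all three ranges span decades and multiplicative steps are the
natural resolution. The tuner (`tune_rbfn`) warm-starts its population
with the default configuration's encoding, standard tuner practice that
also guarantees the tuned CV error never exceeds the default's under the
same folds.

## Baseline optimizers

The six comparators follow their canonical published update rules with the
common configuration (population 30, 100 iterations, unit box); only
qualitative descriptions plus a constants table were available, so where
the table's vocabulary conflicts with the canonical method, the canonical
roles win and the conflict is documented here:

- **WOA**: the table assigns "linearly from 2 to 0" to the spiral
  parameter `b`; in the canonical method `b` is a constant spiral pitch
  while the encircling coefficient `a` anneals 2 → 0. Implemented
  canonically (`a`: 2 → 0, `b = 1`).
- **SBO**: one source line says "Salp Swarm", the prose describes the
  Satin Bowerbird Optimizer; Satin Bowerbird is implemented (step size
  0.94, mutation probability 0.05, mutation spread 2% of the domain
  width).
- **FA**: the configured "wormhole existence probability" is
  multiverse-optimizer vocabulary with no counterpart in canonical FA; it
  is mapped to an annealed random-restart chance applied to the worst
  firefly only (elitism intact). Step size 0.94 as configured, decaying
  geometrically.
- **BA**: the bat population is the common 30 for budget fairness;
  loudness/pulse-rate constants `a = c = 0.9`, frequency range [0, 100],
  local walks around the incumbent scaled by mean loudness.

All six pass the same contract battery as the hybrid, and each beats
budget-matched uniform random search on the unit-box sphere in at least
8 of 10 seeds.

## Synthetic data generator

The generator emulates the structure of a physicochemical monitoring
table: right-skewed continuous features (alternating log-normal and gamma
draws) at scales spanning decades; a binary label driven *only* by a
planted informative subset, through a radial rule (membership of the
standardized informative vector in a centered ball — non-separable by any
single-feature threshold, the regime RBF networks exist for) or a
quadratic-logistic rule; redundant features as noisy linear mixtures of
informative ones; pure-noise decoys; completely-at-random missingness
(default rate 0.1, in the range typical of sensor tables); label frequency
set by quantile thresholding (default 0.4 positives, matching the
imbalance typical of potability-style labels). Defaults: 3276 samples, 3
informative + 2 redundant + 3 noise features.

What it does **not** emulate: correlated missingness (sensor dropouts
cluster in time), measurement drift, outliers and heavy-tailed error,
label noise from disagreeing assays (available via `label_noise` but off
by default), and inter-feature correlation beyond the planted redundant
mixtures. Passing tests on this generator therefore demonstrate that the
machinery recovers planted structure under clean conditions — not that it
would survive every pathology of field data.

## Numerical choices and degenerate inputs

- Wilcoxon signed-rank: zero differences are dropped (the standard
  convention; no observable alternative in the reference tables), ties get
  midranks, and for `n ≤ 25` the two-tailed p comes from the exact null
  distribution of the positive-rank sum over all `2^n` sign assignments,
  computed by integer convolution on the doubled-rank grid (identical to
  full enumeration, without materializing `2^25` patterns); beyond 25, a
  tie-corrected normal approximation. Reports print p to 3 decimals with a
  `<0.0001` floor.
- ANOVA: computed through the base linear-model machinery; a within-group
  sum of squares at numerical zero leaves F undefined (`NA`), never
  infinite.
- Classification metrics with a zero denominator are `NA` ("undefined"),
  never silently 0.
- Split sizes follow the floor rule (test = `⌊0.2·n⌋`, so 3276 → 2621/655)
  with largest-remainder allocation across classes; an epsilon guard
  absorbs the binary-floating-point representation of `1 − 0.8`.
- Imputation chooses median over mean at |skewness| > 1 (classic moment
  estimator), computed on training data only and reused on test data;
  min-max normalization likewise, and test values outside the training
  range are preserved, not clipped — clipping would hide covariate shift.
- Empty feature masks are repaired, never scored; constant columns
  normalize to 0 with a warning.

## Problem sizes in the tests

The test and acceptance workloads are scaled for a desk-class single CPU:
wrapper selection runs use 300-sample tables with 8 features, populations
of 20 and 40 iterations over 10 seeds; tuning comparisons use 250-sample
tables, populations of 10, 10–15 iterations, 5 paired seeds; benchmark
comparisons use the 8-dimensional unit-box sphere and Rastrigin functions
at the full common budget (30 × 100). These sizes reproduce the
qualitative orderings (hybrid ≥ plain DTO, tuned ≥ default, planted
features recovered, noise rejected) without asserting any external
dataset's headline numbers.

## Known limitations

- Binary classification only; the multi-class extension would replace the
  ridge output layer with one-vs-rest columns but is out of scope.
- Box constraints only; no general constraint handling.
- The baselines are one canonical form each, not surveys of their variant
  literature; cross-method comparisons on a given problem are indicative.
- Exact Wilcoxon enumeration is capped at n = 25 by design; the normal
  approximation beyond is standard but approximate.
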