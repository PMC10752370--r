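---
title: "Steering synthetic community composition: models, designs, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steering synthetic community composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commsteer)
```

## The problem

A defined gut bacterial community cultured in batch tends to collapse toward
a few dominant members. This package implements a model-guided workflow for
holding such a community diverse — and, more generally, for steering it
toward any target composition — using only two experimentally cheap control
knobs: the composition of the medium and the per-species inoculation
densities. A third layer uses an inferred interaction network to design
subset communities whose composition is either stable or deliberately
variable across serial passages.

Everything here runs offline against a synthetic ground truth; the package
never requires the original measured datasets. What the tests demonstrate is
therefore *methodological* correctness (the pipeline recovers known truths
from data shaped like the study's), not a reproduction of any particular
laboratory's measured numbers.

## Diversity objectives

Community composition lives on the unit simplex; diversity is Shannon
entropy in natural-log units, $-\sum_i x_i \ln x_i$, maximal at $\ln S$ for
an even $S$-species community (2.30 for ten species). The inverse Simpson
index $1/\sum x_i^2$ is provided as a cross-check. Fractions below $10^{-12}$
are treated as exact zeros ($0\ln 0 := 0$ by continuity). All-zero abundance
vectors mark failed cultures and travel as flagged sentinels rather than
being silently dropped, so replicate-exclusion decisions remain auditable.

The coefficient of variation across passages uses the sample ($n-1$)
standard deviation: the worked check is that a species at relative
abundances $(0.2, 0.1, 0.1, 0.1)$ across four passages has CV exactly 40%
(the population convention would give 34.6%).

## Growth kinetics

Monoculture OD600 series are "blanked" by shifting each curve so its first
reading equals the known inoculation density — a pure shift that preserves
all time differences. Replicates that failed to grow are detected by
z-scoring a per-replicate summary (mean OD over time by default; the
endpoint reading is available as an alternative, since either reading of the
rule is defensible) across replicates with the population SD, flagging only
the low side at $|z| > 1.5$ and never more than one replicate per condition.
Because z-scores are scale-free, a magnitude guard (`min_drop`, default 0.5)
additionally requires a flagged replicate to sit below half the condition
median; without it, a set of essentially identical replicates would flag
pure plate-reader noise.

Logistic fits minimize the SSE between the numerically integrated ODE
(started at the known inoculum) and the series truncated at 30 h, by bounded
quasi-Newton search from a heuristic start (growth rate from the steepest
log-OD slope, capacity from the smoothed maximum) with a deterministic
5-point multi-start. Default bounds are $\mu \in [0, 10]\,/\mathrm{h}$ and
$K \in [10^{-4}, 10]$ OD600. Dilution series are fit jointly: one $(\mu, K)$
for all curves of a species plus one initial condition per curve, with
readings below the 0.05 OD600 detection limit masked out of the residual
(they carry no growth signal, only reader noise); a log–log linear
regression then maps experimental to fitted initial densities.

## Design of experiments

Three screening families generate coded $\{-1, 0, +1\}$ matrices:
resolution-IV half fractions ($2^{k-1}$, e.g. 9 runs for four media factors
with the center point), definitive screening designs (conference-matrix
fold-over `rbind(C, -C, 0)`, $2m+1$ runs, three levels per factor; odd
factor counts use the next even construction with one column dropped), and
the 12-run Plackett–Burman array. A full factorial is also available for
situations needing alias-free estimation. The conference matrices
(orders 4–14) are Paley/skew constructions stored as constants; the test
suite re-verifies their defining property $C^\top C = (n-1)I$, main-effect
orthogonality, and the orthogonality of DSD main effects to quadratics.

Coded levels scale to absolute values either arithmetically or
geometrically; inoculum factors use the log scale, with high/low levels
symmetric about the center (high/center = center/low). Physical inoculation
plans pick, for each species and target density, the ten-fold dilution of
the preculture giving the smallest aspiration volume strictly above 7 µL
(smaller volumes pipette inaccurately; larger ones accumulate).

## Response-surface ensembles

Screening datasets here are tiny (9–21 conditions), so regression uses
elastic net with *nested* leave-one-out cross validation: for each outer
fold, an inner LOO grid search (mixing $\alpha \in \{0.1,\dots,1\}$, penalty
on a 50-point log grid over $10^{-6}$–$10^{2}$) picks hyperparameters
without ever seeing the outer held-out run; the ensemble keeps one
coefficient vector per fold and predicts by averaging. Replicates must be
averaged per condition first, otherwise copies of a condition leak across
folds. Negative predicted growth responses are clipped at zero before any
diversity computation — abundances are physical quantities and the
normalized-capacity objective needs a simplex.

Two bounded multi-start optimizers sit on top: media profiles maximizing the
monoculture diversity of predicted capacities, and inoculum profiles
minimizing the squared error to a target endpoint composition (the
diversity-maximizing target is the even one, mean community OD divided by
the species count). The inoculum search is confined to the observed design
ranges so the polynomial models never extrapolate.

A note on identifiability: a 9-run screen cannot pin down 18 polynomial
coefficients, and in a half fraction each main effect is aliased with a
three-way term. Recovery-style validation of the ensemble machinery
therefore uses an alias-free full factorial and a penalty grid at the
no-penalty floor, where least squares is the closed-form oracle; on the real
9-run screens the ensemble is a regularized predictor, not an identified
model, and is validated by out-of-fold correlation instead.

## The constrained logistic community model

The CSLE couples otherwise independent logistic species through one shared
brake, $\bigl(1 - \sum_j x_j / K_{comm}\bigr)$. Its useful property: when
$\sum_i K_i > K_{comm}$ the endpoint is a race frozen at total biomass
$K_{comm}$, so the endpoint *composition* responds continuously to the
inoculum — the handle the inoculum optimization pulls. Two
parameterizations are kept, as either may be preferred: per-species logistic
fits plus an empirically measured community endpoint for $K_{comm}$, or a
joint bounded L1-penalized fit of all $2S+1$ parameters to the monoculture
curves (bounds $\mu \le 10$, $K \le 10$, $K_{comm} \le 5$, all $\ge 0$).

Steady state is operationalized as integration until
$\max_i |dx_i/dt| < 10^{-9}$ or 200 h, whichever comes first; conservation
tests integrate deeper (tolerance $10^{-13}$, up to 3000 h) because
convergence onto the $\sum x = K_{comm}$ manifold slows as $K_{comm}$
approaches $\sum K$. The inoculum optimization maximizes steady-state
Shannon diversity subject to a total cap (default 0.02 OD600), a cap on the
non-pinned species (default 0.01), optional pinned species, and a
$10^{-7}$ OD600 floor standing in for densities too low to establish.
Although densities span orders of magnitude, the search runs in *raw*
density space — the caps are linear there and are enforced by exact
projection — with multi-starts drawn log-uniformly so small densities are
still explored; a log-space parameterization would make the caps nonlinear.

Design levels for the first inoculum screen are calibrated by the
steady-state fold-change rule: the high level of a species is the initial
density whose predicted steady-state abundance is 3.3-fold its center-point
value (solved by a bracketed root search in log density, verified by forward
simulation), and the low level mirrors it in log space. When the fold is
unreachable within the search bound the bound is returned with a warning —
this happens whenever a species' center-point endpoint is already close to
its ceiling, and is information, not failure.

## Generalized Lotka–Volterra inference

The gLV objective is the SSE between integrated and observed abundances over
a heterogeneous training set — dense monoculture time series, designed
community endpoints observed at their recorded times (28 h), and passage
observations chained as separate initial-value problems from the previous
endpoint divided by 25 — plus an L1 penalty on the inter-species terms
only (self-interactions and growth rates are monoculture-anchored and start
at the monoculture estimates; inter-species terms start at zero, the value
the penalty shrinks toward). Relative-abundance observations are converted
to absolute scale with their total OD before entering the loss; validation
statistics are computed on relative abundances, making them invariant to
per-condition rescaling.

Numerical choices that mattered in practice:

* **Integrators.** All dynamic models use compiled fixed-step RK4
  (`dt` 0.05 h for simulation, 0.15 h inside inference objectives). The
  systems are non-stiff on the biological parameter ranges; accuracy is
  property-tested against the logistic closed form and a stiff reference
  integrator. Inference needs on the order of $10^4$–$10^5$ objective
  evaluations, which rules out per-call overhead.
* **Divergence handling.** Trial parameter sets can send trajectories to
  infinity. States saturate at 10 (OD600-equivalent) instead of aborting, so
  the objective stays finite and decreasing away from divergent regions
  rather than presenting the optimizer with a cliff.
* **Smoothed penalty.** The exact L1 kink at zero makes quasi-Newton line
  searches fail; the penalty is $\sqrt{a^2 + \varepsilon^2} - \varepsilon$
  with $\varepsilon = 10^{-4}$, indistinguishable from $|a|$ beyond an
  $\varepsilon$-neighborhood of zero.
* **Staged search.** Monoculture data carry no information about
  inter-species terms (absent species never enter the dynamics), so each
  start first optimizes the off-diagonal terms with kinetics fixed — a much
  better-conditioned subproblem — then polishes all parameters jointly.
  Bounded PORT (`nlminb`) with a forward-difference gradient computed in
  compiled code; three jittered starts by default.
* **Identifiability.** With designed endpoints confined to a narrow density
  range (e.g. $10^{-4}$–$10^{-2}$ OD600), the off-diagonals sit in a flat
  valley: near-zero residual with visibly wrong parameters. Recovery tests
  therefore use exploration-scale designs spanning $10^{-6}$–$10^{-2}$,
  matching the wide first-cycle design ranges; this is a property of the
  data, not of the optimizer.

Penalty selection scans 10 log-spaced values over $10^{-8}$–$10$, then 13
values over a decade either side of the best, scoring 5-fold out-of-fold
Pearson correlation on relative abundances (monocultures never leave the
training side, and a 10% test split is available). On well-sampled synthetic
data the scan is flat over a wide penalty range; on a 25% subsample it is
peaked — the weak-penalty edge visibly overfits — which is the qualitative
diagnostic the acceptance test checks. Bootstrap uncertainty resamples
community conditions with replacement (100 by default), tolerating up to 10%
fit failures; the shuffled-interaction null permutes the off-diagonal terms
uniformly and keeps only derangements, so roughly $1/e \approx 37\%$ of
shuffles survive.

## Design–test–learn orchestration

`run_dtl()` closes the loop against a synthetic world standing in for the
wet lab. Cycle 1 centers on the CSLE optimum with 3.3-fold calibrated
levels (definitive screening design); learning fits one endpoint-abundance
ensemble per species on all accumulated replicate-averaged conditions minus
a held-out set (default 5 conditions) and declares a species' model
predictive at out-of-fold Pearson $r \ge 0.7$ (exposed as configuration).
Cycle 2 reuses the previous fold magnitudes but caps the total high/low
range at two orders of magnitude; cycle 3 switches to Plackett–Burman at
two-fold levels — exploration first, then a robustness check around a
trusted center. Predictive species get model-guided center updates toward
the even-composition target; the rest are frameshifted to the previous
design extrema (overgrown species to the previous low, undergrown to the
previous high, with under/overgrowth at mean relative abundance
0.025/0.25 — the lower threshold is the study-scale one, the upper is this
package's default since dominance calls were qualitative). One species may
be pinned at a fixed density throughout.

Model-guided center moves carry hysteresis: the optimized center replaces
the current one only when the refit models predict at least a 10% relative
reduction in the distance to the target (`center_move_min_gain`).
Re-centering a design is an experimental cost; once the loop has converged
onto a plateau, chasing marginal predicted gains just lets model error walk
the center around. The loop's improvement readout is the median noise-free
endpoint diversity across each cycle's design conditions — the cycle-level
comparison a campaign would plot — reported alongside the center-point
diversity itself.

## Temporal-variability community design

For each candidate subset (all $\binom{10}{k}$ for $k = 2..9$ by default,
1012 subsets), the present species' initial densities (bounded by 0 and
0.01 OD600; absent species clamped at zero) are optimized against four
simulated passages at 25-fold dilution and 28 h per passage. The low-mode
objective $\sum_{p=1}^{4} \mathrm{Sd}_p / \sum_{p=2}^{4} \mathrm{Eu}_p$
(per-passage Shannon diversity over summed between-passage Euclidean
displacement) rewards diverse *and* stationary series; the first-passage
diversity is included in the numerator while displacements start at the
second passage, matching the natural index ranges. A floor of $10^{-6}$ on
the displacement sum keeps perfectly stationary series from producing
unbounded scores (they rank first regardless). High-variability designs
maximize the product of the same two terms. Endpoint compositions within a
per-species tolerance of 0.05 are collapsed as duplicates, and a greedy
cover over the ranked list picks a minimal validation set containing every
species at least twice. Measured (or simulated-measured) designs are scored
by per-species CV across passages and compared between groups with a
two-sided Mann–Whitney test.

## The synthetic world

`make_world()` draws growth rates uniformly on 0.2–1.0 /h and capacities on
0.3–1.2 OD600 (typical anaerobe scales in rich media), sets
$a_{ii} = -\mu_i / K_i$, and populates half of the inter-species pairs
(80% of them negative — competition dominates in dense gut communities)
with magnitudes scaled to half the mean self-interaction, keeping dynamics
bounded. Media truths are sparse polynomials: a baseline capacity on
0.4–1.0 plus two or three main effects per species on $\pm 0.25$ — sparse
because a 9-run screen can only ever support a handful of active terms.
Noise has two parts, multiplicative log-normal on abundances (sdlog 0.1,
replicate-scale compositional scatter) and additive Gaussian OD noise
(sd 0.005, plate-reader scale). What the generator does *not* emulate:
sequencing count noise and taxonomic misassignment, lag phases and diauxie,
pH feedback, evolution across passages, or any higher-order (non-pairwise)
interactions. Passing tests therefore show the pipeline recovers truths
generated by its own model class under realistic noise — not that real
communities obey gLV dynamics.

Supernatant panels scale each recipient's fresh-media curve by
$1 + 0.4\, a_{ij} / \max|a|$, so the area-under-curve effect of donor $j$ on
recipient $i$ matches the sign of the interaction term by construction; the
sign-consistency statistic (both matrices normalized by their own maximum
absolute value, a 5% zero band with strict inequalities, Spearman
correlation over off-diagonal pairs) then approaches 100% on noiseless
panels.

## Problem sizes used in the automated checks

The acceptance-style tests run at deliberately modest sizes chosen to
exercise each claim: 10-species worlds with 64 designed endpoint conditions
for network recovery; a 4-species, 40-condition world for the
regularization-scan contrast (5-fold, coarse 10-point scan); 100 random
parameter draws for CSLE conservation; ten 5-species worlds for three DTL
cycles each; ten 4-species worlds with subsets of size 2–3 for the
variability-design comparison. Each was picked as the smallest size at which
the property is meaningfully tested, and all sizes are ordinary function
arguments, so any of these checks can be re-run larger.

## Known limitations

* The gLV fit is a local optimizer on a non-convex objective; pathological
  starts can stall, which is why initialization is monoculture-anchored and
  multi-start. The fit does not quantify structural non-identifiability —
  the bootstrap spread is a practical stand-in.
* The CSLE has a single shared brake: it cannot represent facilitation or
  targeted inhibition, and is intended as a *null* competition model for
  first-cycle design, not a mechanistic claim.
* Ensemble response surfaces are interpolators within the design ranges;
  optima on their boundary should be read as "move the next design here",
  not as predicted maxima.
* `detect_nongrowing` assumes at least three replicates and at most one
  failure per condition; systematic condition-level failures need the
  failed-culture sentinels, not the z-rule.
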