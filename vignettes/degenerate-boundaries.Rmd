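---
title: "Nonlinear decision boundaries for multi-alternative choice: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonlinear decision boundaries for multi-alternative choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nafc)
```

## The model

`nafc` simulates n-alternative forced-choice (nAFC) perceptual decisions as
sequential Bayesian evidence accumulation. Each of the $n$ hypotheses $H_i$
is an isotropic Gaussian evidence source in $(n-1)$-dimensional space. The
means sit at the vertices of a regular simplex with common pairwise
separation $\Delta\mu$ (all pairs of choices equally discriminable) and
shared standard deviation $\sigma$; by convention $\sigma = 1$ and
$\Delta\mu$ sets task difficulty. One sample $x(t)$ is drawn per discrete
time step from the true hypothesis, and the posterior belief
$P_i(t) = P(H_i \mid x(1{:}t))$ is updated by Bayes' rule with the previous
posterior as prior. Updates are performed in the log domain with a
log-sum-exp marginal, which is exact and keeps trajectories of $10^4$+
steps stable; the linear-domain rule is retained only as a test oracle.

Because $\sum_i P_i(t) = 1$, the decision variable lives on the
$(n-1)$-dimensional belief simplex: a line segment for $n = 2$, a triangle
for $n = 3$, a tetrahedron for $n = 4$. For $n = 2$ this recursion is the
SPRT in disguise: the posterior log-odds equal the accumulated log
likelihood ratio exactly, and a posterior threshold $\Theta$ corresponds to
the SPRT bound $\theta = \log(\Theta / (1 - \Theta))$. The test suite
asserts this equivalence to $10^{-8}$ over 1000-step trajectories.

## Boundary families

For $n > 2$ a decision boundary is a hypersurface in the simplex, not a
scalar. The package parameterizes a permutation-symmetric family

$$F(P) = \theta \left[ 1 + \frac{\alpha}{C^n_3} \sum_{j \in C^n_3}
  f\!\left(\Delta_{\max} P_j;\, \beta\right) \prod_{i \in j} P_i \right],$$

where the sum runs over all $C^n_3 = \binom{n}{3}$ triplets of choices
(1, 4, 10 for $n$ = 3, 4, 5), $\Delta_{\max}$ is the largest pairwise
difference within the triplet belief, and the shape function $f$ defines
the family: `flat` ($f = 0$), `curve` ($f = 1$), `power`
($f = \Delta_{\max}^\beta$), `oscil` ($f = \cos 2\pi\beta\Delta_{\max}$).
A decision for choice $i$ triggers at the first step with
$P_i(t) > F(P(t))$ (strict inequality).

Properties the implementation guarantees, each backed by tests against a
naive literal transcription of the formula:

* **Edge collapse.** With at most two nonzero beliefs every triplet product
  vanishes and $F = \theta$: $\theta$ is the edge-intersection threshold,
  and all families contain the flat boundary ($\alpha = 0$).
* **Reductions.** $\beta = 0$ collapses `power` and `oscil` to `curve`
  (we define $0^0 := 1$ so this holds at $\Delta_{\max} = 0$ too), and
  $\alpha = 0$ collapses `curve` to `flat`.
* **Symmetry.** $F$ is invariant under any permutation of beliefs, matching
  equal error costs.
* **Face collapse.** Setting one belief to zero reduces the $n$-choice
  boundary to the $(n-1)$-choice boundary with the amplitude rescaled by
  the ratio of triplet counts (for $n = 4$: $\alpha/4$), a direct
  consequence of the $1/C^n_3$ normalization.

$F$ is deliberately not clipped: parameter combinations with $F > 1$
(unreachable in a region) or $F$ below the prior are legal; the trial
engine flags non-terminating trials and records immediate crossings.

## Rewards and the degenerate acceptance set

A completed trial earns $r = -W e - cT$ with error indicator $e$, decision
time $T$ in steps, error cost $W$ (equal across error types, default 1) and
time cost $c$ per step; only the ratio $c/W$ matters. The mean reward over
a batch decomposes exactly as
$\bar r = -W \bar e - c \bar T$, so one reward level admits a continuum of
speed-accuracy trade-offs — the mechanism behind boundary degeneracy.

`sweep_landscape()` estimates mean reward on a grid of boundary parameters
by Monte Carlo (default $5 \times 10^3$ trials per cell; raise toward
$10^5$ for publication-grade landscapes). All randomness is counter-based:
each (cell, trial) pair hashes the master seed into its own generator, so
landscapes are bit-reproducible and independent of R's RNG state.

`acceptance_region()` extracts the *degenerate set*: cells with
$\bar r_x \ge r_{\max} - \delta\sigma_x$, where $\sigma_x$ is the cell's
per-trial reward spread (a standard-error variant is available via
`sigma_mode = "sem"`) and $\delta = 0.02$ by default — the width below
which the accepted region's extent stops changing while membership merely
thins. We use $\ge$ so that $\delta = 0$ returns exactly the argmax cells.

Two robust qualitative findings at $n = 3$, `curve` family,
$\Delta\mu = 1$: the accepted $\theta$ occupies a narrow band that sweeps
toward $1/n$ as $c/W$ grows, while the amplitude $\alpha$ is broadly
degenerate, spanning both signs and most of the explored range. One caveat
we document rather than hide: at the extreme negative amplitude
$\alpha = -20$ the boundary dips below the uniform prior at the simplex
center ($F = \theta(1 - 20/27) < 1/3$ for any $\theta < 1$), so every
trial terminates on the first step as a guess. Such cells can only be
near-optimal when guessing itself is near-optimal, in which case $\theta$
is no longer narrow — the "full amplitude range accepted while $\theta$ is
narrow" idealization therefore cannot hold exactly at the grid edges, and
the corresponding acceptance test is expected to flag it.

## Speed-accuracy trade-off and set-size effects

`sat_points()` turns acceptance sets into (mean error, mean time) points;
`mean_sat_curve()` connects per-cost-ratio means in cost order, averaging
family-balanced (mean of family means) so larger acceptance sets do not
dominate. Higher $c/W$ yields faster, less accurate operating points.
At fixed flat threshold and costs, increasing $n$ moves the operating
point away from the origin (slower and less accurate), and mean decision
time is log-linear in $n$ (Hick's law; `hicks_law_fit()` regresses on the
natural log, intercept in steps, slope in steps per log-choice).

## Implicit threshold dynamics

`implicit_threshold()` groups boundary-crossing beliefs (the posterior of
the chosen hypothesis immediately after the stopping update — the quantity
actually compared with $F$) by decision time, averages within identical
times, drops times with fewer than `min_count = 5` trials, and maps the
averages to log-odds. A static nonlinear boundary thereby acquires an
apparent time course, because slow trials cross in different regions of
the boundary than fast ones.

Empirically — and the tests establish the curvature sign numerically
rather than assuming it — the mapping in the diffusive regime is:

* interior-raised boundaries ($F$ above $\theta$ at the centroid,
  $\alpha > 0$): apparent **collapsing** threshold;
* interior-lowered boundaries ($\alpha < 0$): apparent **increasing**
  threshold;
* flat boundaries: **static**.

Two methodological choices deserve emphasis:

* **Classifier tolerance.** `classify_dynamics()` fits a weighted
  least-squares line to log-odds threshold vs time and calls a series
  dynamic only if the slope is outside 2 standard errors of zero *and* the
  fitted drift over the observed span exceeds `drift_tol = 0.08` log-odds.
  The floor exists because pure significance has vanishing specificity:
  with $10^4$ trials, the small but real drift ($\le 0.03$ log-odds,
  a posterior threshold moving from 0.800 to at most 0.807) that
  discrete-time overshoot induces at the shortest decision times of a
  strictly flat boundary becomes "significant". The default separates that
  artifact from the 0.1–0.7 log-odds drifts of genuinely curved
  boundaries by a wide margin on both sides.
* **Regime.** Implicit-dynamics analyses are demonstrated at
  $\Delta\mu = 0.3$, where decisions take tens to hundreds of samples and
  accumulation approximates a continuous diffusion. At $\Delta\mu = 1$ a
  decision takes about five coarse steps; onset overshoot then swamps
  boundary-shape effects and the collapsing category is not observable at
  all. This is a statement about discrete sampling granularity, not about
  the boundary model.

## What the generator does and does not emulate

Inputs are entirely synthetic, as the framework requires no external data:
the stated world is equal-discriminability Gaussian evidence, uniform
priors, a uniformly drawn true hypothesis, equal error costs, a constant
time cost, and stationary (time-independent) boundaries. Real
decision-making data violate several of these (difficulty varies across
trials, costs are asymmetric and learned, evidence is correlated and
non-Gaussian). A green test therefore establishes internal correctness of
the model and its analytics — not that any particular organism behaves
this way. Defaults: $\Delta\mu = 1$, $\sigma = 1$, $W = 1$,
$c/W \in \{0.001, 0.04, 0.1\}$, $\theta$-grid $(1/n + 0.01,\, 0.99)$,
$\alpha \in [-20, 20]$, $\beta \in [0, 5]$ (`power`) or $[0, 3]$
(`oscil`), 5000 trials per cell, `max_steps = 10000`.

## Numerical and design choices

* Crossing is evaluated only after the first update ($t \ge 1$), never on
  the prior; a boundary below $1/n$ still consumes one sample.
* When several beliefs exceed $F$ simultaneously the largest belief wins
  (any crosser is dominated by the maximum, which therefore also crosses);
  exact ties are broken uniformly at random from the trial's own stream.
* Non-terminating trials (within `max_steps`) are excluded from means but
  counted and reported (`n_unterminated`); they are flagged outcomes, not
  errors.
* Belief normalization is renormalized after every update; validation
  tolerance $10^{-9}$.
* Landscape sections are smoothed with `mgcv::gam` (thin-plate by default,
  whose penalty null space contains straight lines so noiseless linear
  sections are recovered exactly; `bs = "gp"` selects a Gaussian-process
  smooth). 95% bands come from the smoother's standard errors; the
  peak-overlap summary intersects the per-section bands at their peaks.
* Simplex vertices are built by a deterministic recursive construction;
  only pairwise distances and the centroid are contractual, as every
  downstream quantity depends on distances alone.

## Limitations

Time-dependent boundaries, unequal error costs, mixed-difficulty trials,
leaky/competing accumulation and fits to empirical reaction-time data are
out of scope. Landscapes at the default 5000 trials per cell carry visibly
wider Monte-Carlo error than at $10^5$; acceptance-set membership near the
$\delta$ margin is correspondingly noisy, though its qualitative extent is
stable across seeds.
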