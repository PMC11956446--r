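---
title: "Bayesian sequential two-endpoint designs with B-spline priors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian sequential two-endpoint designs with B-spline priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splinetrial)
```

## The design

`splinetrial` implements a Bayesian adaptive sequential design for two-arm
randomised trials with a binary primary endpoint and a binary secondary
acceptability endpoint, of the kind used in paediatric settings where
enrolment is hard and prior information is scarce or conflicting. The three
unknowns are the event rate under treatment $\pi_T$, the event rate under
control $\pi_C$, and the treatment-discontinuation rate $\pi_{disc}$ in the
treated arm. Efficacy is expressed through the absolute risk reduction
$\mathrm{ARR} = \pi_T - \pi_C$; the treatment works when $\mathrm{ARR} < 0$.
Acceptability requires the discontinuation rate to stay below a threshold
$m$ (default 0.2).

The trial has exactly two looks. At mid-enrolment
($n_1 = \lceil 0.5\,n \rceil$ subjects per arm) an interim analysis may stop
the trial early; otherwise the trial runs to its planned size and a final
analysis declares efficacy or no effect on the primary endpoint alone.
Two families of decision rules are provided.

**Classical (posterior-probability) rules.** With first-look boundary
$c_1 = 2.74$ (an O'Brien–Fleming-like conservative bound,
$\Phi(c_1) = 0.997$):

* stop for efficacy at interim iff
  $P(\pi_T^* - \pi_C^* < 0) > \Phi(c_1)$ **and**
  $P(\pi_{disc}^* < m) > \Phi(c_1)$;
* stop for futility at interim iff both probabilities fall below 0.5;
* at the final look declare efficacy iff
  $P(\pi_T^* - \pi_C^* < 0) > 0.976$.

The final threshold is stored directly as the probability 0.976 — the
standard final bound of a two-look O'Brien–Fleming design — rather than as a
z value, because a z of 2.75 and a probability of 0.976 are mutually
inconsistent ($\Phi(2.75) \approx 0.997$) and the probability is what the
rule actually consumes. All comparisons are strict; a tie at a boundary
resolves to the non-stopping action, an event of probability zero under
continuous posteriors.

**HDI rules.** The same structure expressed through highest-posterior-density
intervals: stop for efficacy when the 0.994-coverage HDIs lie entirely on
the favourable side ($\mathrm{ARR}$ interval wholly below 0, discontinuation
interval wholly below $m$); stop for futility when the 0.5-coverage HDIs
straddle their thresholds; declare efficacy at the final look when the
0.95-coverage ARR HDI lies wholly below 0. The 0.994 coverage mimics the
one-sided $z = 2.74$ boundary through
$1 - 2\,(1 - \Phi(2.74)) = 0.994$ (`hdi_coverage_from_bound()`). Whether the
final coverage should instead be $1 - 2(1 - 0.976) = 0.952$ to mirror the
classical final bound is unknowable from the printed constants; 0.95 is used
as printed, and both are configurable in `design_config()`.

## Priors

Each of the three rates receives its own prior on $[0,1]$, in one of two
families and at one of three informativeness levels.

**Parametric (Beta) priors** come from the mean/ESS parameterisation
(`beta_from_summary()`): a mean $\mu$ and effective sample size $s$ give
$\mathrm{Beta}(\mu s, (1-\mu)s)$. Discounting holds the mean and rescales the
ESS to 5 (`low_informative`) or replaces the prior by $\mathrm{Beta}(1,1)$
(`uninformative`).

**Semiparametric (B-spline) priors** represent a density as a nonnegative
expansion $f(x) = \sum_j c_j B_j(x)$ in a clamped cubic B-spline basis on
$[0,1]$, fitted to elicited quantile judgements. Nonnegative coefficients
make the density nonnegative and its CDF nondecreasing by construction, and
the exact identity $\int_0^1 B_j = (t_{j+d+1} - t_j)/(d+1)$ turns unit mass
into one linear constraint. Discounting mixes the fitted density with the
uniform at weight 0.5; the uniform itself is the all-ones coefficient vector
(partition of unity), so `uninformative` is exactly flat.

### The fitting scheme

`fit_spline_prior()` solves a small convex problem. Given judgements
$\{(p_i, v_i)\}$ ("the rate is below $v_i$ with probability $p_i$"):

1. A Beta distribution is fitted to the judgements by least squares on the
   CDF scale (deterministic Nelder–Mead on log-parameters).
2. A working elicited CDF is built. If the fitted Beta already reproduces
   every judgement to within $10^{-4}$ it *is* the working CDF — exact
   quantiles of a Beta belief are recovered essentially perfectly this way.
   Otherwise the judgements are interpolated monotonically on the probit
   scale ($\Phi^{-1}(p)$ against $v$, a nearly linear relationship for
   rate-like beliefs) inside the elicited range, and the fitted Beta's
   tails, proportionally rescaled for continuity, complete the CDF outside
   the range where the expert supplied no information.
3. The spline CDF is fitted to ~200 dense targets from the working CDF by
   nonnegative least squares (Lawson–Hanson) with a strongly weighted
   unit-mass row, and the coefficients are renormalised so the mass
   constraint holds exactly.

Interior knots are equally spaced, augmented with the elicited values
themselves (deduplicated at $10^{-3}$) so the basis has resolution exactly
where the judgements sit. A pure quantile-anchored least-squares fit was
rejected during development: the nonnegative cone of a small cubic basis
cannot interpolate steep elicited CDFs, and fit errors an order of magnitude
above the dense-target scheme result. With the adopted scheme, exact Beta
quantiles at the five standard elicitation levels are recovered with CDF
sup-norm error below 0.005 across shapes $a, b \in [1, 20]$, and uniform
judgements return the flat density to within $10^{-6}$.

The fit object records the residuals at the elicited judgements
(`glance()` surfaces the maximum). With very small bases (e.g.
`n_basis = degree + 1` and no knot augmentation) the fit is a documented
least-squares compromise rather than an interpolant; the residuals say by
how much.

**Multiple experts** are pooled linearly: each expert's working CDF is
completed separately and the spline is fitted to their pointwise average.
Linear opinion pooling is the least-assumption default; fitting per expert
and averaging afterwards is available by splitting the panel.

### The synthetic elicitation panel

`generate_elicitation_fixture()` stands in for a real elicitation exercise:
each expert reports the exact quantiles of a common Beta belief, perturbed
by Gaussian noise on the logit scale (sd `jitter_sd`, default 0.1) and
re-sorted to restore monotonicity. It emulates between-expert scatter around
a shared belief; it does not emulate systematic expert bias, heavy-tailed or
multimodal judgements, within-expert incoherence, or anchoring effects —
passing tests built on it show the pipeline recovers a coherent consensus
belief, not that it is robust to pathological panels. The default
informative stand-ins used by `default_trial_priors()` — treatment mean
0.40, control mean 0.30, discontinuation mean 0.20, all at ESS 20 —
deliberately centre the treatment belief *above* the control belief
($\pi_T - \pi_C > 0$), so that simulations with a true benefit
($\pi_T < \pi_C$) exercise prior–data conflict.

## Posterior computation

All posteriors are one-dimensional, so no MCMC is used. `grid_posterior()`
evaluates $f(x) \propto \pi(x)\, x^s (1-x)^{n-s}$ on an equally spaced grid
(default $G = 2001$), assembling the product in log space so large-$n$
likelihoods cannot underflow, and normalises by the trapezoid rule. Under a
Beta prior this reproduces the conjugate closed form to below $10^{-5}$
sup-norm, which the test suite asserts on a $G = 4001$ property grid.

Draws come from inverse-CDF sampling with linear interpolation
(`sample_posterior()`); ARR draws subtract independent treatment and
control draws obtained from separate, deterministically derived substreams
of the master seed (`arr_posterior()`, default 20,000 draws), so arms are
modelled as independent. Sampling generalises unchanged to spline priors,
for which no closed form exists; an exact grid-convolution oracle in the
test suite checks the sampled $P(\mathrm{ARR} < 0)$ against discrete
convolution of the two grid densities. $P(\pi_{disc}^* < m)$ is taken
exactly from the grid CDF rather than sampled — it is a single-rate
tail probability and the deterministic route removes one source of Monte
Carlo noise from the decision.

`hdi()` on draws returns the shortest window of
$\lceil \gamma N \rceil$ consecutive sorted draws (leftmost on ties —
deterministic given the draws); on a grid it performs a density water-level
scan. A multimodal spline posterior can split the highest-density region
into several intervals; the grid method then returns the bounding interval
of the whole region with `contiguous = FALSE`, which is what the interval
rules consume — conservative for the efficacy rule, which needs the whole
interval on one side.

## The simulation engine

`run_trial()` draws accumulating data (interim counts are nested in final
counts, as in a real sequential trial), applies the interim rule, and only
on `continue` proceeds to the final analysis. Discontinuation is simulated
independently of the event process in the treatment arm; no dependence
structure between endpoints is asserted anywhere in the design, and none is
modelled. `operating_characteristics()` repeats this `n_sims` times with
per-trial seeds derived from the master seed by a counter-based scheme (no
global RNG state crosses trials), and aggregates five indicators: the
proportion declaring the effect (interim or final), the false discovery
rate under a null scenario, true and false interim futility proportions,
and the true interim efficacy proportion. Ground truth for
"true/false" classification: the effect is real iff $\pi_T < \pi_C$;
futility stopping is "true" when $\pi_T \ge \pi_C$ *or*
$\pi_{disc} > m$. Indicators whose ground-truth condition does not apply
are `NA` rather than silently zero.

`sample_size_search()` estimates the power curve over a candidate grid,
applies isotonic regression before thresholding (power is nondecreasing in
$n$; raw Monte Carlo estimates need not be), and returns the smallest
candidate whose smoothed power reaches the target, or an explicit
not-achieved marker.

### Problem sizes

The package's own studies run at desk scale: 2,000 simulated trials per
scenario for operating characteristics (Monte Carlo standard error about 1
percentage point on a 25% proportion), 600–1,000 per candidate size in
power searches, and 20,000 ARR draws per analysis. These sizes make every
reported proportion's uncertainty explicit through the `mc_se` fields;
scaling to larger runs is a single argument.

### What the calibration actually gives

The 0.5/0.5 futility thresholds are described as calibrated to stop roughly
25% of no-effect trials at interim: with $\pi_T = \pi_C$ the efficacy
condition fails with probability $\tfrac12$ by arm symmetry, and with
$\pi_{disc} = m$ the acceptability condition fails with probability
$\approx \tfrac12$, giving $\approx \tfrac14$ jointly. At finite interim
sizes the second factor is not exactly $\tfrac12$: with a uniform prior and
$d$ discontinuations in $n_1$ subjects the posterior is
$\mathrm{Beta}(1+d,\, 1+n_1-d)$, whose median sits slightly above $d/n_1$,
so $P(\pi_{disc}^* < m) < 0.5$ occurs with probability
$P(d \ge d^*) \approx 0.56$ at $n_1 = 50$, $m = 0.2$. The engine therefore
measures an interim futility proportion near 27–28% rather than exactly
25% under this calibration scenario — a property of the design at finite
$n$, not a simulation artefact; the acceptance test works to the
3-MC-SE band around the nominal 25%.

## Numerical choices

* Grid size $G = 2001$; log-space likelihood; trapezoid normalisation.
* Exact B-spline antiderivatives via the de Boor identity (one extra
  boundary knot, degree raised by one, reversed cumulative sum), verified
  against independent Gauss–Legendre quadrature to machine precision.
* NNLS tie-breaking and the leftmost-shortest-window HDI make every fitted
  object and every decision deterministic given data and seed.
* Seeds derived with Lehmer-style mixing stay in $[1, 2^{31}-2]$, valid for
  `set.seed()` on any platform.
* Degenerate inputs: `n = 0` returns the prior; `pi = 0` scenarios generate
  structurally zero counts; duplicate elicited quantiles are rejected at
  construction; an infeasible spline fit (zero mass) raises an error
  carrying the residual rather than returning garbage.

## Limitations

* The elicited prior parameters and the exact scenario grid of the
  motivating study are not public; the defaults here are declared
  stand-ins spanning the same qualitative regimes (effect/no effect,
  discontinuation above/below $m$), so figure-level results of that study
  are reproduced qualitatively (orderings, bounds), not numerically.
* One interim look only; no alpha-spending machinery beyond the two printed
  boundaries.
* Discontinuation is a binary endpoint; no dropout-time modelling.
* Arms are independent; no correlation between $\pi_T^*$ and $\pi_C^*$.
* Linear pooling of experts is the only built-in aggregation.
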