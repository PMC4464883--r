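---
title: "Stability selection with boosting: models, bounds, and design choices"
author: "boostsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability selection with boosting: models, bounds, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In high-dimensional regression ($n \ll p$, or rich additive models with
many candidate effects) the practically important question is rarely
"what is the best predictive model" but "which variables can I report
with a controlled risk of false discovery".  Stability selection
answers this by wrapping any variable-selection procedure in half-size
subsampling: a variable is *stable* when its relative selection
frequency $\hat\pi_j$ over the subsample fits reaches a threshold
$\pi_{thr} \in (0.5, 1]$, and the expected number of falsely selected
noise variables — the per-family error rate, $\mathrm{PFER} = E(V)$ —
is bounded analytically.  `boostsel` implements this with
component-wise gradient boosting as the selection engine.

## Component-wise boosting

For a loss $\rho(y, \eta)$ (half-squared error for Gaussian responses,
the negative binomial log-likelihood with logit link for binary ones),
boosting minimizes the empirical risk
$n^{-1}\sum_i \rho(y_i, \eta(x_i))$ by repeated steepest descent in
function space: at iteration $m$ the working residuals
$u_i = -\partial\rho(y_i,\eta)/\partial\eta$ are computed at the
current fit, every *base-learner* (a linear effect with its own
intercept, a P-spline smooth, or a ridge-penalized categorical block)
is fitted to $u$ by (penalized) least squares, and only the best-fitting
learner is updated by a shrunken step $\nu$.  Early stopping makes this
a variable-selection method; within stability selection each subsample
fit simply runs until $q$ *distinct* learners have been selected.

Design choices of note, each switchable:

* **Offset.** The paper's algorithm statement initializes at
  $\hat\eta^{[0]} \equiv 0$; `boostsel` defaults to the empirical-risk
  minimizer (mean, or logit of the mean) because a zero offset without
  an intercept learner biases the first selections toward whichever
  learner can best absorb the grand mean.  `offset_mode = "zero"`
  restores the literal rule.
* **Step length** $\nu = 0.1$ by default.
* **Loss scaling.** The Gaussian loss is $(y-\eta)^2/2$ so that the
  negative gradient is the raw residual.
* **Penalized learners.** P-splines use cubic B-splines on 20 equally
  spaced interior knots with a second-order difference penalty; ridge
  blocks use one indicator per level.  In both cases the ridge
  multiplier $\lambda$ is resolved *once per data set, before boosting*,
  so that the trace of the smoother matrix equals the target degrees of
  freedom (4 by default, within $10^{-6}$); equal degrees of freedom
  across learners keep the per-iteration selection fair.  Subsample
  fits reuse the full-data $\lambda$ and spline knots, which keeps the
  learners identical across subsamples (and is also what makes the
  subsampling loop cheap).
* **Ties** in the per-iteration selection go to the lowest learner
  index — deterministic and order-stable.
* **No internal standardization** of covariates; linear learners carry
  their own intercept instead.

## The error-bound calculus

With $q$ selections per fit out of $p$ learners and threshold
$\pi_{thr}$, three successively tighter PFER bounds are available
(`pfer_bound()`), all exposed through the same parameter-solving
interface (`solve_cutoff()`, `solve_q()`, `stabsel_parameters()`):

1. **Worst case** (no assumptions):
   $E(V) \le q^2 / ((2\pi_{thr}-1)\,p)$.
2. **Unimodal** simultaneous selection probabilities under
   complementary-pairs subsampling: $C(\pi_{thr}, B)\, q^2/p$ with the
   piecewise constant $C$ breaking at $\pi_{thr} = 3/4$.
3. **r-concave**: $p \cdot \min\{D(\theta^2, 2\pi_{thr}-1, B, -1/2),
   D(\theta, \pi_{thr}, 2B, -1/4)\}$ with $\theta = q/p$, where
   $D(\theta, \tau, N, r)$ (`d_value()`) is the maximal tail
   probability $P(X \ge \tau)$ over random variables on the grid
   $\{0, 1/N, \dots, 1\}$ whose probability sequence is r-concave
   ($p_k^r$ convex on a contiguous support) with mean at most $\theta$.

`d_value()` computes the maximization from the extremal structure of
the problem: on its support the convex sequence $p_k^r$ can be taken
affine, giving one-parameter families $p_k \propto (a + k)^{-1/|r|}$
(decreasing), their mirror images (increasing), and versions with a
depressed point mass adjacent to the support (subject to the convexity
constraint at that point).  The mean constraint pins the shape
parameter; a one-dimensional optimization handles the mixtures.  The
unit tests check this construction against an independent brute-force
oracle (penalized multistart optimization over arbitrary convex
sequences) on small grids.  Two honest caveats: (i) for tail points
below twice the mean budget the affine-extremality argument from the
literature does not cover the problem; `boostsel` searches the
increasing-shape families there, which agrees with the oracle on small
grids but is not backed by a proof, and reference implementations
simply return the trivial bound 1 in that regime; (ii) because
r-concavity at $r=-1/2$ implies unimodality, `boostsel` caps the
r-concave bound at the unimodal one (and the unimodal at the worst
case), which makes the ordering of the three bounds structural.  Both
choices only make the reported bound more conservative, and neither
affects the reference configuration ($q=10$, $p=57$, $B=50$,
$\mathrm{PFER} \le 1$), which resolves to $\pi_{thr} = 0.87$
(unimodal, realized bound 0.963), $0.69$ (r-concave, 0.941), and a
capped $\pi_{thr} = 1$ with `attainable = FALSE` under the worst-case
bound (realized bound $q^2/p = 1.75 > 1$).

Validity limits: the unimodal constant requires
$\pi_{thr} \ge 1/2 + \min(\theta^2, 1/(2B) + 3\theta^2/4)$; below it
the worst-case bound is used.  Computed cutoffs are reported on the
grid of multiples of $1/(2B)$ — empirical frequencies over $2B$ fits
can only attain that grid, and rounding *up* keeps the bound
conservative (at $B = 50$ this is what turns the un-rounded unimodal
solution 0.8647 into the reported 0.87).

Changing $\pi_{thr}$, $\mathrm{PFER}_{max}$ or the assumption for fixed
$q$ does not require re-running the subsampling: `rethreshold()`
re-cuts the stored frequencies, and `run_experiment()` exploits the
same fact to evaluate whole $(\mathrm{PFER}_{max},$ assumption$)$ grids
from one set of fits per replicate.

## Subsampling

Complementary pairs is the default scheme: each of $B = 50$ random
permutations contributes both disjoint halves of size
$\lfloor n/2 \rfloor$, $2B$ fits in total; for odd $n$ one observation
per pair is left out, re-randomized each pair.  The
Meinshausen–Bühlmann scheme ($B$ independent half-samples, 100
recommended) is available as `sampling = "mb"`.  Frequencies are
computed over all fits, so they lie on the $1/(2B)$ grid.  Every
subsample draw derives its own seed from the master seed by counter,
making runs reproducible regardless of execution order.  The subsample
size $\lfloor n/2 \rfloor$ is not tunable — the error bounds are
derived for exactly this size.  Two practical extensions: `stratify`
draws within outcome strata (binary responses on small $n$),
and `cluster` subsamples at the level of a grouping variable so that
all rows of a subject move together — the default in the
phenotype-microarray pipeline, where wells within a replicate are
strongly dependent (row-level subsampling remains available).

## Simulation scenarios

Two generators mirror the standard evaluation settings:

* `gen_logistic_linear()`: rows i.i.d. $N(0, \Sigma)$ with $\Sigma = I$
  or Toeplitz $\Sigma_{kl} = 0.9^{|k-l|}$, signal coefficients drawn
  from $\{-1, +1\}$, Bernoulli response through the logistic link.
* `gen_gaussian_additive()`: columns uniform on $(-2, 2)$ (Toeplitz
  correlation through a Gaussian copula; the realized product-moment
  correlation of the uniforms is slightly below $0.9^{|k-l|}$), additive
  predictor built from eight centered reference shapes — oscillating
  $\sin 3x$, quadratic $x^2 - 4/3$, two smooth shapes, a cosine, a
  piecewise-linear and two linear ones ($f_1$–$f_2$ for two signals,
  $f_1$–$f_3$ for three, all eight for eight).  The exact analytic
  forms are stand-ins chosen to match the published taxonomy of shapes;
  no formulas are published.  The noise variance is calibrated against
  the *realized* predictor variance, $\sigma^2 =
  \widehat{\mathrm{Var}}(\eta)(1 - R^2)/R^2$ with $R^2 = 0.33$.

Signals occupy the first `p_infl` columns by default (configurable to
equally spaced).  Under Toeplitz correlation contiguous signals are
mutually correlated — a deliberately hard case for the exchangeability
assumption behind the worst-case bound.  What a green simulation test
establishes: with these generators the mean false-positive count stays
below the configured bound and signal frequencies dominate noise
frequencies.  What it does not establish: error control under
correlation structures that violate exchangeability between noise and
signal variables, non-Gaussian/non-uniform designs, or model
misspecification beyond what the additive scenario covers.
The desk-scale defaults (20 replicates, $n \le 500$, $p \le 100$,
$B = 50$) are deliberate reductions of the published grid (50
replicates, $p$ up to 1000); the full grid is a configuration away
(`run_experiment()`, CLI `experiment`).

## The phenotype-microarray pipeline

The case-study model explains log relative absorbance of each well by
an intercept, a global group effect, amino-acid main effects
(dummy-coded incidence), group-specific amino-acid interactions in
sum-to-zero coding (control $= -1$, case $= +1$, so a group difference
is *twice* the interaction coefficient), and an overall plus a
group-specific replicate random effect: $1 + 2A + 2$ base-learners
(57 at $A = 27$).  `fit_offset_then_stabsel()` first boosts the main
effects only (stopping iteration by 5-fold cross-validation) and uses
those predictions as a fixed offset for the stability-selection stage
over the full learner list, so the interaction learners only compete
for what the main effects cannot explain.  Natural logarithms are used
throughout (effect magnitudes then read directly as log-scale
differences).  Random effects are ridge-penalized replicate indicators
at 4 degrees of freedom — the boosting surrogate for a Gaussian random
effect; the original random-effect specification is not published.

Effect sizes are reported from a long fixed-iteration full-data
boosting fit (`final_mstop = 1500`), not from the $q$-stopped fit:
stopping at $q$ distinct selections leaves the coefficients heavily
shrunken, while as $m$ grows component-wise boosting approaches the
penalized least-squares solution and the planted shifts of the fixture
are recovered to within a few hundredths.

The fixture generator (`gen_pm_fixture()`) emulates the data *shape*:
35 replicates (17 cases, 18 controls) times 384 wells, a plate layout
of 1–4 annotations per well drawn once and shared by all replicates,
main effects $N(0, 0.15^2)$, random-effect and residual standard
deviations 0.1 and 0.2 on the log scale.  It does not emulate kinetic
curve estimation, plate/batch effects, or the real annotation
structure, so a green recovery test establishes that the pipeline
finds planted log-scale group differences of $\ge 0.25$ under this
noise model — not that it reproduces the original biological findings,
which require the real data set.

## Numerical choices

* Tie-breaks: lowest learner index (boosting selection), smallest grid
  value (cross-validated $m_{stop}$), inclusive $\ge$ comparison at the
  stability threshold.
* $\lambda$-from-df root finding: bisection on $\log\lambda$ over
  $[10^{-10}, 10^{12}]$, trace tolerance well below the $10^{-6}$
  contract; degenerate designs (constant columns, unreachable df)
  raise errors naming the learner.
* The binomial loss is evaluated in log-sum-exp form and its offset
  errors out on single-class responses rather than returning
  $\pm\infty$.
* `boost_until_q()` caps at `max_iter = 2500` and raises a typed error
  carrying the partial fit and the count reached, rather than looping
  silently.
* All serialized outputs are timestamp-free so identical runs produce
  byte-identical files.

## Known limitations

* The r-concave tail maximization is exact against the oracle on small
  grids but rests on an extremal-family argument; in the
  low-tail-point regime (irrelevant for thresholds above 0.5 and
  moderate $q/p$) it is best-effort, bounded by the Markov inequality,
  and capped by the unimodal bound.
* Error control is a bound on the *expected* number of false
  positives under the stated assumptions; individual runs can exceed
  it, and strong noise–signal correlation can break the
  exchangeability premise of the worst-case bound.
* The boosting engine covers Gaussian and binomial losses and the
  three learner types the experiments need; survival/quantile losses
  and spatial/cyclic/monotone learners are out of scope.
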