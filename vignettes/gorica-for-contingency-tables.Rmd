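---
title: "Evaluating theory-based hypotheses on contingency tables with GORICA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating theory-based hypotheses on contingency tables with GORICA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goricct)
```

## The problem

Researchers analyzing cross-classified counts usually hold directional
expectations — "the proportion of men among bachelor's graduates exceeds the
proportion among holders of any other degree", or "two interacting people
tend to look where the other just looked". Written out, such expectations
are order constraints on *functions* of the cell probabilities
$\pi$ of a multi-way contingency table: conditional proportions, marginal
sums, or odds ratios. Classical log-linear modeling answers a different
question (is there any association?), becomes uninterpretable for
high-dimensional tables (a $5\times5\times5$ table has 124 log-linear
parameters), and breaks down when the table is sparse.

This package ranks a set of competing constrained hypotheses by the
generalized order-restricted information criterion approximation (GORICA),

$$\mathrm{GORICA}_m = -2\,L(\tilde\eta_m \mid \hat\eta, \hat\Sigma) + 2\,PT_m,$$

an AIC-type criterion whose fit term is the order-restricted maximum of a
multivariate-normal approximation to the likelihood of the parameter
estimates, and whose penalty $PT_m$ is the *expected number of free
parameters* under the constraints. With only equality constraints the
criterion reduces to AIC. GORICA values are transformed into weights
$w_m \propto \exp(-\mathrm{GORICA}_m/2)$; ratios of weights are evidence
ratios.

## Reparameterization: making restrictions linear

Hypotheses about conditional probabilities or odds ratios are non-linear in
$\pi$. The package therefore evaluates them on a reparameterized vector
$\eta = g(\pi)$ chosen so the restrictions become linear,
$H_m : S_m\eta = s_m,\; R_m\eta > r_m$. Five families are built in
(`builtin_spec()`): cell probabilities, marginal sums, row/column
conditional proportions, local odds ratios, and marginal/conditional odds
ratios for three-way tables; `marginal_pattern_spec()` builds arbitrary
marginal sums and `eta_spec()` arbitrary sum/ratio/cross-ratio components.

Working on $\eta$ is not cosmetic. The penalty is computed from a zero-mean
normal null; for linear constraint systems the (relocated) feasible region
is a closed convex cone, so the penalty is invariant to the scale of the
covariance matrix. Constraints stated directly on the bounded simplex
$\{0 \le \pi \le 1, \sum\pi = 1\}$ do **not** form a cone, and their
penalty depends on both the null mean $\mu$ and any scale factor $c$
applied to the covariance. The package ships a bounded-simplex penalty mode
(`penalty_bounded_pi()`) precisely to make that dependence measurable;
`test-penalty.R` demonstrates that at $c = 1$ a tight covariance reproduces
the full $D-1$ free parameters while a $10^5$-fold inflation collapses the
penalty. For real analyses, reparameterize.

Only components referenced by the hypotheses should enter $\eta$: when the
`cells` family covers the whole simplex the last cell is dropped
(`drop_last = TRUE`), otherwise the sum-to-one constraint makes the
covariance singular. Hypotheses on different parameterizations answer
different questions and are not competing; mixing term kinds in one spec
therefore triggers a warning.

## Estimation: nonparametric bootstrap

$\hat\eta$ is computed from the observed table (the plug-in MLE
$\hat\pi = y/n$); $\hat\Sigma$ is the sample covariance of $\eta$ across
`B` bootstrap replicates, each drawn as a multinomial$(n, \hat\pi)$ —
equivalent to resampling the $n$ observations with replacement. The
observed-table value, not the bootstrap mean, is reported as the estimate.
The default `B = 1000` puts the Monte-Carlo error of the variances well
below the leading digit for the table sizes treated here; `B` is a plain
argument everywhere.

Sampling zeros need care. An empty cell can make a component of $\hat\eta$
exactly 0 or 1 (no variation across replicates, hence a zero variance and a
singular $\hat\Sigma$) or inestimable (zero denominator). The package:

* flags each component (`ok` / `zero` / `one` / `inestimable`) instead of
  erroring (`eta_value()`);
* discards-and-redraws bootstrap replicates containing inestimable
  components rather than perturbing them, which would bias $\hat\Sigma$; a
  configurable ceiling (default 50%) turns chronic inestimability into an
  error advising a different parameterization;
* repairs zero diagonal entries of $\hat\Sigma$ by substituting the
  smallest strictly positive variance in the matrix, zeroing the
  corresponding covariances (`adjust_covariance()`). The minimum is the
  smallest change compatible with the data — small counts have small
  bootstrap variances — but if the result is still not positive definite,
  `ensure_positive_definite()` escalates to the mean and then the maximum,
  recording which strategy succeeded. Positive definiteness means smallest
  eigenvalue above $10^{-12}$ times the largest diagonal entry.

An inestimable component of the *observed* $\hat\eta$ cannot be repaired by
covariance surgery; the evaluation errors and, inside the simulation
harness, the trial is skipped and counted.

## Fit: projection onto the constraint set

The order-restricted MLE $\tilde\eta_m$ minimizes the Mahalanobis distance
$(\eta - \hat\eta)^\top \hat\Sigma^{-1} (\eta - \hat\eta)$ subject to
$S\eta = s$, $R\eta \ge r$. Strict inequalities are treated as closed
constraints: the boundary has probability zero under the sampling
distribution, and convex solvers require closed sets. The solver
enumerates candidate active sets of the inequality rows; each candidate
gives a closed-form equality-constrained projection, and the
Karush-Kuhn-Tucker conditions (non-negative multipliers, feasible inactive
rows) identify the optimum exactly. With $h_r$ inequality rows this costs
at most $2^{h_r}$ small linear solves which are shared across samples — for
the systems arising here ($h_r \le 4$) this is faster and more exact than
iterative quadratic programming; a cyclic Dykstra projection covers systems
with more than a dozen inequality rows. The projection is cross-checked in
the test suite against an independent zoom-in grid minimizer on all
$K \le 3$ systems to $10^{-4}$.

The log-likelihood is the normal log-density
$-\tfrac{K}{2}\ln(2\pi) - \tfrac12\ln|\hat\Sigma| - \tfrac12 q$, with $q$
the achieved Mahalanobis distance and $\ln|\hat\Sigma|$ computed via
Cholesky. Active constraints are identified from residuals at tolerance
$10^{-8}$, not from solver multipliers, so the reported active set does not
depend on the algorithm.

## Penalty: Monte-Carlo level probabilities

$PT_m = \sum_{l} l \cdot LP_l$, where $LP_l$ is the probability that a draw
from $N(0, \hat\Sigma)$ projects onto the constraint cone with exactly $l$
parameters left free — $l$ being $K$ minus the *rank* of the constraint
rows active at the projection (rank, not count, so linearly dependent
active rows are not double-counted). Hypotheses are relocated first
(constants zeroed), which shifts the cone apex to the origin and makes the
penalty scale-invariant. Closed forms short-circuit the sampling:
$PT = K$ for the unconstrained hypothesis and $K - \operatorname{rank}(S)$
for equality-only hypotheses. The default `T = 10000` gives a Monte-Carlo
standard error of about 0.01 on the penalties of the worked examples; the
standard error is always reported so callers can size `T` rationally. The
level split of simple systems is verified in the tests against the
closed-form bivariate-normal orthant probability
$\tfrac14 + \arcsin(\rho)/(2\pi)$.

The bounded-simplex mode works in the $D-1$ free cell probabilities (last
cell implied), draws from $N(\mu, c\hat\Sigma_{\hat\pi})$ with
$\mu_i = 1/D$ by default (every cell equally likely — the center of the
feasible region), and projects infeasible draws onto the feasible set:
exactly, by the active-set enumeration, when the constraint system is
linear in the cells; otherwise by an augmented-Lagrangian minimizer over
BFGS with analytic constraint gradients and multistart (the clipped
sample, the simplex center, and the point where the ray from the center
towards the sample leaves the simplex). Ratio constraints make the
feasible set non-convex, so multistart matters; samples whose projection
fails all starts are dropped with a warning and more than 1% of drops is
an error. The activity tolerance is scaled by $\sqrt{c}$ because the
solution's distance from the boundary scales with the sampling spread.

## The selection-rate simulation

`run_condition()` reproduces a designed operating-characteristics study:
2×4 tables are drawn from one of twelve embedded population vectors
(four true-hypothesis cases × Cramér's V $\Phi \in \{0.10, 0.30, 0.50\}$,
stored as printed to four decimals and renormalized to exact simplex
points before sampling, since multinomial samplers require exact simplex
membership), designated cells are set to zero *after* generation to force
sampling zeros (counts are replaced without redistribution — the literal
reading of the design; the total shrinks accordingly), and the four-part
hypothesis set on the male conditional proportions is evaluated per table.
A trial is "successful" when the pipeline completes; covariance failures
are skipped and counted, and a skip rate above one half aborts the
condition as pathological. Ties for the smallest GORICA split the
selection count fractionally so percentages always sum to 100.

The desk-scale defaults — 250 trials with `B = 200`, `T = 2000` per trial —
keep one condition near ten seconds while leaving the Monte-Carlo standard
error of a selection percentage near two points; the study-scale setting
(1000 trials) is a single argument away. The embedded populations are
validated in the tests by recomputing Cramér's V
($\sqrt{\phi^2/\min(I-1, J-1)}$) from each vector.

What the generator emulates is exactly the sampling scheme of the design:
i.i.d. multinomial tables with forced structural-looking zeros at fixed
positions. It does not emulate overdispersion, clustered observations, or
temporally dependent counts (the gaze example's frames are serially
correlated, for instance), so passing selection-rate checks speak to the
criterion's behavior under clean multinomial sampling, not to robustness
against dependence.

## Numerical choices and limitations

* Cell order is row-major over factors in declared order, everywhere.
* Constraint rows are normalized to lexicographic order, so penalties,
  active sets, and reports do not depend on how a hypothesis was written.
* The equality-feasibility check compares $\operatorname{rank}([S\,|\,s])$
  with $\operatorname{rank}(S)$; inconsistent systems error before any
  optimization.
* Degenerate estimates flagged `zero`/`one` enter the fit with their
  degenerate value; this mirrors the covariance-repair philosophy of
  changing as little as possible.
* The bounded-simplex penalty at very large scale factors ($c \sim 10^5$)
  probes the regime where almost every draw is projected from far outside
  the simplex onto its boundary. The level distribution then hinges on
  fine details of the sampling-and-projection procedure; published
  demonstrations of this regime rest on supplementary procedure details,
  and our exact-projection values for the unconstrained case differ from
  some published ones even though the $c = 1$ regime agrees to three
  decimals. Conclusions should never be based on this mode — that is the
  point the mode exists to make.
* GORICA rests on a large-sample normal approximation; with very small
  $n$ (or bootstrap distributions pinned to a boundary) the weights
  inherit that approximation error.

## A worked example

```{r example, eval = FALSE}
tab <- load_fixture("degrees")
sp  <- builtin_spec("conditional_row", c(2, 4), row = 2)
hs  <- read_hypothesis_file(
  system.file("extdata", "degrees_hypotheses.txt", package = "goricct"),
  sp$names)
evaluate_set(tab, sp, hs, B = 1000, T = 10000, seed = 7)
```

The README shows the printed output and its reading; the same pipeline is
available from the shell through the `inst/cli/goricct` script
(`evaluate`, `penalty`, `simulate`, `fixtures` subcommands), with every
report embedding the seeds and configuration that produced it.
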