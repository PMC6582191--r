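---
title: "Calibrating unstructured kinetic models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating unstructured kinetic models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model and the data

Batch biodegradation experiments track two variables over time: the
concentration of a limiting substrate $S$ (mg/L) and a proxy for the
degrading biomass — optical density or cell counts — denoted $C$. An
unstructured kinetic model treats the biomass as a single lumped state
$X$ (mg/L) growing at a specific rate $\mu(S, X)$ and dying at a
first-order endogenous decay rate $k_d$:

$$
\frac{dS}{dt} = -\frac{1}{Y}\,\mu X, \qquad
\frac{dX}{dt} = \mu X - k_d X, \qquad
X = b\,C .
$$

$Y$ is the yield of biomass per substrate consumed and $b$ converts the
measured cell signal into a biomass concentration; because $b$ is fitted,
the initial biomass is recomputed as $X_0 = b\,C_0$ inside **every**
objective evaluation, so the initial condition moves consistently with the
candidate parameter vector (the only self-consistent reading of $X = bC$
when $b$ is unknown).

Eight growth laws are registered (`list_models()`), in a fixed 1–8
ordering: Monod, Tessier, Contois, Blackman, Dabes, Powell, Moser,
Heijnen. Monod ($\mu = \mu_{max} S/(K_s+S)$) and Moser
($\mu = \mu_{max} S^n/(K_s+S^n)$) are the canonical forms of this
literature; the other six laws are standard published forms, flagged
`literature_sourced` in the registry with their citation, and the `growth`
function of a spec can be replaced to adopt a different variant. Following
the classic Contois form $\mu = \mu_{max}S/(K_{sx}X+S)$, the Contois
constant is the extra parameter `Ksx`; the core `Ks` slot is kept for
interface uniformity but does not enter that law.

Integration uses `deSolve::lsoda` (adaptive, stiff-capable) driving a
compiled right-hand side, at `rtol = 1e-8`, `atol = 1e-10`, with states
floored at $10^{-12}$. An integrator failure is not an error: the
prediction is penalty-marked and the objectives map it to a large finite
value ($10^{12}$), so global optimizers simply move away from pathological
parameter regions.

## Fitting criteria

All residuals are taken on the $\log_{10}$ scale,
$r_i = \log_{10}(\text{obs}_i) - \log_{10}(\text{pred}_i)$, which places
the two variables on equivalent scales and removes magnitude bias. The
single-objective criterion is the unweighted sum of the two per-variable
sums of squared residuals,
$OF_1 = \mathrm{SSR}_S + \mathrm{SSR}_C$: when models are fitted to
replicate-averaged data the per-variable variance weights are dropped
($\sigma_1=\sigma_2=1$); `of1()` retains an optional `sigma_weights`
argument for users with enough replicates to estimate them. Covariance
between the variables is deliberately ignored (diagonal error model). The
percent contributions dissect the total into its substrate and cell
shares; `pct_cells` is computed as `100 - pct_subs`, so the two shares sum
to 100 exactly, not merely to rounding.

The multi-objective criterion is the vector
$(\mathrm{SSR}_S, \mathrm{SSR}_C)$ minimized jointly. The *extreme
solutions* minimize one component alone; the *compromise solutions* are
the Pareto tradeoffs between them.

The ABC fitness is
$OF_2 = \min_j\{\varepsilon_j - |S_j - \hat S_j|\}$ over the $m = 2$
summary statistics — the per-variable SSRs of the best compromise
solution ($S_j$, observed) versus those of a candidate ($\hat S_j$,
simulated). A candidate is *behavioral* iff $OF_2 \ge 0$. The tolerance
default is $\varepsilon_j = \max(0.05\,S_j,\ 0.01)$: the 5% band ties the
tolerance to the achieved fit quality, and the 0.01 floor keeps the
behavioral region non-degenerate when the compromise fit is essentially
perfect (zero-noise data). Both are configurable and reported in output.

## The three-stage workflow

1. **Global single-objective stage** (`fit_extremes_and_compromise()`).
   A self-adaptive differential evolution (saDE) minimizer locates the two
   extreme solutions and the best compromise solution. The implementation
   follows the classic self-adaptation scheme: per-individual choice
   between `rand/1/bin` and `current-to-best/2/bin` with a success-driven
   strategy probability (sliding window of `lp = 50` generations,
   population 50), crossover rates from an adapting normal memory
   `N(CRm, 0.1)`, scale factor `N(0.5, 0.3)` truncated to $(0, 2]$, and
   reflection at the bounds. Termination mirrors the published run
   conditions: a 500,000-evaluation budget, population objective range
   below $10^{-8}$, or population parameter range below $10^{-2}$ — and
   the termination cause is recorded. Five independent seeded repetitions
   are the default, so the spread of the estimates is part of the result.
   Ties ($f_u = f_x$) replace the incumbent, which lets the population
   drift across flat ridges instead of stalling on them.
2. **Global multi-objective stage** (`fit_mo()`). An elitist
   non-dominated-sorting genetic algorithm (binary tournaments, simulated
   binary crossover $\eta_c = 15$, polynomial mutation $\eta_m = 20$,
   crowding-distance truncation) evolves the front of
   $(\mathrm{SSR}_S, \mathrm{SSR}_C)$. With exactly two objectives,
   reference-direction machinery adds nothing, so NSGA-II-style crowding
   is used deliberately. A cumulative archive of all non-dominated
   solutions is maintained (crowding-pruned above 500 members) and
   returned as the front; its 2-D hypervolume against the initial
   population's worst point is tracked and is non-decreasing by
   construction. The published budget is 20,000 generations at
   $N = 100$; the front on these two-objective problems stabilizes far
   earlier, so desk-scale runs use hundreds of generations.
   `verify_against_so()` then cross-checks stage 2 against stage 1: two
   independent search frameworks agreeing on the compromise total is the
   designed evidence that the compromise region has truly been found.
3. **ABC stage** (`abc_sample()`). Six chains (default) explore the prior
   box with differential-evolution proposals built from a thinned archive
   of past states: $x' = x + \gamma(z_1 - z_2) + \text{jitter}$ with
   $\gamma = 2.38/\sqrt{2d}$ and a 10% fraction of full $\gamma = 1$
   jumps. Acceptance is monotone and likelihood-free: outside the
   behavioral region a candidate is accepted iff its $OF_2$ does not
   decrease (hill-climb into the region); once inside, any behavioral
   candidate is accepted, which yields uniform exploration of the region.
   Convergence is monitored with the Gelman–Rubin statistic
   ($\hat R = \sqrt{(n-1)/n + B/(nW)}$ per parameter on the second half
   of each chain, overall $\hat R$ = max over parameters) against the
   conventional 1.2 threshold. The full production schedule is 150,000
   generations (900,000 model evaluations over 6 chains); the sampler
   scales down freely.

`run_workflow()` chains the stages, derives each stage's seed
deterministically from the master seed, embeds a config hash in every
artifact, and supports `skip_mo = TRUE` (ABC targets the single-objective
compromise instead) as the documented reduced-cost mode.

## Parameter scales, priors, and tunables

Kinetic parameter magnitudes span $10^{-4}$–$10^{3}$, so all searching
and sampling operates on $\log_{10}$-transformed parameters inside the
bound box; results are reported on the natural scale. The uniform ABC
prior is therefore uniform *in the decade scale* — the conventional
uninformative choice for scale parameters. Default bounds are broad
positive boxes per parameter (e.g. $\mu_{max} \in [10^{-4}, 10^2]$ 1/h,
$K_s \in [10^{-4}, 10^3]$ mg/L), overridable everywhere; the Moser/Hill
exponent uses $[0.5, 5]$, outside of which the law degenerates or becomes
implausibly switch-like. Every fitting function accepts `fixed`, a named
list of parameters held at known values — the natural mode when $Y$ or
$b$ are known from independent assays (see the identifiability note
below).

Diagnostics follow the same small-sample realism as the rest of the
design: `residual_report()` gives moments, Shapiro–Wilk (or
Anderson–Darling beyond $n = 5000$) normality, lag-1 autocorrelation
(Pearson correlation of consecutive residuals, so a strictly alternating
vector scores $-1$), and a *descriptive* first-half/second-half variance
ratio. Formal heteroscedasticity test batteries are deliberately omitted:
with 5–10 timepoints they cannot support reliable inference.

## What the synthetic generator emulates — and what it does not

`generate_synthetic()` reproduces the structure of published batch
biodegradation datasets: 8 timepoints (configurable 4–20) spread over 96 h
by default (within the reported 1.3–10-day range), at most a few
replicates (default 3), substrate decay over one or more decades with
sigmoidal biomass growth, and noise that is multiplicative on the natural
scale — each replicate is $\text{truth}\times 10^{\varepsilon}$,
$\varepsilon \sim N(0, 0.05)$ by default — i.e. additive and
homoscedastic on the $\log_{10}$ scale, matching the objective's error
model exactly. What it does **not** emulate: detection-limit censoring,
sampling-time irregularity, correlated errors between the two variables,
and noise that is additive on the natural scale (real instruments are
usually somewhere between the two models). Passing tests on this
generator therefore demonstrate correctness of the machinery and
recoverability under the assumed error model, not robustness to
misspecified noise.

The worked examples use Moser truth
$(\mu_{max}, K_s, Y, k_d, b, n) = (0.1\ \text{1/h}, 20\ \text{mg/L},
0.4, 0.005\ \text{1/h}, 2, 1.5)$ with $S_0 = 50$ mg/L, $C_0 = 0.05$:
substrate falls three decades over four days while the cell signal rises
two — dynamics representative of the published experiments.

## A structural identifiability finding: only $Y/b$ is identifiable

For every registry law whose rate depends only on $S$ (all except
Contois), the scaling $(Y, b) \to (\alpha Y, \alpha b)$ leaves **both**
predicted observables exactly invariant: $X_0 = bC_0$ and the linear $X$
dynamics scale by $\alpha$, the substrate equation is untouched because
$X/Y$ is unchanged, and $C = X/b$ cancels the scaling. Only the ratio
$Y/b$ is identifiable from $(S, C)$ data — verified numerically in this
package to $10^{-15}$. Consequently no optimizer, however good, can pin
$Y$ and $b$ individually: across seeded repetitions both wander along the
ridge (with their ratio reproduced to $\sim 10^{-3}$%), and their
cross-repetition spread is orders of magnitude larger than that of
$\mu_{max}$, $K_s$, $k_d$ or $n$. The acceptance suite asserts full
six-parameter recovery and its $Y$/$b$ expectations fail for exactly this
reason; the package treats that as a property of the model class worth
surfacing, not as a defect to be hidden by tightened bounds. The
practical remedies are to fix $b$ (or $Y$) from an independent
calibration via `fixed`, or to report $Y/b$.

## Numerical choices and degenerate inputs

* Predictions are floored at $10^{-12}$ before $\log_{10}$; observations
  must be strictly positive (validated with the offending row cited).
* A zero total objective makes percent contributions undefined; the
  50/50 convention is used and flagged `degenerate`.
* Compromise selection (`select_compromise()`): objectives are min–max
  normalized over the front and the member nearest the normalized ideal
  point is returned, with lexicographic tie-breaks; a single-member front
  is returned flagged. On *strongly asymmetric* fronts — one SSR spanning
  decades while the other barely moves, which happens when one variable
  hardly constrains the fit — any normalized-geometry rule becomes
  unreliable: the selected member can have a poor absolute fit of the
  wide-ranging objective. The stage-1/stage-2 verification is the
  designed safeguard (a large relative gap triggers a warning before the
  ABC stage), and the front CSV export lets the analyst choose a member
  by inspection.
* The SO/MO relative gap is reported as
  $|T_{MO}-T_{SO}|/\max(T_{SO}, 10^{-12})$; on zero-noise data both
  totals approach zero and the *relative* gap is ill-conditioned —
  compare absolutely there.
* Gelman–Rubin with all-constant identical chains returns 1 (no spread at
  all); constant-but-offset chains return `NA` with a warning rather than
  a spurious finite value.
* Mean-parameter traces (`chain_mean_trace()`) are assessed for
  stabilization on the $\log_{10}$ sampling scale; on the natural scale
  the mean of a decade-spanning parameter is dominated by its upper range.

## Problem sizes used in the tests

The suite runs entirely on synthetic data generated at test time. Unit
tests use restricted two-parameter problems (thousands of ODE solves);
the acceptance-style checks use the full published algorithmic settings
where they are cheap (6 chains, termination tolerances, 5 repetitions)
and scaled-down budgets where they are not: 100,000 saDE evaluations per
repetition for the six-parameter recovery, a $200\times200$ log-spaced
brute-force grid as the optimizer oracle, 1,000 NSGA generations at
population 40 for the front cross-checks, and 20,000 ABC generations for
the convergence/coverage check. The full production budgets (500,000
evaluations; 20,000 generations at $N = 100$; 150,000 ABC generations)
remain the package defaults.

## Known limitations

* One representative algorithm per stage (saDE / NSGA-II-style /
  ABC-with-DE-proposals); multi-method ensembles and their restart
  machinery are out of scope.
* The ABC sampler's monotone acceptance yields uniform sampling of the
  behavioral region, not a tempered posterior; near the $\varepsilon$
  boundary, samplers with annealed tolerances may shape the posterior
  differently.
* Batch operation only (no fed-batch/chemostat), no inhibition laws, no
  temperature/pH dependence, no censoring.
* The predictive band widens the parameter band by a single pooled
  residual scale; with replicate-rich data a per-variable (or per-point)
  noise model would be preferable.
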