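---
title: "Bounded causal capacity models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bounded causal capacity models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalcap)
```

## The model

`causalcap` represents an effect variable with value range $[-L, U]$ and
baseline $0$, influenced by quasi-independent causal capacities. Each cause
is inactive at value $0$, takes values in $[0, M]$, and carries a strength
$w \ge 0$ interpreted as the *expected change* in the effect per one-unit
increase of the cause from its inactive state, with every other cause
inactive. Three roles exist:

* a **generator** pushes the effect up toward $U$,
* a **reducer** pushes it down toward $-L$,
* a **blocker** acts as a probabilistic switch that, when active, prevents
  every other capacity from influencing the effect; its $w$ is the per-unit
  increase in the probability of complete blocking.

The conditional expectation of the effect given cause values is

$$
\mathbb{E}(E) \;=\; \prod_k (1 - w_k b_k)\left[
  U\!\left(1 - \prod_i \frac{U - w_i g_i}{U}\right) -
  L\!\left(1 - \prod_j \frac{L - w_j r_j}{L}\right)\right].
$$

The generator bracket is the noisy-OR combination carried to the $[0, U]$
scale: normalize contributions to $[0, 1]$, combine by
$1 - \prod(1 - \cdot)$, and scale back. Reducers are negative generators
normalized against $L$; blockers multiply the whole bracket by the
probability that none of them fires.

Two distinctions matter and are encoded in the types. First, the **baseline
is not the lower bound**: $L = 0$ means they coincide, $L > 0$ means the
effect can be driven below its resting value. Second, **blocking is not
reducing**: a blocker keeps the effect near baseline by eliminating other
influences, a reducer actively moves it toward the lower bound. The two are
observationally indistinguishable only in the binary case where baseline
and lower bound coincide.

### Assumptions behind the accumulation rule

Because causes are assumed quasi-independent, their contributions
$x = w g$ accumulate through a two-argument function $f(x, y)$ that should
be symmetric and associative (order of incorporation cannot matter),
deterministic, produce no uncaused effect ($f(0,0) = 0$), leave a lone
contribution unchanged ($f(x, 0) = x$ — this is what makes $w$ readable as
an expected change), and saturate at the bound ($f(U, U) = U$). Among
finite polynomials these conditions leave exactly one solution,

$$ f(x, y) = x + y - \frac{xy}{U}, $$

which is the noisy-OR rule at $U = 1$. A further *smooth accumulation*
property — any increase in any argument strictly increases the result
whenever it is below $U$ — separates this rule from MAX-type accumulation,
which ignores the smaller argument; whether smoothness can replace the
polynomial restriction in the uniqueness result is an open question, and the
package takes no position on it: `run_axiom_suite()` simply lets users
submit candidates and see which conditions fail.

## The axiom engine and the uniqueness solver

Axioms are analytic statements; the engine verifies them **numerically on
finite grids**, defaulting to 21 points per axis (11 for the cubic-cost
associativity triples) with absolute tolerance $10^{-9}$. Products of many
near-one factors accumulate rounding error, which the single configurable
tolerance absorbs. Every failure report carries the first concrete
counterexample found, so reports are self-verifying; a pass never carries
one. Determinism is recorded as satisfied structurally — any side-effect-free
evaluator maps equal inputs to equal outputs — because no dynamic test can
distinguish it. Closure ($f$ mapping $[0,U]^2$ into $[0,U]$) is reported
separately from associativity: plain addition is associative as a map on the
reals while escaping the bounded range, and conflating the two would
misattribute its one genuine failure (saturation).

`solve_unique_polynomial()` verifies uniqueness by brute force. It
parametrizes a symmetric polynomial of total degree $\le d$ with
$f(x, 0) = x$ built in structurally (constant term 0, linear coefficients 1,
pure powers $x^i$, $i \ge 2$, absent), then solves the saturation constraint
plus associativity residuals on all corner triples of $\{0, U\}^3$ and 50
seeded pseudo-random interior triples by Levenberg–Marquardt least squares
from 8 random starts. Polynomial identities that hold on enough generic
points hold identically, so a near-zero residual certifies associativity at
that degree cap.

Two numerical facts shaped the implementation:

* **A quartically flat valley.** At degree cap 4 the associativity operator
  has a near-kernel direction, the symmetric quartic
  $xy(1 - x/U)(1 - y/U)$: perturbing the solution along it violates
  associativity only at second order, so the summed squares behave like
  $t^4$ along the valley and Gauss–Newton stalls around $10^{-4}$ from the
  solution. Each converged start is therefore polished with a
  derivative-free Nelder–Mead descent of the summed squares, which reaches
  a few $10^{-7}$.
* **Cluster resolution for the uniqueness flag.** Independently converged
  starts can only be expected to agree to $\varepsilon^{1/4} \approx
  1.2\times 10^{-4}$ (scaled by $1/U$, like the coefficients) in a
  quartically flat minimum — the analogue of the familiar
  $\sqrt{\varepsilon}$ bound for quadratic minima. The uniqueness flag uses
  that bound for clustering; coefficient agreement with $x + y - xy/U$ is
  much tighter in practice (below $10^{-6}$ at all tested degree caps and
  bounds).

## Special-case reductions

The package verifies numerically, not symbolically, that the bounded
equation contains the classical forms:

* **Binary noisy-OR/AND.** At $L = 0$, $U = 1$ with binary causes and no
  reducers, the equation *is* the noisy-OR/AND probability; both sides are
  evaluated over exhaustive binary assignments (up to $2^{10}$; seeded
  sampling beyond) and agree at rounding level ($\le 10^{-12}$).
* **Linear and noisy-addition limits.** "Infinite bounds" are verified as
  limits over finite bound sequences, default $U, L \in \{10, 100, 1000,
  10^4\}$, keeping the engine purely numeric. The two-generator case anchors
  the rate analytically: $U(1 - (1 - x/U)(1 - y/U)) = x + y - xy/U$, so the
  discrepancy from linearity is exactly $xy/U$ — convergence is $O(1/U)$,
  and the verifiers additionally check monotone decrease and fit the
  envelope constant $C$ in $C/\min(U, L)$.
* **Signed values.** The finite-bound machinery requires nonnegative cause
  values in $[0, M]$, because the normalized product factors must stay in
  $[0, 1]$. Signed contributions are meaningful only in the unbounded linear
  regime and are accepted only by `linear_expected_effect()`.

Saturation at the bound ($f(\mathbf M) = U$) is exactly attained only when
some $w_i M_i = U$; models with all $w_i M_i < U$ approach it from below.
The generative-accumulation check is therefore a boundary property: the
axiom engine tests it at the two-argument realization $f(U, U) = U$, and
model validation merely caps $w M$ at the relevant bound.

## Synthetic data: what it emulates, and what it does not

The model specifies only the conditional expectation; observation noise is
the package's choice, made so each family's support matches its effect
range (the mean-parametrization makes the capacity equation the regression
function in every case):

| family | support | effect range | dispersion |
|---|---|---|---|
| `bernoulli` | $\{0, 1\}$ | $L = 0$, $U = 1$ | — |
| `scaled-beta` | $(-L, U)$ | finite bounds | Beta precision $\alpha + \beta$, default 10 |
| `gaussian` | $\mathbb{R}$ | unbounded (linear form) | sd |

Means exactly at a Beta endpoint are clamped $10^{-9}$ into the interior
before parametrization; the Beta is degenerate there and the clamp sits
below every tolerance used in the package.

The trial **design** is the presence/absence scheme of standard
causal-learning experiments: each cause independently at `max_value` with
probability 0.5 (configurable), with always-present background causes
represented literally as a cause clamped to its maximum in every trial —
never as a special intercept — so the binary model's semantics stay exact.
`generate_value_sequences()` reproduces the three numeric framings of the
same functional information used to cue variable-type interpretations: exact
$\{0, 1\}$ values; tight jitter around 0 and 1 (sd 0.02, so the rounded
pattern is preserved with overwhelming probability); and near-zero "off"
values (sd 0.03) against a wide "on" level ($\mathcal N(15, 2)$ — matching
the magnitude of illustrative values like 17.32, with only two functionally
distinct levels). Thresholding at half the functional gap recovers the
generating pattern in every regime.

What passing these simulations does **not** show about real data: real
causal-learning responses involve judgment noise, probe-question effects,
and participant heterogeneity in assumed functional form, none of which the
generator models (judgment predictions are point predictions). The
synthetic trials are exchangeable given the cause values, with
correctly-specified noise; real data are neither guaranteed.

## Estimation

`fit_weights()` estimates strengths by bound-constrained optimization:
negative Bernoulli log-likelihood for binary effects (success probabilities
clamped to $[10^{-12}, 1 - 10^{-12}]$), least squares on the conditional
mean for the continuous families (for Gaussian noise this is the ML
estimate of the mean structure). Each strength lives in the box its role
dictates — $[0, U/M]$, $[0, L/M]$, or $[0, 1/M]$ — enforced by L-BFGS-B.
Because the likelihood can be multi-modal with correlated causes, the
optimizer restarts from 5 seeded random points plus the box midpoint; the
best objective wins, ties broken by the first start found. A final
Nelder–Mead polish is applied because L-BFGS-B's relative-improvement stop
can terminate within $\sim 10^{-6}$ of the optimum, which is visible when
the fit is compared against closed forms: on aggregated single-cause binary
data with an always-present background, the ML fit coincides with the
causal-power estimator $\Delta P / (1 - P(e \mid \neg c))$, and the package
tests that identity at $10^{-6}$.

Identifiability is flagged narrowly: a cause whose column is constant **at
zero** never enters the mean and is reported unidentifiable (`NA`). A cause
constant at a nonzero value — the explicit background cause — is estimable
from the shift it induces and is fitted normally.

Only the generative contingency estimators are provided in closed form
(`delta_p`, `causal_power`); preventive variants are out of scope, and
reducers are handled by `fit_weights()` instead. A preventer that targets
one specific generator is not a separate role: it is equivalent to lowering
that generator's strength, and the package documents rather than implements
it.

## Degenerate inputs and numerical conventions

* $L = 0$ with reducers (or $U = 0$ with generators) is a **validation
  error**, not a silent no-op: the normalizing division is undefined.
* Constraint violations ($wM$ above the relevant bound, assignment values
  outside $[0, M]$) raise errors rather than clamping — clamping would
  silently change the model.
* Empty generator (or reducer) sets contribute a bracket of 0 (empty
  product = 1), so a causeless model predicts the baseline.
* All file output uses 12 significant digits, below every tolerance here;
  infinity is spelled `"inf"` in model files to stay JSON-safe.
* Every stochastic routine takes an explicit integer seed and reproduces
  its output bit-for-bit; derived sub-seeds (in `recovery_experiment()`)
  stay below $2^{31}$.

## Problem sizes

The shipped tests and verification drivers use sizes chosen to make
sampling error negligible relative to the quantities checked while staying
comfortably interactive: exhaustive binary enumeration up to $2^{10}$
assignments, $10^5$ trials for conditional-mean checks (asserted within 4
standard errors), 20 000 trials for two-parameter recovery (binomial
sampling error $\approx 0.007$, asserted within $\pm 0.05$), recovery grids
$n \in \{10^2, 10^3, 10^4\}$ with 3 replicates, and the polynomial solver at
degree caps 2–4 with $U \in \{0.5, 1, 2\}$.

## Known limitations

* Uniqueness of the combination polynomial is certified at bounded degree
  (caps 2–4 by default); the unbounded-degree statement is not proved here.
* The smoothness-only uniqueness conjecture is neither proved nor refuted;
  the axiom engine only falsifies candidates.
* Within a single blocker the blocking probability is linear in its value
  ($w b$); a nonlinear within-blocker dose response would need the same
  rescaling treatment as nonlinear generators (`linearize_cause()`, which
  takes the monotone transform as given rather than estimating it).
* No multi-effect networks: one effect node, no graph machinery.
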