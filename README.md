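# causalcap

Causal capacity models with bounded effect ranges: evaluation, axiom
checking, simulation, and strength estimation.

## The problem

In human causal cognition and in machine-learning models of causal systems,
two functional forms dominate how independent causes are assumed to combine
into an effect: the **noisy-OR/AND** family (probabilistic "or" of binary
causes, gated by preventers) and **linear** combination (contributions
simply add, as in the ΔP and Rescorla–Wagner traditions). These look like
competing theories, and experiments find people using both.

`causalcap` implements the unifying view: both are special cases of a
single privileged expected-effect equation for an effect with value range
[−L, U] and baseline 0, driven by quasi-independent causal capacities of
three kinds —

* **generators** push the effect up toward U,
* **reducers** push it down toward −L,
* **blockers** probabilistically switch off all other causal influence.

With generator values gᵢ and strengths wᵢ (expected change in the effect
per unit of cause, all else inactive), reducers (rⱼ, wⱼ) and blockers
(bₖ, wₖ):

```
E(E) = Π_k (1 − w_k b_k) · [ U(1 − Π_i (U − w_i g_i)/U)
                           − L(1 − Π_j (L − w_j r_j)/L) ]
```

At L = 0, U = 1 with binary causes this is exactly the noisy-OR/AND model
(causal power theory); as L, U → ∞ it converges to the blocked linear form
Π(1 − w_k b_k)·(Σ w_i g_i − Σ w_j r_j). The underlying two-argument
accumulation rule

```
f(x, y) = x + y − xy/U
```

is the *unique* finite polynomial that is symmetric, associative, leaves a
lone contribution unchanged (f(x, 0) = x), produces no uncaused effect, and
saturates at the bound (f(U, U) = U). The package verifies all of this
numerically: an axiom-checking engine for candidate combination functions,
a brute-force polynomial solver for the uniqueness claim, and reduction
verifiers for the special cases. A simulation/estimation layer generates
synthetic causal-learning trial data (binary, narrow-continuous, and
wide-continuous value-range regimes) and recovers strengths by
bound-constrained maximum likelihood, alongside the classic ΔP and
causal-power contingency estimators.

## Worked example

A heart-rate model on the range [−2, 10] (baseline 0 = resting rate):
exercise and caffeine raise it, an anesthetic actively lowers it, a beta
blocker switches other influences off with probability w·b.

```r
library(causalcap)

hr <- capacity_model(
  effect_range(2, 10),   # magnitudes: lower bound -2, upper bound 10
  list(cause("exercise",    "generator", 2,   max_value = 3),
       cause("caffeine",    "generator", 1,   max_value = 5),
       cause("anesthetic",  "reducer",   0.5, max_value = 4),
       cause("betablocker", "blocker",   0.5, max_value = 1)))

expected_effect(hr, c(exercise = 3, caffeine = 5, anesthetic = 2, betablocker = 1))
#> [1] 3.5
expected_effect(hr, c(exercise = 1.5, caffeine = 0, anesthetic = 0, betablocker = 0))
#> [1] 3
```

The first value: generators contribute 10(1 − (4/10)(5/10)) = 8, the
anesthetic pulls 2(1 − 1/2) = 1 the other way, and the beta blocker lets
influence through with probability 0.5 → 0.5·(8 − 1) = 3.5. The second
shows the strength semantics: a lone generator contributes w·g = 2·1.5 = 3.

Axiom checking separates the accumulation rules:

```r
run_axiom_suite(builtin_combination("max"))
#> Axiom report for noisy-MAX (U = 1, grid 21, tol 1e-09)
#> symmetry                 pass
#> associativity            pass
#> determinism              pass
#> no_uncaused_effects      pass
#> distinct_causal_effect   pass
#> generative_accumulation  pass
#> smooth_accumulation      fail
#>   counterexample at (0.00, 0.05, 0.01): lhs = 0.05, rhs = 0.05
```

MAX ignores an increase in the smaller argument — exactly the smoothness
failure. The uniqueness solver recovers the privileged coefficients from
the axioms alone:

```r
solve_unique_polynomial(3, U = 1)
#> Polynomial solution (degree <= 3, U = 1): residual 4.07e-31, unique across 8 converged starts
#>   a_1_0 = 1
#>   a_1_1 = -1     # i.e. f(x, y) = x + y - xy
```

Simulation and recovery:

```r
m   <- capacity_model(effect_range(0, 1),
                      list(cause("a", "generator", 0.3),
                           cause("b", "generator", 0.6)))
tab <- simulate_trials(m, noise_spec("bernoulli"), design_bernoulli(0.5),
                       20000, seed = 106)
fit_weights(tab, m, noise_spec("bernoulli"), seed = 106)
#> Strength estimates from 20000 trials (converged):
#>   a            0.297353
#>   b            0.599813
#>   objective: 9412.69

causal_power(contingency_table(80, 20, 20, 80))  # noisy-OR/AND judgment
#> [1] 0.75
delta_p(contingency_table(80, 20, 20, 80))       # linear judgment
#> [1] 0.6
```

The two judgment estimators agree exactly when the background rate
P(e | ¬c) is zero and diverge otherwise — the observable signature of which
functional form a reasoner assumes.

## Command line

A thin wrapper over the same functions is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "causalcap.R", package = "causalcap"))')" \
  check-axioms --function max --U 1
```

Subcommands: `evaluate`, `simulate`, `fit`, `check-axioms`,
`verify-reductions`. Model files are JSON or YAML (`effect_range` with
`lower`/`upper`, `"inf"` for infinity; `causes` with `label`, `role`,
`strength`, `max_value`); trial data are plain CSV.

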