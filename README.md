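# l1mrl — penalized multistage ramp loss learning for dynamic treatment regimens

`l1mrl` estimates optimal multistage dynamic treatment regimens (DTRs) and
selects the tailoring variables **simultaneously across all stages**.  For
a cohort with per-stage histories `H_t`, binary treatments `A_t ∈ {-1,+1}`,
assignment probabilities `p(A_t|H_t)` and a terminal reward `Y`, it
maximizes an inverse-probability-weighted multistage ramp surrogate of the
regimen value

    (1/n) Σᵢ [ wᵢ⁺ · min_t ψ(A_it g_t(H_it)/η)
             + wᵢ⁻ · Σ_{a≠A_i} min_t ψ(a_t g_t(H_it)/η) ]
      − λ Σ_p ω_p Σ_t |β_tp|,        ψ(x) = max(min(x, 1), 0),

over linear decision rules `g_t(H_t) = O_t'β_t + W_t'α_t + γ_t`, where
`wᵢ± = Yᵢ± / Π_t p(A_it|H_it)` and the adaptive group-lasso weights
`ω_p = (Σ_t β̃_tp²)^{-1/2}` pool a pilot estimate across stages, so a
feature is eliminated exactly when it matters at **no** stage.  The
nonconvex objective is minimized by a difference-of-convex (DC) algorithm
whose convex subproblems are solved by cyclic coordinate descent with exact
piecewise-linear line search; `(λ, η)` are tuned by twofold cross-validation
of an AIC-type criterion.  The package also implements the sequential
comparison learners built from the same ingredients — lasso-penalized
Q-learning, L1-penalized outcome-weighted learning solved as exact linear
programs, and augmented outcome-weighted learning (AOWL, which doubles as
the pilot) — plus a two-scenario SMART-style simulation benchmark with
Monte-Carlo value evaluation and selection-accuracy metrics (FN/FP/FDR,
Jaccard stability), and a stabilized IPW value estimator for observational
data.

Intended users: biostatisticians and methods researchers working on
individualized treatment rules over a small number of decision stages
(2–4), with moderate cohort sizes (hundreds of subjects).

## Worked example

Simulate a two-stage cohort from benchmark Setting 1 (reward linear in the
five true tailoring variables `Z1, Z2, Z7, Z8, X1` out of 15 candidates per
stage), fit the tuned regimen, and evaluate it:

```r
library(l1mrl)
set.seed(101)
cohort <- generate_cohort(simulation_config(setting = 1, n = 200))
fit <- fit_l1mrl(cohort)
fit
#> Penalized multistage ramp regimen
#>   selected lambda = 1024, eta = 0.0001
#> Linear dynamic treatment regimen coefficients
#>   stage 1: 6/15 penalized features selected; intercept -9.134e-06
#>   stage 2: 5/15 penalized features selected; intercept 0.0001575

selection_metrics(fit)
#>   stage FN FP        FDR
#> 1     1  0  1 0.06666667
#> 2     2  0  0 0.00000000

true_value(fit, setting = 1, n_test = 5000, seed = 999)
#> [1] 8.446467
```

The fit keeps all five truly important variables at both stages (FN = 0)
with a single false positive, and its Monte-Carlo testing reward (8.4) sits
close to the oracle rule's (about 10.1) and far above any one-size-fits-all
rule (at most about 1.1 on this scenario).  `predict(fit, newdata)` returns
recommended treatments for raw-scale data, and the comparison learners
(`fit_l1_qlearning()`, `fit_l1_olearning()`, `fit_aowl()`) share the same
dataset containers, metrics and evaluation tools.  `run_replications()`
drives whole seeded replication studies, and a command-line front end
(`inst/cli/l1mrl.R`) exposes `simulate`, `fit`, `evaluate` and `benchmark`
for shell use.

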