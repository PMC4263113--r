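# invbif — inverse bifurcation analysis of bistable mass-action networks

Bistable biochemical switches — substrate-inhibited enzyme cascades,
mutually repressing gene pairs — show hysteretic dose-response curves: as a
stimulus is ramped up and down, the measured steady state jumps at two
different stimulus values. Those two saddle-node (limit point) bifurcations
can be located experimentally, and they carry a lot of information about
the kinetics. `invbif` is a toolbox for researchers in systems biology who
want to *invert* that information: given a mass-action reaction network of
known structure and the measured limit-point locations (plus the species
concentrations there), infer the kinetic rate constants, characterize which
parameters and parameter combinations are identifiable, and propagate
measurement noise into confidence intervals.

The method rests on Chemical Reaction Network Theory. With complexes as
graph nodes, the balance equations are `ċ = Y A ψ(c)` where
`ψ_j(c) = ∏ c_i^{y_ij}`. On the equilibrium locus the complex flux lies in
the deficiency subspace `Ker(Y) ∩ Im(A)` (dimension `δ = n − ℓ − s`),
giving the equilibrium manifold `H_s(c, α; k) = 0` of dimension
`λ = m − s`. Steady states are intersections of the manifold with a
stoichiometric compatibility class `B^T c = b`; a limit point is a
*tangency* between the two, which holds exactly when

```
det G = 0,   G = | D_c H_s   D_α H_s |
                 |   B^T        0    |
```

The inverse problem then becomes box-constrained optimization with
algebraic constraints — no ODE integration and no bifurcation diagram
inside the loop: find `k, α^l, α^u` such that `det G = 0` at both observed
limit points while `B^T c = b` and `Q c = q` match the measurements.

## What's inside

| Stage | Functions |
| --- | --- |
| Network + structure | `parse_network`, `parse_network_text`, `structural_summary` (Y, N, Λ, B, ω, ℓ, t, s, δ, λ) |
| Manifold + tangency | `manifold_system`, `manifold_residual`, `solve_manifold_point`, `dc_dalpha`, `tangency_matrix` |
| Continuation | `trace_branch`, `detect_limit_points`, `dose_response` |
| Inverse estimation | `inverse_problem`, `solve_error_free`, `solve_noisy`, `polish_estimate` |
| Identifiability | `explore_viable_region`, `viable_ranges`, `propose_identifiable_combinations` |
| Uncertainty | `generate_noisy_data`, `fit_observation_distribution`, `sample_observations`, `estimate_distribution` |
| Worked networks | `protein_activation_fixture`, `toggle_switch_fixture`, `synthetic_bistable_fixture` |

A thin command-line wrapper lives at `inst/cli/invbif.R`
(`analyze`, `continue`, `infer`, `simulate-data`, `mc` subcommands).

## Worked example

The genetic toggle switch: two genes repress each other (cooperative
two-step binding of repressor P1 to gene G2), the dose is the P2
degradation constant `k7_13`, and the hysteretic response was observed to
jump at `k7_13 = 0.86` and `2.96` with gene totals 0.16605.

```r
library(invbif)

fx <- toggle_switch_fixture()
fx$summary
#> CRNT structural summary
#>   species m = 7, complexes n = 13, reactions r = 10
#>   linkage classes l = 6, terminal strong l.c. t = 6
#>   stoichiometric subspace dim s = 5
#>   deficiency delta = n - l - s = 2
#>   manifold dimension lambda = m - s = 2
#>   conservation laws:
#>      G1 + G1P2
#>      G2 + G2P1 + G2P1P1

problem <- fixture_problem(fx, seed = 7)
est <- solve_error_free(problem)     # a few minutes on one core
signif(est$k, 4)
#>     k1_8    k3_10     k4_9     k9_4    k5_11    k11_5    k6_12    k12_6
#> 100.0000 993.2000   0.9987   1.0010   9.9670   0.1003   1.0010   1.0030
#>    k2_13    k7_13
#>   6.0130   0.8600

# self-consistency: continuation of the estimate reproduces the folds
lps <- estimate_limit_points(fx, est)
sort(sapply(lps, `[[`, "stimulus"))
#> [1] 0.860000 2.960009
```

The recovered decay constant of P1 is `k2_13 ≈ 6.0` and the expression
rate of P2 is `k3_10 ≈ 993`; binding pairs are identifiable only through
their ratios (`k4_9/k9_4 ≈ 1`, `k5_11/k11_5 ≈ 99` — strong cooperativity
of the second repressor binding), and the final regularized pass reports
the smallest-magnitude representative along those flat directions.
Re-running the continuation at the estimate puts the folds at 0.86000 and
2.96001 — the inversion is self-consistent to five digits.

For uncertainty, `generate_noisy_data()` produces replicates with 10%
proportional normal noise, `fit_observation_distribution()` +
`sample_observations()` + `estimate_distribution()` re-estimate per draw
and return percentile confidence intervals and parameter correlations.

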