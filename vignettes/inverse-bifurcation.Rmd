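---
title: "Inferring kinetic parameters from the limit points of hysteretic dose responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring kinetic parameters from the limit points of hysteretic dose responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invbif)
```

## The problem

Bistable biochemical switches convert a graded stimulus into an
all-or-none response. Experimentally the signature is a hysteretic dose
response: as the stimulus (a total protein amount, or a tunable rate
constant such as a degradation rate) is ramped up and down, the measured
steady state jumps at two different stimulus values. Those two values are
the saddle-node (limit point, LP) bifurcations of the underlying kinetic
model, and they are among the most information-dense quantities a titration
experiment can deliver. `invbif` turns this around: given the measured
location of the two limit points and the species concentrations there, it
infers the rate constants of a mass-action model of known structure.

The leverage comes from Chemical Reaction Network Theory (CRNT). For a
mass-action network the balance equations can be written
$\dot c = Y A \psi(c)$ with $Y$ the molecularity matrix of the complexes,
$A$ the rate-constant-weighted graph matrix and
$\psi_j(c) = \prod_i c_i^{y_{ij}}$ the complex monomials. At equilibrium
the complex flux $A\psi(c)$ lies in the deficiency subspace
$D_\delta = Ker(Y)\cap Im(A)$, whose dimension is the deficiency
$\delta = n - \ell - s$ ($n$ complexes, $\ell$ linkage classes, $s$ the
rank of the stoichiometric subspace). Writing
$A\psi(c) = \sum_{i=1}^\delta \alpha_i\omega_i$ in a basis
$\omega$ of $D_\delta$ gives the *equilibrium manifold*
$\mathcal H_s(c, \alpha; k) = 0$, a system of $n-\ell$ independent
equations in the concentrations and the deficiency parameters $\alpha$,
whose solution set has dimension $\lambda = m - s$. Steady states are the
intersections of this manifold with the stoichiometric compatibility class
$\{c \ge 0: B^T c = b\}$ ($B$ spans the conservation laws). A limit point
is exactly a *tangency* between the manifold and the class, which holds iff

$$\det G = 0, \qquad
G = \begin{pmatrix} D_c\mathcal H_s & D_\alpha\mathcal H_s \\ B^T & 0 \end{pmatrix}.$$

$G$ is square of size $m + \delta$. This purely algebraic condition lets
the inverse problem be solved without ever integrating the ODEs or
re-computing a bifurcation diagram inside the optimization loop.

## What the package computes

* `structural_summary()` derives $Y$, $N$, $\Lambda$, the terminal strong
  linkage classes, $\ell, t, s, \delta, \lambda$, an integerized basis $B$
  of the conservation laws and a basis $\omega$ of the deficiency subspace.
  Only networks with $t = \ell$ are supported; others are refused, since
  the tangency theory is stated for that class (which includes all weakly
  reversible networks).
* `manifold_system()` realizes $\mathcal H_s$ as the projection
  $U^T(A\psi - \omega\alpha)$ with $U$ an orthonormal basis of $Im(A)$.
  For $t=\ell$ networks $Im(A)$ equals the span of the incidence vectors
  of the graph of complexes and is therefore independent of $k$: the
  projector is computed once per network. Any other choice of $n-\ell$
  independent rows has the same zero set; the projection merely fixes a
  well-conditioned representative. Jacobians are analytic
  ($\partial\psi_j/\partial c_i = y_{ij}\psi_j/c_i$); finite differences
  appear only as test oracles.
* `trace_branch()` / `detect_limit_points()` / `dose_response()` follow
  equilibrium branches against a stimulus. For a conservation-constant
  stimulus on a $\delta=\lambda=1$ network, continuation runs natively in
  $\alpha$ (the manifold's own coordinate, monotone through folds); in
  every other case (rate-constant stimuli, $\delta=\lambda=2$) a standard
  pseudo-arclength predictor–corrector runs on $[\mathcal H_s; B^Tc - b]$
  with the stimulus appended as an unknown. Folds are bracketed by the
  sign reversal of the stimulus increment and refined by bisection on the
  equilibrated $\det G$, which changes sign across each fold. Stability is
  inferred from branch geometry (the segment between the folds is the
  unstable one), which suffices for dose-response synthesis and is far
  cheaper than eigenvalue classification.
* `solve_error_free()` solves the inverse problem: find $k$ (and
  $\alpha^l, \alpha^u$) such that the manifold is tangent to the two
  classes fixed by the observed limit points while reproducing the
  observed concentrations. `solve_noisy()` minimizes
  $w_1 J_1 + w_2 J_2$ ($J_1$: squared tangency determinants; $J_2$:
  squared observation residuals) for one noisy observation draw, and
  `estimate_distribution()` wraps the Monte Carlo loop: fit normals to
  replicates, draw $M$ observation vectors, re-estimate per draw
  (warm-started), summarize with percentile confidence intervals and
  correlations.
* `explore_viable_region()` characterizes the parameter sets compatible
  with the observations below a ladder of cost thresholds, and
  `propose_identifiable_combinations()` screens the samples by PCA for
  locally identifiable parameters and parameter ratios. The screen is
  explicitly local and heuristic.

## Numerical strategy of the inverse solver

The decision vector is $p = (\log_{10} k_{free}, \alpha^l, \alpha^u)$
(plus pinned concentration coordinates when $\lambda > \delta$), of
dimension $r_{free} + 2\lambda$. The manifold equalities are never handed
to the optimizer: given $(\alpha, k)$, the concentrations are recovered by
a damped, positivity-safeguarded Newton solve of
$\mathcal H_s(\cdot,\alpha;k)=0$ (square for $\delta=\lambda$), so the
search is box-constrained.

The search itself has two phases. A seeded differential-evolution phase
explores the box (rate constants in $\log_{10}$, default bounds
$[10^{-4}, 10^4]$; $\alpha$ bounds inferred from a preliminary sweep in
which random moderate rate draws are combined with concentrations
completed from the observations). Half of the initial population is
seeded data-consistently: concentrations completed from the observations
and $\alpha$ set to the least-squares deficiency coordinates of the
complex flux. The best members then enter a Levenberg–Marquardt
refinement over the *full* variable set
$(\log_{10}k_{free}, \alpha^l, \alpha^u, \log c^l, \log c^u)$ in which
the mutually consistent equation block — manifold residuals, the
stimulus-class constraints $B^Tc=b$, and the two tangency determinants —
is escalated through a weight ladder $(3, 10^2, 10^4, 10^6, 10^8)$ while
the concentration observables $Qc=q$ stay at unit weight.

That split is deliberate. Published observable tables are rounded, and
rounding generically makes the *complete* equality system infeasible: for
the protein-activation example the shipped observables are mutually
inconsistent at about the 1% level (see below), so a solver that treats
every equation as exact must park the misfit somewhere. Escalating the
consistent block reproduces the stimulus coordinates of the limit points
to printed precision — the quantity the method exists to invert — and
lets the rounding error land in the least-consistent concentration
observable. On exactly consistent (synthetic) data all residuals fall to
machine precision and the distinction is invisible. A final regularized
pass pulls non-identifiable rate-constant directions (e.g. the common
scale of a binding/unbinding pair whose ratio alone is determined) toward
the smallest-magnitude representative without degrading the fit; all
within-tolerance optima are equivalent along such flat directions.

Degenerate pseudo-solutions at the corners of the box (where $\det G$
vanishes because $D_c\mathcal H_s$ itself becomes singular) are detected
by the conditioning of $D_c\mathcal H_s$ and rejected; a genuine fold has
a singular $G$ but a well-conditioned $D_c\mathcal H_s$. The determinant
is always evaluated after row/column max-norm equilibration, so tangency
tests do not depend on concentration units.

Key tolerances: Newton residual $10^{-10}$ (relative to the complex-flux
scale), numerical rank decisions at $10^{-10}$ times the leading singular
value, fold refinement to $|\det G| < 10^{-6}$, strict feasibility at
$10^{-7}$ on scaled observation residuals, continuation step control with
halving on failure and growth 1.4 after two successes.

## The two worked networks

**Protein activation** (deficiency one): an enzyme E converts S to P
(E+S → E+P), with binding E+S ⇌ ES, substrate inhibition ES+S ⇌ ESS,
degradation of S and P, and constitutive formation of S. One conservation
law, total enzyme $E_T = E+ES+ESS$, is the dose. The fixture carries the
noise-free observables at the two limit points
($E_T = 0.007079$ and $0.010973$; S, ESS, P measured at both).

Two properties of this network matter for interpreting results. First,
the S-moiety balance forces $k_{73} = k_{37}[S] + k_{57}[P]$ at *every*
steady state with a single shared $k_{73}$; with [S] increasing and [P]
decreasing from the lower to the upper limit point by exactly the same
amount in the shipped observables, the degradation constants are pinned
to $k_{57} = k_{37}$ (= 0.01, since $k_{37}$ is conventionally fixed at
0.01 along with $k_{14}=1$), and $k_{73} = 0.15$. This balance also
dictates how each observable's pair of printed values attaches to the two
limit points: P must be high (13.8571) at the low-enzyme point and low
(8.1637) at the high-enzyme point; no steady-state family exists
otherwise. Second, the observables are internally inconsistent at about
1%: $[ESS]/([P][S])$ should be equal at the two limit points but differs
by 1.2%, so the strict-feasibility flag cannot clear on this fixture and
the solver reports a residual floor of about $10^{-2}$ (scaled), carried
almost entirely by ESS. Both facts are consequences of the network
structure plus arithmetic on the shipped table, not solver choices.

**Genetic toggle switch** (deficiency two): two genes repress each other
under mass action — P1 (from G1) binds G2 in two cooperative steps, P2
(from G2) binds G1; both proteins decay. The dose is the P2 decay
constant $k_{7\,13}$; both gene totals are 0.16605. The shipped
observables are exactly consistent as printed and imply round generating
values (P1 decay 6, P2 expression rate 1000, binding ratios 1, 1 and a
cooperativity ratio of ~100). The inverse solve reproduces the folds at
$k_{7\,13} = 0.86$ and $2.96$ to continuation accuracy.

## The synthetic-data generator

`generate_noisy_data()` emulates replicate measurements of the
bifurcation-point observables: each replicate is the noise-free value
times $(1 + cv\cdot z)$, $z\sim N(0,1)$, independent across observables
(uncorrelated error proportional to the mean), redrawn while nonpositive.
The default CV is 0.10. For a conservation-law stimulus the stimulus
values are measured quantities and receive noise too; a rate-constant
stimulus is imposed by the experimenter and stays exact.
`synthetic_bistable_fixture()` perturbs the protein-activation reference
rates by up to ±0.12 decades, verifies bistability by continuation, and
reads the noise-free observables off the fold states, giving problems
with exactly known truth for calibration (parameter recovery, interval
coverage).

What the generator does *not* emulate: correlated errors across
observables, non-Gaussian noise, systematic (calibration) error,
uncertainty in locating the jump along the stimulus axis beyond the
stimulus noise itself, and model-structure error. Passing tests therefore
demonstrate correctness of the machinery and calibration under the stated
error model, not robustness to misspecification.

Monte Carlo defaults: per-point multivariate normal fits (covariances
reduced to the stimulus–observable pairing structure, since replicates of
different concentration observables are acquired in separate titrations;
a joint option exists), $M = 1000$ replicates for full fidelity with
$M = 50$–$200$ used at desk scale, percentile (not normal-approximation)
intervals at 95%.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the full pipeline at sizes
chosen to keep a complete run at desk scale: differential evolution with
a population of 30 for 60 generations plus up to one restart; $M = 50$
Monte Carlo refits (warm-started) for the confidence intervals; 20
synthetic repetitions at $M = 16$ for the coverage check, warm-started
from the base reference parameterization; continuation with a target of
200 points per branch. Each of these can be raised through the exported
arguments; estimates and intervals reported here were generated at these
sizes.

## Known limitations

* Only $t = \ell$ networks are accepted, and branches with more than two
  folds (isolas, mushrooms) are out of scope for dose-response synthesis.
* The identifiability screen is local and heuristic; it cannot prove
  structural identifiability.
* The error-free solver's global phase is stochastic; with the shipped
  seeds and budgets it is reproducible, but pathological networks may
  need larger budgets.
* Strict feasibility on published (rounded) observable tables is
  generally unattainable; the feasibility report tells you the data's own
  consistency level, and should be read together with the tangency
  objective $J_1$.
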