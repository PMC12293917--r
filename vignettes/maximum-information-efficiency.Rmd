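---
title: "Semantic information, the R(G) function, and maximum information efficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic information, the R(G) function, and maximum information efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infoeff)
```

## The model

`infoeff` works with finite probability objects tied together by a dual
probability framework. Statistical probabilities `P` describe what happens:
a source `P(x)` over an instance alphabet, a row-stochastic Shannon channel
`P(y|x)` over labels. Logical probabilities `T` describe what labels *mean*:
a truth function `T(θj|x) ∈ [0, 1]` is the membership grade of `x` in the
fuzzy set θj denoted by label `yj` — equivalently a similarity function, or
`exp(−d)` for a distortion `d`. Truth columns are not normalized; a
tautology is all ones, and the logical probabilities of a label set may sum
past one. The two sides meet in the logical probability
`T(θj) = Σx P(x) T(θj|x)` — simultaneously a partition function and a
regularization term — and the semantic Bayes prediction
`P(x|θj) = T(θj|x) P(x) / T(θj)`.

Two mutual informations are measured on the joint `P(x, y)`:
the Shannon rate `R = I(X;Y)` and the semantic information
`G = I(X;Y_θ) = Σ P(x,y) log₂ m`, with prediction ratio
`m_ij = T(θj|xi)/T(θj) = P(xi|θj)/P(xi)`. `G` is the average code length
saved by predicting with the labels' semantics; it is negative for
misleading labels and never exceeds `R`:

`R − G = H(X|Y_θ) − H(X|Y) = Σj P(yj) · KL(P(x|yj) ‖ P(x|θj)) ≥ 0.`

`H(X|Y_θ)`, the semantic conditional entropy, is what variational Bayes
reports as free energy `F` (exactly `F` once the latent prior matches the
channel marginal; in general `F = H(X|Y_θ) + KL(P⁺¹_Y ‖ P_Y)` with `P⁺¹_Y`
the marginal). The identity above is the package's organizing principle:
channel-matching iterations drive `R − G` (equivalently `KL(P ‖ P_θ)`)
down monotonically, while `F` itself has no such guarantee. `entropy_report()`
returns every diagnostic at once — `R`, `G`, the entropy decompositions,
`F`, `F′ = −F`, the mean-field objective `F#`, the complete-data
log-likelihood `Q = −H(X, Y_θ)`, and the two KL terms — and the identity is
verified to machine precision in the test suite on hundreds of random
triples.

All information quantities default to bits (`log₂`); every measure takes
`unit = "nats"`, and the thermodynamics module works in nats throughout.

## The R(G) solver

The rate-fidelity function `R(G)` is the least Shannon rate compatible with
a given semantic information. Its parametric solution at strength `s`
(the Lagrange multiplier, exposed as a constraint-sharpness hyperparameter)
is found by Minimum Information Difference (MID) alternation: update the
channel row-wise as `P(yj) m_ij^s / λi`, then the latent prior as the channel
marginal, and repeat. `m^s` is evaluated in the log domain (`s · log m`) so
strengths of 40 and beyond cannot overflow, with the conventions `0^s := 0`
for `s > 0` and `0^0 := 1`. Each update provably lowers `R − sG`; the suite
checks descent on every tested instance and compares converged objectives
against an exhaustive grid search over row-stochastic channels on small
instances.

Numerical choices that matter:

- **Convergence** is declared when the largest prior change falls below
  `tol` (default `1e-8`, `max_iter` 1000, both arguments). Prior-only
  convergence with fixed constraints can be slow — geometrically, with a
  ratio near one when a label is dying — which is itself the motivation for
  the EnM variants below; tests that need fixed-point accuracy run with
  tighter tolerances and generous caps rather than looser assertions.
- **Initial prior** is uniform over labels unless supplied.
- **Dying labels**: a prior component that reaches zero stays zero — mass
  cannot return under the multiplicative update. The label is kept in the
  alphabet so trace dimensions never change.
- In the parametric normalizer `Zi = Σk P(yk) m_ik^s` the sum runs over the
  label index; the parametric `R(s)`, `G(s)` agree with direct measure
  evaluation on the returned channel at the fixed point, and this agreement
  is asserted.
- Negative `s` (the "lying" branch, where semantic information is driven
  down) is accepted experimentally, without convergence guarantees.

The curve produced over an `s` grid is bowl-shaped: `G(s)` non-decreasing,
`R` convex in `G` with slope `dR/dG ≈ s`, efficiency `G/R = 1` exactly at
`s = 1` for source-consistent constraints. Maximizing `G/R` — getting the
largest fraction of transmitted information to be semantically useful — is
the package's optimization criterion everywhere.

## Mixture models: EM, EnM, En, and why free energy is not monotone

For a discrete source and a family of likelihood columns the E-step
`P(yj|x) = P(yj) P(x|θj)/P_θ(x)` is exactly the MID channel update at
`s = 1`. One EnM(n) outer iteration repeats the (E-step, marginal update)
pair `n` times — so the latent prior settles onto the channel marginal —
then refits the Gaussian parameters as the weighted mean and standard
deviation of `x` under `P(x) P(yj|x)/P⁺¹(yj)`. EM is EnM(1); En fixes the
likelihoods and iterates only the prior.

Traces record the full diagnostic set twice per (E, M1) block: after the
E-step, where the prior and marginal differ and the exact bookkeeping
`KL(P ‖ P_θ) = (R − G) + KL(P⁺¹_Y ‖ P_Y)` can be checked
(`convergence_identity_check()` does, at `1e-9` bits), and after the
marginal update, where the KL term vanishes and `F` collapses onto
`H(X|Y_θ)` — the convention under which `F` is reported. The stop rule is
`|ΔKL(P ‖ P_θ)| < 1e-9` bits across outer iterations by default (a threshold
on KL itself is available); iteration counts are therefore only meaningful
relative to one another under a shared rule, and the package never asserts
absolute counts.

Why can `F` rise while the model converges? The per-label cross-entropy
`H(X|θj) = −Σ P(x|yj) log₂ P(x|θj)` falls when the model posterior
approaches a fixed actual posterior — but when it is the *actual* posterior
that moves toward a fixed, broader model, the cross-entropy rises: with
`P(x|θj) = (0.1, 0.4, 0.4, 0.1)`, an actual posterior `(0, 0.5, 0.5, 0)`
costs `log₂(10/4) ≈ 1.32` bits, and letting it disperse to equal the model
raises the cost to `0.2·log₂10 + 0.8·log₂(10/4) ≈ 1.72` bits. When the true
mixture is broad (`H(X|Y)` large) and the initial model narrow, convergence
*must* raise `H(X|Y_θ)` on the way. Three packaged configurations
(`mixture_fixture()`) realize this:

- `"counterexample"` — true means 40/75, both sd 15, equal weights;
  initialized at sd 5. `F` rises over a stretch of iterations while
  `KL(P ‖ P_θ)` and `R − G` fall monotonically.
- `"neal_hinton"` — components (46, sd 2) and (50, sd 20); with the mixing
  ratio set to 0.3 : 0.7 (`swap_ratio = TRUE`), `F′ = −F` is visibly
  non-monotone because the broad component's cross-entropy grows with its
  weight.
- `"poor_convergence"` — true (100, 125, sd 10/10, weights 0.7/0.3)
  initialized far off at (80, 95, sd 5/5, 0.5/0.5). Both EM and E3M
  converge; E3M needs strictly fewer outer iterations under the identical
  stop rule.

## What the generator emulates — and what it does not

`discretize_mixture()` is the package's population mode: the deterministic
large-sample limit of a one-dimensional Gaussian mixture on a regular grid
(component densities renormalized per column, mixture density renormalized
as the source). It makes every convergence trace reproducible bit for bit,
which is what the counterexamples require. `sample_mixture()` is the
finite-sample mode — seeded draws snapped to the grid — and converges to the
population law (the suite checks `KL < 10⁻³` bits at `n = 10⁶`).

Grid defaults are unit step over a range reaching at least five standard
deviations past every component (less than 0.1% clipped mass is tolerated;
more raises an error). A unit step puts ≥ 10 bins under every σ used by the
packaged studies; discretization biases the refitted σ upward by roughly
`step²/(24σ)` (about 0.2% at σ = 2), well inside the 5% recovery tolerance
asserted. The refit floors σ at half a grid step so a collapsing component
cannot fall below the resolution of its own support; components whose weight
reaches zero are frozen, not dropped. What population mode deliberately does
not emulate: sampling noise, model misspecification (the data really are the
discretized mixture), multimodality of the likelihood surface beyond what
the initializations probe, and dimensions above one. Passing tests show the
algorithms' analytic properties, not robustness to real data.

## Goal-oriented control

Constraint control reuses the MID machinery with the goals as truth
functions: optimize the action channel `P(a|x)` and action ratio `P(a)`
(initial ratio uniform) to minimize `I(X;A) − s·I(X;A/θ)`. The solution's
headline `G` is the purposeful information delivered through the action
channel, which never exceeds the complexity `R = I(X;A)`; the
strength-sharpened outcomes `P(x|aj, s) ∝ P(x) m^s` are reported per goal
alongside (`G_outcomes`), as is a moment-matched normal surrogate outcome
when the state labels are numeric — reported, never silently substituted.
Goals may be given as crisp ranges, Gaussian center/width pairs, or explicit
tables.

The packaged `two_pastures_demo()` is a 1-D world (positions 0–100, initial
herd density a discretized normal at 50 with sd 22) with Gaussian goals at
25 and 75. The goal width defaults to 15: wide enough that the two fuzzy
pastures jointly cover the world (narrow goals leave most initial mass at
near-zero truth values and make the channel-borne semantic information
negative, which is a property of badly posed goals, not of the solver). On
this demo `G(s)` and `R(s)` grow with `s` and the gains beyond `s ≈ 5` are
marginal (about 1% from `s = 5` to `s = 40`), so strong control mainly
spends rate.

## Semantic compression demo

`grayscale_truth_bank()` builds eight Gaussian truth functions over 256 gray
levels with centers on the power law `255·((j − ½)/8)^1.5` and widths 0.45
of the local center spacing — a Weber-like placement, denser and narrower in
the dark range where gray discrimination is finest. The exponent and width
factor were fixed once as a plausible perceptual bank; both are arguments.
Under a uniform source the En run starts from the uniform 8-label prior
(`H(Y) = 3` bits exactly) and converges to a rate near 2.1 bits at
efficiency above 0.99; the latent prior stabilizes (largest change below
`10⁻³`) within a handful of iterations.

## Thermodynamic identities

For a spectrum of energy levels with degeneracies `g_i` (microstates
equiprobable a priori, `Gm = Σ g_i`), regions at temperatures `T_j` holding
fractions `P(y_j)` of the molecules carry energy information
`I(E;Y) = Σj P(yj) KL(P(e|yj) ‖ P(e))`, and the package verifies
`I(E;Y) = ln Gm − S/(kN) = I(X;Y)` at the microstate level, in nats, to
`1e-9`. In equilibrium mode (region conditionals Boltzmann at their own
temperature) the same information equals the semantic form built from truth
functions `T(θj|x) = exp(−e_i/(kT_j))` — whose logical probabilities are the
partition functions — and `H(X|Y_θ)` equals `S/(kN)`: the quantity called
free energy in variational inference is, in the physical analogy,
conditional *entropy*. Boltzmann distributions are computed in the log
domain (tiny temperatures underflow otherwise), `k` and `N` default to 1
(they scale, never shape, the results), and non-equilibrium mode accepts
arbitrary region conditionals so the KL-form path is testable on its own.
The free-energy increment against a reference temperature `T0` is evaluated
on its entropy side only; the constant-internal-energy premise behind it is
not enforced.

## Problem sizes and limitations

The studies shipped with the package run on grids of a few hundred points
(251 for the 46/50 configuration, 236 for 40/75, 186 for 100/125), 256 gray
levels, 101 control positions, and random-instance suites of 100–200 draws
with alphabets of 2–6 — sizes chosen so every experiment is exactly
reproducible and the full suite runs in well under a minute on one core.
Known limitations: one-dimensional Gaussian components only (no covariance
structure); no parameter priors or hyperpriors on the model side (the
variational machinery here treats parameters as point values); absolute
iteration counts depend on the stop threshold and are never asserted;
continuous sources are handled only through discretization; and the negative
strength branch of `R(G)` is exposed without convergence guarantees.
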