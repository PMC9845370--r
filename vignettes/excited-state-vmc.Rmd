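---
title: "Excited-state variational Monte Carlo with overlap penalties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Excited-state variational Monte Carlo with overlap penalties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Variational Monte Carlo (VMC) finds the ground state of a Hamiltonian
$\hat H$ by minimizing the energy expectation of a parametrized trial
wavefunction $\psi_\theta(\mathbf r)$ over the space of electron
coordinates. The expectation is evaluated stochastically as the mean of the
*local energy*

$$E_{\mathrm{loc}}(\mathbf r) = \frac{\hat H \psi(\mathbf r)}{\psi(\mathbf r)}
 = -\tfrac12 \sum_k \left[\partial_k^2 \ln|\psi| +
 (\partial_k \ln|\psi|)^2\right] + V(\mathbf r)$$

over samples $\mathbf r \sim |\psi_\theta|^2$. When $\psi$ is an exact
eigenstate, $E_{\mathrm{loc}}$ is constant (the zero-variance principle),
which this package exploits everywhere as a correctness oracle.

`excitedvmc` extends this to the lowest $n$ eigenstates at once: $n$ trial
wavefunctions are optimized jointly under the penalized loss

$$\mathcal L(\theta) = \sum_i \mathbb E_i\!\left[E_{\mathrm{loc}}[\psi_i]\right]
 + \alpha \sum_{i > j} \left(\frac{1}{1 - |S_{ij}|} - 1\right),$$

where $S_{ij}$ is the pairwise overlap of the (unnormalized) states. The
penalty is zero at orthogonality, linear to first order
($|S| + |S|^2 + \dots$), bounded below by $S^2$, and diverges as two states
collapse onto each other, so states may overlap transiently during
optimization but cannot merge. For a sufficiently large $\alpha$ the global
minimum of $\mathcal L$ is the sum of the $n$ lowest eigenvalues with
mutually orthogonal states; the package verifies this on an exactly
solvable two-state family by brute-force sweep.

Overlaps of unnormalized states are estimated norm-free as the signed
geometric mean of two directional ratio expectations,

$$S_{ij} = \mathrm{sgn}\!\left(\mathbb E_i\!\left[\tfrac{\psi_j}{\psi_i}\right]\right)
 \sqrt{\mathbb E_i\!\left[\tfrac{\psi_j}{\psi_i}\right]
       \mathbb E_j\!\left[\tfrac{\psi_i}{\psi_j}\right]},$$

and the same construction with a local operator action
$(\hat O \psi)(\mathbf r)/\psi(\mathbf r)$ inserted yields arbitrary mixed
matrix elements: transition dipole moments
$\mathbf d_{ij} = \langle \psi_i | \sum_k q \hat{\mathbf r}_k | \psi_j\rangle$
and, from them, oscillator strengths
$f_{ij} = \tfrac23 \Delta E \, d_{ij}^2$. All of these reduce exactly to the
overlap for $\hat O = \mathrm{Id}$ and to the energy for $i = j$,
$\hat O = \hat H$, and all are invariant under rescaling either state.

Gradients never need second parameter-derivatives: the energy gradient is
the covariance form
$2\,\mathbb E[(E_{\mathrm{loc}} - \bar E_{\mathrm{loc}})\,\partial_\theta \ln|\psi|]$,
and the overlap gradient is the matching covariance expression with the
directional ratios in place of the local energy. On a *shared weighted
point set* (both expectations evaluated over one frozen point cloud with
self-normalized importance weights) these formulas are the exact
derivatives of the estimators — the package's finite-difference validations
rest on this identity.

## The ansatz

The molecular trial wavefunction is a cusped Slater–Jastrow–backflow form,

$$\psi_\theta(\mathbf r) = e^{\gamma(\mathbf r) + J_\theta(\mathbf r)}
 \sum_p c_p \det[\tilde\varphi^\uparrow_{\mu_p i}]
            \det[\tilde\varphi^\downarrow_{\mu_p i}],
 \qquad
 \tilde\varphi_{\mu i} = \varphi_\mu(\mathbf r_i) f^{(m)}_{\mu i}(\mathbf r)
 + f^{(a)}_{\mu i}(\mathbf r),$$

with these roles:

* $\gamma$ — a fixed (non-trainable) envelope enforcing the Kato coalescence
  conditions: radial slope $-Z_I$ of $\ln|\psi|$ at each nucleus, $+1/2$ at
  opposite-spin and $+1/4$ at same-spin electron coalescences. It is built
  from the saturating feature $u(d) = d/(1 + b\,d)$; the locality parameter
  `cusp_range` $= b$ (default 8, i.e. a correction range of roughly
  1/8 bohr) leaves imported baseline orbitals essentially untouched outside
  the coalescence regions — with a long-ranged envelope ($b = 1$) the
  imported hydrogen baseline is distorted by about 40 mHa, with $b = 8$ by
  less than 1 mHa.
* $J_\theta$ — a symmetric Jastrow factor: a sum of small scalar tanh
  networks (two hidden layers) over the cusp-neutral pair feature
  $s(d) = d^2/(1+d)$, with separate channels for same-spin pairs,
  opposite-spin pairs, and one electron–nucleus channel per element. It
  cannot move the nodal surface.
* $f^{(m)}, f^{(a)}$ — backflow heads: per-spin-channel vector tanh
  networks mapping permutation-equivariant per-electron features
  (electron–nucleus distances plus pooled same/opposite-spin pair features)
  to one multiplicative and one additive dressing per orbital. Backflow can
  deform nodes while preserving antisymmetry.
* $\varphi_\mu$ — orbitals as trainable linear combinations of analytic
  Gaussian (s, p) or Slater basis functions; determinant coefficients
  $c_p$ are trainable unless the fixed-spin mode freezes them.

All output layers initialize to zero, so a freshly built ansatz evaluates
*exactly* to its determinant baseline with the cusp envelope attached —
states imported from a multi-configuration baseline therefore start nearly
orthogonal. Every derivative the method needs (coordinate gradient,
Laplacian, parameter gradient) is computed analytically by hand-coded
forward/backward passes; finite differences appear only in the test suite
as oracles.

For the desk-scale validations two closed-form families play the role of
the network ansatz: a polynomial-times-Gaussian family in 1D (spans every
harmonic-trap eigenstate) and a radial polynomial-times-exponential family
in 3D (spans the hydrogenic s states). Both are flexible enough to train
from a perturbed start to the exact spectrum, and both make every
validation quantitative because the targets are known in closed form.

## Sampling

Each state owns an independent walker ensemble driven by a
Metropolis-adjusted Langevin chain: proposals
$\mathbf r' = \mathbf r + \delta^2 \nabla \ln|\psi| + \delta\,\xi$ accepted
with the exact Metropolis–Hastings ratio for the drifted Gaussian, so
$|\psi|^2$ is the exact stationary law. The step size adapts
multiplicatively toward acceptance 0.57 (the standard Langevin
optimal-scaling target) and is frozen during evaluation windows.

The drifted kernel crosses nodal surfaces only rarely — drift points away
from nodes on both sides — so lobe populations of excited states would
equilibrate too slowly on their own. An auxiliary full-configuration
random-walk Metropolis move (scale tied to the walker cloud, adapted only
while tuning is unfrozen) is interleaved every few steps; it leaves
$|\psi|^2$ exactly invariant and restores ergodicity across nodal pockets.
Walkers landing exactly on a node (sign 0) are auto-rejected; singular
configurations are rejected rather than clamped so the cusp behavior stays
testable.

## Stochastic optimization

Each iteration advances every chain by `decorr` (default 10) decorrelation
moves, estimates the batch energy and pairwise overlaps, assembles
per-state gradients and steps the parameters. The ground state is subject
to unconstrained energy minimization; state $i$ adds one penalty term per
lower-lying state $j < i$ with the lower state detached (treated as a
constant), so convergence cascades upward from the ground state.

Three design choices here deserve explanation, because each was forced by a
measurable failure mode of the naive implementation:

* **Stochastic reconfiguration is the default optimizer.** Plain SGD on
  these families stalls ~60 mHa above the exact excited-state eigenvalue:
  the excited-state direction is badly conditioned, and heavy-tailed
  gradient noise (parameter-derivatives of $\ln|\psi|$ diverge near moving
  nodes) makes the parameters diffuse rather than descend — initializing
  *at* the exact eigenstates and watching SGD drift away isolates the
  effect, while the exact quadrature gradient flow stays put. The natural
  gradient update $(S + \epsilon I)\,\delta = g$, with $S$ the batch
  covariance of the per-sample parameter gradients, removes the
  conditioning problem and converges to $<10^{-4}$ Ha on the same budget.
  Plain SGD remains available (`optimizer = "sgd"`).
* **The penalty must not chase its own noise.** Near orthogonality the
  overlap estimate is pure sampling noise, and the factor
  $\mathrm{sgn}(S)\,\mathrm{penalty}'(|S|)$ correlates with the noise in
  $\partial S$, producing a systematic drift that visibly biases
  nearly-converged excited states — the small-batch bias regime. Two
  measures remove it: the penalty prefactor and the overlap gradient are
  estimated on independent half-batches (so the prefactor's sign is
  symmetric noise at orthogonality and the product has zero mean), and the
  overlap gradient is gated to zero whenever $|S|$ lies within 2
  block-jackknife standard errors of zero — the quantitative form of
  treating statistically-zero overlaps as orthogonal.
* **Stabilizers are caps, not reshaping.** Local-energy winsorization at
  median $\pm k$ mean-absolute-deviations is implemented and config-exposed
  (`winsor_k`) but off by default: for low-parameter families the
  node-region samples it clips carry precisely the gradient signal that
  positions the node, and the winsorized flow has a fixed point measurably
  displaced from the eigenstate. Instead, per-sample parameter-gradient
  rows are capped at the 99th-percentile norm (`pgrad_cap`), overlap ratios
  at their 99.9th percentile (`cap_quantile`, capped fraction reported for
  audit), and each state's total gradient is norm-clipped (`clip_at`,
  default 10). All caps vanish from the fixed point because the centered
  local energy is identically zero at an eigenstate.

Per-iteration energy means and variances are smoothed with a bias-corrected
exponential moving average (decay 0.99), parameters are checkpointed every
100 iterations, and a divergence guard aborts if any smoothed energy rises
by more than 1 Ha over 100 iterations. Given a seed, runs are bit-exactly
reproducible in a single-threaded session.

## Variance matching

Different states converge at different quality, which biases excitation
energies. Because the energy variance measures distance to an eigenstate,
the matched excitation energy pairs *checkpoints of equal smoothed
variance*: the state whose final variance is higher sets the target, the
other state is rewound to the checkpoint whose smoothed variance is closest
(ties resolve to the latest), and both selected checkpoints are re-evaluated
by fresh long sampling. If the target exceeds the other state's entire
series, the final checkpoints are kept and the pair is flagged unmatched.
On the toy systems the states converge essentially exactly, so matched and
raw excitation energies coincide; the selection logic itself is tested
against brute-force search over the checkpoints.

## Tunable parameters at a glance

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `alpha` | 1 | Ha per penalty unit | weight of the overlap penalty; a linear ramp is available |
| `s_max` | 0.999 | — | overlap clamp: loss finite exactly at collapse, repulsion preserved |
| `batch_size` | 2000 | walkers | the regime where the nonlinear penalty shows no measurable bias |
| `decorr` | 10 | moves | decorrelation between parameter updates |
| `lr`, `lr_decay` | 0.05, none | — | natural-gradient step size and optional 1/(1+t/decay) schedule |
| `checkpoint_every` | 100 | iterations | variance-matching granularity |
| `ema_decay` | 0.99 | — | smoothing of energy mean/variance |
| `cusp_range` | 8 | 1/bohr | locality of the cusp envelope (see above) |
| `eval_samples` | 1e5 | samples | "exhaustive" final evaluation per state |

## The synthetic study systems, and what they do (not) show

The generator-side systems are the 1D harmonic trap (spectrum
$\omega(n + \tfrac12)$), the 1D box ($n^2\pi^2/2L^2$), the soft-Coulomb
well, and the hydrogenic atom ($-Z^2/2n^2$); interacting two-particle 1D
systems are available through the grid oracle with a selectable exchange
sector. Study runs initialize from the analytic baseline with a relative
Gaussian perturbation of 0.1 (0.08 for hydrogen) — large enough that the
initial energies are off by ~0.1–0.5 Ha and training genuinely has to find
the states, small enough to emulate the quality of a reasonable
quantum-chemistry starting point. Problem sizes used by the shipped
validations: three harmonic states at batch 2000 for 2000 iterations, two
hydrogen states at batch 2000 for 1000 iterations, mixture calibrations at
batch 10⁴, final evaluations at 3·10⁴ samples per state.

These runs exercise every estimator, the penalty coupling, the sampler and
the optimizer against exact references — but on systems with one particle
per state and few-parameter ansatzes. They do not probe fermionic
antisymmetry under optimization pressure, multi-electron correlation, or
network-scale parameter counts; the molecular ansatz's symmetry, cusp and
derivative contracts are tested separately (exact antisymmetry,
equivariance, Kato slopes, finite-difference agreement), not trained to
chemical accuracy here.

## Numerical choices and degenerate inputs

* Everything is evaluated in sign/log form; determinant expansions combine
  via signed log-sum-exp; Hartree units internally, with Å accepted at the
  geometry interface (1 Å = 1.8897259886 bohr).
* The grid oracle uses second-order central differences with a Richardson
  step (two spacings at fixed extent, giving fourth-order eigenvalues) and
  refuses eigenfunctions that put more than 10⁻⁶ of their mass on the
  boundary nodes.
* Overlap standard errors use a 20-block jackknife, floored by the
  geometric mean of the directional-mean standard errors: near
  orthogonality the jackknife collapses (sign-disagreeing blocks all map to
  zero) while the floor retains the natural scale of the estimate. The
  error-bar definition is a package-level choice.
* Estimator ties and edge cases: identical state and batch give
  $S_{ii} = 1$ exactly; directional sign disagreement reports orthogonality
  (value 0, flagged); $|S| < 10^{-8}$ zeroes the gradient (no $1/S$
  blow-up); points with zero weight under their own state (quadrature nodes
  on a nodal set) are excluded from expectations; walkers with non-finite
  drift are re-initialized and counted.
* A point exactly on a *component's* node of a linear-combination state has
  no finite $\ln|\psi_k|$-derivative; derivatives there are NaN by design
  (a measure-zero set that samplers reject) rather than silently wrong.

## Known limitations

* The molecular ansatz evaluates walker-by-walker in R; it is meant for
  few-electron systems and contract testing, not for production-scale
  molecules. The formal scaling of the method (per-state cost cubic-ish in
  electron number, quadratic in the number of states from the pairwise
  overlaps) is inherited, but the constant factor is interpreted.
* Which excited states are found depends on the baseline: states outside
  the span of the initialization's symmetry sector can be missed, and
  near-degenerate clusters are not guaranteed to be resolved completely.
* Spin is controlled only through the fixed $(N_\uparrow, N_\downarrow)$
  split and, optionally, frozen determinant coefficients; total-spin
  measurement is out of scope.
* Pseudopotentials, periodic systems, external fields, non-local operators
  and nuclear forces are out of scope.
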