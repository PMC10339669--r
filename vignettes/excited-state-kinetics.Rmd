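---
title: "Diabatic crossing kinetics and vibronic spectra from perturbed matrix method trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diabatic crossing kinetics and vibronic spectra from perturbed matrix method trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmmkin)
```

`pmmkin` turns classical perturbation trajectories around a quantum center
(QC) into excited-state relaxation observables: perturbed electronic
energies, diabatic gap trajectories, first-crossing rate constants,
vibronic spectra, and the lifetimes and quantum yield of a bright-state
equilibrium feeding a dark channel. This vignette is the package's own
account of the model, its assumptions and the numerical choices; it states
no empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The perturbed electronic Hamiltonian

The QC (for the motivating system: the indole chromophore in water) is
described by its unperturbed electronic eigenstates — energies
$\varepsilon_j^0$, per-atom point charges $q_{N,j}^0$, diagonal and
transition dipoles $\mu_{j,l}^0$. The environment enters only through the
electric potential $V(\mathbf R_N)$ it exerts at the QC atom positions and
the field $\mathbf E(\mathbf r_0)$ at a reference point (typically the
center of mass). Per frame, the electronic Hamiltonian in the unperturbed
basis is

$$[\tilde H_e]_{jj} = \varepsilon_j^0 + \sum_N q_{N,j}^0\, V(\mathbf R_N)
  + \Delta V, \qquad
  [\tilde H_e]_{jl} = -\mathbf E(\mathbf r_0)\cdot\boldsymbol\mu_{j,l}^0
  \;(j \ne l),$$

where the scalar $\Delta V$ collects state-independent higher-order
diagonal terms. Because it is state independent it cancels in every energy
gap; the package keeps it as an explicit frame field with default 0.
Diagonalizing $\tilde H_e$ (`pmm_diagonalize()`) yields perturbed energies,
eigenvector coefficients $c_{ji}$ and perturbed transition dipoles
$\boldsymbol\mu_{0,i} = \sum_{j,l} c_{j0} c_{li} \boldsymbol\mu_{j,l}^0$.

**Diabatic character.** The physically meaningful (diabatic) states — Lb,
La, πσ* — keep their charge/dipole identity through crossings while the
adiabatic energy order may swap. `assign_diabatic_character()` maps a
perturbed state onto the basis state with the largest squared coefficient;
a dipole-direction (cosine) metric is available as an alternative, since
the states are equally well distinguished by their diagonal and transition
dipoles. The coefficient metric is the default because it is
basis-intrinsic, needs no auxiliary threshold and is exactly
permutation-equivariant; ties within $10^{-12}$ are flagged and resolved
to the lower-energy label.

**Diabatic gaps.** The transition energy of an R → P channel is the
difference of diagonal elements $[\tilde H_e]_{PP} - [\tilde H_e]_{RR}$,
optionally shifted by per-state vibronic corrections (e.g. matching
experimental gas-phase 0–0 energies: −0.32 eV for the Lb signal and
−0.57 eV for La in the motivating system, entering the Lb→La gap as their
difference). Geometry fitting of reference structures to MD frames is
treated as a precomputed input transformation: the package consumes
already-projected potentials and fields.

Units are fixed package-wide: energy kJ/mol, time fs, charge e, length nm,
dipole e·nm, field kJ mol⁻¹ e⁻¹ nm⁻¹, with
$\hbar = 63.5078$ kJ mol⁻¹ fs and $k_B = 8.31446\times10^{-3}$
kJ mol⁻¹ K⁻¹ (`pmm_constants()`). These match MD conventions and keep all
tabulated magnitudes O(1)–O(10²).

## 2. First-crossing kinetics

An electronic transition is modeled as a first-passage problem for the gap
trajectory $\Delta U(t)$, which is positive in the reactant ensemble and
crosses zero at a diabatic crossing.

- `detect_first_crossing()` finds the first sign change, interpolates the
  crossing time linearly within the bracketing step and takes the crossing
  speed $v_{cr}$ from the bracketing-interval slope. Traces that start
  non-positive are rejected — the caller must re-select the start frame,
  mirroring the nonequilibrium start-selection protocol implemented in
  `gen_reactant_starts()`. Gap velocities default to central finite
  differences (one-sided at the ends); the expected sampling interval is
  1 fs.
- `survival_trace()` censuses an ensemble of first-crossing times into a
  survival curve; trajectories that never cross are right-censored (they
  keep "surviving" through the horizon) rather than discarded, so slow
  channels are not biased fast.
- `fit_survival()` fits $n_1 e^{-t/\tau_1} + n_2 e^{-t/\tau_2}$ with
  $n_1 + n_2 = 1$ by Nelder–Mead least squares in transformed coordinates
  (logit $n_1$, log lifetimes — positivity and the sum constraint are
  built into the parameterization). The attempt lifetime is the mixture
  mean $\tau_0 = n_1\tau_1 + n_2\tau_2$. When the two fitted scales agree
  within a factor of two the nested single-exponential model is used
  instead; non-convergence also falls back, with a warning. A survival
  curve that never decreases is an error, not a fit.

**Landau–Zener transmission.** At a crossing traversed with speed
$v_{cr}$ under mean coupling $|\bar H_{e,R,P}|$, the probability of
hopping between diabats is
$\chi_e = 1 - \exp[-2\pi|\bar H|^2/(\hbar v_{cr})]$. A reaction event may
traverse several product vibronic surfaces; the traversed Franck–Condon
weight $\Omega = \sum_{i=0}^{n_P-1}\xi_i^2$ (`omega_overlap()`) enters the
per-event reaction probability $1 - (1-\chi_e)^\Omega$. Averaging over
sampled events gives the explicit transmission coefficient
(`transmission_explicit()`, with a seeded 1000-resample bootstrap standard
error); when event-resolved sampling is unavailable,
`transmission_approx()` uses $\alpha_G \approx 1-(1-\alpha_e)^{\langle\Omega\rangle}$
with the caller choosing $\langle\Omega\rangle$: $\xi_0^2$ for dark-state
channels where the large gap mean makes only the first vibronic crossing
accessible, or 1 when essentially all productive surfaces are traversed.

**Gaussian-approximation rate.** When crossings are too rare to sample,
the attempt rate comes from the equilibrium reactant ensemble under the
assumption of Gaussian gap fluctuations:

$$k^0 = \tfrac12\,\langle v\rangle_{R_A}\;
  \rho\!\left(0;\ \langle\Delta U\rangle_{R_A},\ \sigma_{R_A}\right),$$

the mean absolute gap speed times the Gaussian density at zero, halved to
count only unidirectional (downward) crossings. For a stationary
differentiable Gaussian process with velocity standard deviation
$\sigma_v$ one has $\langle|v|\rangle = \sigma_v\sqrt{2/\pi}$, and $k^0$
is exactly Rice's downcrossing rate
$\rho(0)\,\sigma_v/\sqrt{2\pi}$ — asserted analytically in the tests and
verified by simulation against seeded surrogates (empirical downcrossing
counts per unit time agree within 10 % for $\mu/\sigma \in \{0.5, 1, 2\}$
at 2000 trajectories; the survival-fit route is additionally compared at
$\mu/\sigma = 2$, where crossings are rare enough for the
exponential-interval assumption behind "rate = 1/mean-first-passage").
Note the convention: `gaussian_rate()` takes the **mean absolute speed**
$\langle v\rangle_{R_A}$, not $\sigma_v$. Under the Gaussian assumption
the distribution mode equals the mean; the package centres the density on
the sample mean and exposes the kernel-density mode as a diagnostic
(`gap_statistics()`), since the sample mode is a far noisier estimator.

**Reaction lifetime.** Each approach to the transition region offers two
hop opportunities — inbound and outbound traversal — each succeeding with
probability $\alpha_G$, so

$$\tau = \frac{\tau_0}{1-(1-\alpha_G)^2}.$$

This single relation reproduces, at their printed precision, all the
attempt-lifetime/transmission/lifetime triplets of the motivating study's
kinetics table (both the explicit-sampling and the approximate rows),
which is how the package fixes the reaction-step chaining; the fully
adiabatic limit $\alpha_G = 1$ returns $\tau_0$, and $\alpha_G = 0$
returns an absent value rather than an infinite lifetime.

**Crossing-mean-coupling $\alpha_e$.** Without crossing sampling the
electronic coupling statistics are reconstructed from the equilibrium
field. Within the dipolar approximation the gap is linear in the field
component along $\boldsymbol\eta_\parallel =
\Delta\boldsymbol\mu^0/|\Delta\boldsymbol\mu^0|$
($\Delta\boldsymbol\mu^0 = \boldsymbol\mu_R^0 - \boldsymbol\mu_P^0$), so
the crossing condition pins
$E_\parallel = -\Delta\varepsilon^0/|\Delta\boldsymbol\mu^0|$. With
$\boldsymbol\eta_\perp$ the in-plane unit vector orthogonal to
$\boldsymbol\eta_\parallel$ in the plane spanned by
$\Delta\boldsymbol\mu^0$ and the mean transition dipole
$\bar{\boldsymbol\mu}^0_{R,P}$ (so that
$\bar{\boldsymbol\mu}$ has no projection outside that plane by
construction — the resolution adopted for the general case where the full
field is not $E_\parallel + E_\perp$), the mean squared coupling over the
reactant ensemble is

$$\langle|\bar H|^2\rangle = (E_\parallel\bar\mu_\parallel)^2
 + 2E_\parallel\bar\mu_\parallel\bar\mu_\perp\langle E_\perp\rangle
 + \bar\mu_\perp^2\langle E_\perp^2\rangle,$$

and $\alpha_e = 1-\exp[-2\pi\langle|\bar H|^2\rangle/(\hbar\langle
v_{cr}\rangle)]$ with $\langle v_{cr}\rangle \approx \langle
v\rangle_{R_A}$ (the same equilibrium-speed approximation as above).
Replacing $\langle e^{-a|H|^2}\rangle$ by $e^{-a\langle|H|^2\rangle}$ is
the "mean coupling" step; it is accurate in the weak-coupling regime
(nearly linear exponential), which is where the approximation is needed,
and the tests verify 10 % agreement against brute-force averaging over a
simulated coupling ensemble there. If
$|\Delta\boldsymbol\mu^0| < 10^{-9}$ e·nm the crossing condition is
undefined and the constructor errors.

## 3. Vibronic structure and spectra

Vibrational modes of the two electronic states of a transition are treated
as identical in frequency, displaced in their minima, and uncoupled
(quasi-diagonal Duschinsky matrices justify this; Duschinsky rotation and
Herzberg–Teller terms are out of scope). Modes split at
$\hbar\omega = k_B T$ into quantum modes (Franck–Condon progressions) and
classical-like modes (ensemble broadening). For a quantum mode with
Huang–Rhys factor $S = \omega d^2/(2\hbar)$ (mass-weighted displacement
$d$, in amu$^{1/2}$·nm), the 0→n factor is the Poisson weight
$\xi_n^2 = e^{-S}S^n/n!$; multi-mode factors are products, enumerated by
per-mode truncation at cumulative weight $1-10^{-6}$ and weight-ordered
pruning capped at $10^6$ retained terms (`fc_transitions()`), which keeps
million-line progressions tractable.

Vertical spectra (`vertical_spectrum()`) bin the per-frame transition
energies (default bin width 1 kJ/mol), weight each bin by its frame count
and mean squared transition dipole, and broaden with a Gaussian whose
width defaults to the bin width; `classical_broadening()` provides the
physical alternative $\sigma = \sqrt{2\lambda_{cl}k_BT}$ from the
classical-mode reorganization energy $\lambda_{cl} = \sum S_m\hbar\omega_m$
(the broadening is attributed to semiclassical QC vibrations, with no
prescribed numeric width — hence a configurable default). Absorption
weights intensities by $\nu$, spontaneous emission by $\nu^3$; the
absolute prefactors use the full physical constants (the Einstein-A
coefficient for emission — also exposed directly via `einstein_A()` and
`radiative_lifetime()` — and the integrated-cross-section constant for
absorption), validated against an independent SI-units evaluation in the
tests. Vibronic replicas shift each bin by
$\nu_{ref}^m = \nu_{ref} + (\nu_m^0 - \nu_{el}^0)$ — downward in energy on
the emission side — plus any constant 0–0 correction.
`assemble_spectrum()` mixes subensemble spectra with nonnegative weights
summing to 1 (tolerance $10^{-9}$) on the union grid by linear
interpolation.

## 4. The relaxation network

The bright-state interconversion is far faster than every decay channel,
so the Lb/La mixture is taken at full equilibrium during relaxation:

- $\Delta A$ (Lb→La) from the two ensemble gap means, default estimator
  $\tfrac12(\langle\Delta U\rangle_{Lb} + \langle\Delta U\rangle_{La})$ —
  the two-sided linear-response mean. The printed source equation for this
  estimator is not recoverable from the available text, so the package
  adopts the linear-response form as its default and offers a
  Gaussian-fluctuation variant with the variance-asymmetry term
  $-(\sigma_{Lb}^2-\sigma_{La}^2)/(4k_BT)$ for users who prefer it.
- $K_{eq} = e^{-\Delta A/k_BT}$, $f_a = K_{eq}/(1+K_{eq})$,
  $f_b = 1-f_a$.
- Population-weighted harmonic lifetimes
  $\tau_r = (f_b/\tau_{r,b} + f_a/\tau_{r,a})^{-1}$ and
  $\tau_{nr} = (f_b/\tau_b + f_a/\tau_a)^{-1}$ — the fast-pre-equilibrium
  approximation.
- $\tau_F = (1/\tau_r + 1/\tau_{nr})^{-1}$, $\Phi = \tau_F/\tau_r$.
  An intersystem-crossing channel enters only as an external first-order
  rate added to the nonradiative side
  ($1/\tau_{nr}' = 1/\tau_{nr} + 1/\tau_{ISC}$); no triplet manifold is
  modeled.

Dark-state back transitions are orders of magnitude slower than the
forward ones and are excluded from $\tau_{nr}$ by default (the transition
is treated as virtually irreversible); `master_equation_lifetimes()`
solves the full three-state linear network by eigendecomposition as a
sensitivity check, and the tests confirm it reproduces the
fast-pre-equilibrium $\tau_F$ when interconversion is fast and departs
from it when interconversion is artificially slowed.

Uncertainties propagate first order (delta method, central differences
with relative step $10^{-6}$) from any supplied component standard errors;
the propagation reproduces analytic sensitivities in the tests. A
parametric bootstrap is not built into the scheme object, but the
underlying chain is a pure function, so resampling inputs through
`relaxation_scheme()` is a one-liner if needed.

## 5. Synthetic surrogates: what they emulate, and what not

The generators provide the statistical structure the analysis *assumes*,
so every stage can be validated end-to-end:

- `gen_gap_ensemble()` / `gen_gap_trace()`: a second-order (underdamped)
  Langevin process — not a plain OU process, because the kinetics needs a
  well-defined gap velocity for the crossing speed and the
  level-crossing-rate identity. Position marginal Gaussian(mean, σ²),
  velocity marginal Gaussian(0, σ_v²), stationary start, and the exact
  Gaussian transition kernel of the discretized dynamics (matrix
  exponential of the drift and the exactly matching innovation
  covariance), so there is no step-size bias to tune away. The friction
  defaults to the oscillator frequency σ_v/σ; a step coarser than 1/20 of
  the velocity correlation time 2/γ is rejected. Default parameter
  magnitudes in tests follow the motivating study's tabulated regime
  (means 3.6–14 kJ/mol for bright channels, σ ≈ 6.5–7.1 kJ/mol, mean
  speeds ≈ 0.4 kJ mol⁻¹ fs⁻¹, 1 fs sampling, 500-trajectory ensembles).
- `gen_field_frames()`: exact multivariate AR(1)/OU sampling of site
  potentials and the reference field with requested stationary covariance
  and per-component correlation times.
- `gen_toy_qc()`: neutral per-state charge sets, symmetric transition
  dipoles, mode sets spanning both classical and quantum regimes at
  300 K.

One global seed expands deterministically into decoupled stream seeds
(`expand_seed()`: gap, fields, starts, bootstrap), giving end-to-end
bit-reproducibility, which the acceptance suite asserts.

These surrogates deliberately do **not** reproduce a real solvent's
spectral density, non-Gaussian tails, or the coupling between field
components and the gap; passing tests therefore demonstrate the
correctness of the estimators under the model's own assumptions, not the
accuracy of those assumptions for any particular chromophore/solvent
system.

## 6. Numerical choices and degenerate inputs

- Eigen decomposition via the symmetric QR path; eigenvalues ascending;
  eigenvector sign fixed by making the largest-magnitude component
  positive; ties broken by input order with a $10^{-12}$ kJ/mol
  degeneracy tolerance. Orthonormality and trace conservation are asserted
  to $10^{-10}$/$10^{-9}$ on every test diagonalization, and eigenvalues
  are cross-checked to $10^{-8}$ against an independent
  characteristic-polynomial root finder.
- Crossing interpolation is linear in the bracketing step — consistent
  with the trace resolution; the analytic-sinusoid test bounds the error
  by half a step.
- Zero-variance field components, all-dark dipole sets, never-crossing
  traces, constant survival curves, non-PSD covariances and
  charge-inconsistent state sets are all explicit, tested degenerate
  paths (absent value, error, or censoring as appropriate — never a
  silent NaN).
- Problem sizes in the default test run are chosen for tight Monte Carlo
  bounds at interactive runtimes: 2000 × 1500-step ensembles for the
  crossing-rate oracle, 4000-sample survival refits, 5 × 10⁴-frame field
  streams; the full suite runs in well under a minute.

## 7. Known limitations

- No electronic-structure or MD capability: energies, charges, dipoles,
  modes, potentials and fields are inputs (plain text formats; JSON for
  quantum centers, delimited tables for frames, traces, spectra and
  results).
- The Landau–Zener treatment counts transitions at crossings; it does not
  propagate electronic wavefunctions or surface-hopping trajectories, and
  dark-state → ground-state internal conversion is out of scope.
- The mean-coupling route inherits the weak-coupling accuracy of the
  $\langle e^{-x}\rangle \to e^{-\langle x\rangle}$ step and assumes
  $E_\parallel$, $E_\perp$ statistically independent.
- The Gaussian-approximation rate is an equilibrium-ensemble statement; in
  regimes with reactant inner relaxations comparable to the reaction time
  (frequent crossings), the explicit survival route and the Gaussian route
  legitimately differ — both are reported, and the package makes no
  attempt to reconcile them.
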