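# pmmkin

Excited-state relaxation kinetics of solvated chromophores from perturbed
matrix method (PMM) trajectories.

## The problem

The fluorescence of indole — and hence of tryptophan, the workhorse
intrinsic probe of protein structure — is controlled by what the first
singlet excited state does after excitation in water: the nearly degenerate
bright states Lb and La interconvert on the sub-picosecond scale, their
equilibrium mixture emits, and both feed an optically dark πσ* state that
quenches the emission irreversibly. Reconstructing that network from
simulation requires per-frame excited-state energies in the fluctuating
solvent field, first-passage statistics of diabatic energy-gap crossings,
and a way to turn crossing statistics into rate constants.

`pmmkin` implements that pipeline for users of QM/MM electrostatic
embedding of the perturbed-matrix-method type:

- **PMM electronic structure per frame.** The electronic Hamiltonian in the
  basis of unperturbed (gas-phase) eigenstates: diagonal elements
  `ε_j⁰ + Σ_N q_{N,j}⁰ V(R_N) + ΔV`, off-diagonal couplings
  `−E(r₀)·μ_{j,l}⁰`; diagonalization, diabatic-character assignment and
  diabatic gaps (`build_hamiltonian()`, `pmm_diagonalize()`,
  `diabatic_gap()`).
- **Crossing kinetics.** First crossings of gap trajectories, survival
  curves and constrained biexponential fits giving the fully adiabatic
  attempt lifetime `τ₀ = n₁τ₁ + n₂τ₂`; Landau–Zener adiabatic fractions
  `χ_e = 1 − exp(−2π|H̄|²/(ℏ v_cr))`; transmission coefficients
  `α_G = 1 − ⟨(1 − χ_e)^Ω⟩` (explicit) or `1 − (1 − α_e)^⟨Ω⟩`
  (approximate); the Gaussian-approximation attempt rate
  `k⁰ = ½⟨v⟩ ρ(0; ⟨ΔU⟩, σ)` (Rice's level-crossing rate); the
  crossing-mean-coupling route to `α_e` from equilibrium field statistics;
  and the reaction lifetime `τ = τ₀ / (1 − (1 − α_G)²)`.
- **Vibronic spectra.** Poisson Franck–Condon factors
  `ξ_n² = e^{−S} Sⁿ/n!` for displaced identical-frequency modes, binned
  vertical spectra with `ν` (absorption) / `ν³` (emission) weighting,
  vibronic progressions, equilibrium-weighted band mixtures and
  Einstein-A radiative lifetimes.
- **The relaxation network.** `ΔA → K_eq → (f_b, f_a)` via Boltzmann
  statistics, population-weighted harmonic lifetimes
  `τ_r = (f_b/τ_r,b + f_a/τ_r,a)⁻¹`, `τ_nr = (f_b/τ_b + f_a/τ_a)⁻¹`,
  fluorescence lifetime `τ_F = (1/τ_r + 1/τ_nr)⁻¹` and quantum yield
  `Φ = τ_F/τ_r`, with optional intersystem crossing and delta-method
  uncertainty propagation.
- **Synthetic surrogates.** Seeded exact-kernel Langevin gap trajectories,
  Ornstein–Uhlenbeck field/potential streams and random-but-physical toy
  quantum centers, so the whole pipeline is testable without any MD or
  quantum-chemistry run.

Units throughout: energy kJ/mol, time fs (lifetimes in ns where noted),
charge e, length nm, field kJ mol⁻¹ e⁻¹ nm⁻¹; ℏ = 63.5078 kJ mol⁻¹ fs.

## Worked example

First-crossing kinetics on a synthetic reactant ensemble (500 seeded
Langevin gap trajectories with mean 14.2 kJ/mol, σ 7.1 kJ/mol, mean speed
0.4 kJ mol⁻¹ fs⁻¹), compared against the Gaussian-approximation route:

```r
library(pmmkin)

ens <- gen_gap_ensemble(500, 4000, mean = 14.2, sd = 7.1,
                        sd_v = 0.4 / sqrt(2 / pi), dt = 1, seed = 11)
pos <- which(ens$gap[1, ] > 0)
tcr <- vapply(pos, function(j) {
  e <- detect_first_crossing(gap_trace(ens$times, ens$gap[, j], ens$deriv[, j]))
  if (is.null(e)) NA_real_ else e$time
}, numeric(1))

fit_survival(survival_trace(tcr, 4000))
#> exponential survival fit: tau0 = 607.7 fs

gaussian_rate(gap_statistics(as.numeric(ens$gap), as.numeric(ens$deriv)))
#> rate estimate (gaussian): tau0 = 644.6 fs
```

The explicit first-passage fit and the equilibrium-statistics estimate
agree within ~6 % in this rare-crossing regime — the regime in which the
Gaussian shortcut is meant to replace explicit crossing sampling.

The relaxation network, from component lifetimes (ns) and the
bright-state free energy (kJ/mol), with propagated standard errors:

```r
sc <- relaxation_scheme(dA = -5.01, tau_r_b = 56, tau_r_a = 20,
                        tau_b = 11.0, tau_a = 3.7,
                        se = list(dA = 0.5, tau_b = 0.5, tau_a = 0.4))
sc
#> Bright-state relaxation scheme (fast Lb <-> La pre-equilibrium)
#>   dA = -5.010 kJ/mol at 300 K -> K_eq = 7.452, f_b = 0.118, f_a = 0.882
#>   tau_r = 21.6 ns, tau_nr = 4.02 ns
#>   tau_F = 3.39 ns, quantum yield Phi = 0.156
```

So a 12 % Lb / 88 % La equilibrium mixture emits with a ~3.4 ns
fluorescence lifetime and a quantum yield of ~0.16; `network_summary(sc)`
returns the full chain as a table with delta-method standard errors
(e.g. K_eq 7.45 ± 1.49, τ_nr 4.02 ± 0.42 ns).

## Documentation

The methods vignette (`vignettes/excited-state-kinetics.Rmd`) documents
the model, its assumptions, the tunable parameters, what the synthetic
generators do and do not emulate, and the numerical choices. Every
exported function has a help page.
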