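Package: pmmkin
Title: Excited-State Relaxation Kinetics from Perturbed Matrix Method Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the relaxation kinetics of solvated
    chromophore excited states from classical perturbation trajectories.
    Builds and diagonalizes perturbed electronic Hamiltonians (QM/MM
    electrostatic embedding in the unperturbed eigenstate basis), assigns
    diabatic character, and follows diabatic energy-gap trajectories to
    their first crossings.  Crossing statistics are converted to rate
    constants through Landau-Zener transmission coefficients, a
    Gaussian-approximation (level-crossing) attempt rate, and a
    crossing-mean-coupling estimate of the electronic transmission
    coefficient.  Franck-Condon factors for displaced harmonic modes give
    vibronic absorption and emission spectra and radiative lifetimes, and a
    two-state bright-state equilibrium feeding an irreversible dark channel
    yields combined radiative, nonradiative and fluorescence lifetimes and
    the quantum yield.  Seeded Langevin and Ornstein-Uhlenbeck surrogate
    generators provide statistically controlled synthetic inputs so the
    full pipeline can be exercised and validated without any molecular
    dynamics or quantum chemistry run.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
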