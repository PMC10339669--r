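# Shared in-code fixtures: tiny quantum centers with hand-checkable numbers.

# Two-state, two-atom QC: unperturbed energies 0 and `gap0`, neutral charge
# sets whose difference is (+0.1, -0.1) e, transition dipole `mu01`.
toy_qc_2state <- function(gap0 = 10, mu01 = c(0.04, 0, 0)) {
  sR <- unperturbed_state("GS", 0, c(-0.05, 0.05), c(0.02, 0, 0))
  sP <- unperturbed_state("Lb", gap0, c(0.05, -0.05), c(0.10, 0, 0))
  td <- array(0, c(2, 2, 3))
  td[1, 1, ] <- sR$diagonal_dipole
  td[2, 2, ] <- sP$diagonal_dipole
  td[1, 2, ] <- mu01
  td[2, 1, ] <- mu01
  quantum_center(list(sR, sP), td)
}

# Perturbed-state stub with prescribed coefficient columns (for testing the
# diabatic-assignment rule in isolation).
fake_perturbed_state <- function(coefficients, labels,
                                 energies = seq_len(ncol(coefficients))) {
  structure(list(energies = energies, coefficients = coefficients,
                 transition_dipoles = matrix(0, ncol(coefficients), 3),
                 labels = labels),
            class = "perturbed_state")
}

# First-crossing times of every positive-start column of a gap ensemble.
ensemble_crossing_times <- function(ens) {
  pos <- which(ens$gap[1L, ] > 0)
  vapply(pos, function(j) {
    e <- detect_first_crossing(
      gap_trace(ens$times, ens$gap[, j], ens$deriv[, j]))
    if (is.null(e)) NA_real_ else e$time
  }, numeric(1))
}

# Empirical zero-downcrossing rate of a gap ensemble (crossings per fs).
ensemble_downcrossing_rate <- function(ens) {
  g <- ens$gap
  down <- sum(g[-nrow(g), ] > 0 & g[-1L, ] <= 0)
  down / (ncol(g) * (nrow(g) - 1L) * ens$dt)
}
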