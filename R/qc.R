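#' Unperturbed electronic state of a quantum center
#'
#' One gas-phase (unperturbed) electronic eigenstate of the chromophore:
#' its energy, per-atom point charges, permanent (diagonal) dipole and an
#' optional vibronic energy correction.  The correction is the shift applied
#' to any diabatic gap involving this state (relative to the ground state),
#' typically used to match experimental gas-phase 0-0 transition energies.
#'
#' @param label State label, one of `"GS"`, `"Lb"`, `"La"`, `"piSigma"` or
#'   any other identifier.
#' @param energy Unperturbed electronic energy, kJ/mol.
#' @param charges Numeric vector of atomic point charges (e), one per atom.
#' @param diagonal_dipole Permanent dipole 3-vector, e nm.
#' @param vibronic_correction Gap correction involving this state, kJ/mol
#'   (default 0).
#' @return An object of class `"unperturbed_state"`.
#' @export
unperturbed_state <- function(label, energy, charges, diagonal_dipole,
                              vibronic_correction = 0) {
  stopifnot(is.character(label), length(label) == 1L)
  .assert_scalar(energy, "energy")
  .assert_finite(charges, "charges")
  .assert_finite(diagonal_dipole, "diagonal_dipole")
  if (length(diagonal_dipole) != 3L)
    stop("diagonal_dipole must be a 3-vector", call. = FALSE)
  .assert_scalar(vibronic_correction, "vibronic_correction")
  structure(
    list(label = label, energy = energy, charges = as.numeric(charges),
         diagonal_dipole = as.numeric(diagonal_dipole),
         vibronic_correction = vibronic_correction),
    class = "unperturbed_state")
}

#' Quantum center: the subsystem treated quantum mechanically
#'
#' Bundles the unperturbed electronic description of the chromophore: a set
#' of [unperturbed_state()]s sharing one atom list, the matrix of transition
#' dipoles between them, and (optionally) per-state vibronic mode sets used
#' for Franck-Condon factors.  The environment enters the model only through
#' the electric potential it exerts at the atom positions and the field at a
#' reference point (see [perturbation_frame()]).
#'
#' @param states List of [unperturbed_state()] objects (first is taken as the
#'   reference/ground state unless `reference` says otherwise).
#' @param transition_dipoles Numeric array `c(n_states, n_states, 3)` of
#'   transition dipole 3-vectors in e nm; must be symmetric in its first two
#'   indices and its diagonal must equal the states' diagonal dipoles.
#' @param atoms Optional data frame with columns `element`, `mass` (amu) and
#'   `x`, `y`, `z` (nm reference positions).
#' @param mode_sets Optional named list of [vibronic_mode_set()] objects,
#'   one per state label.
#' @param charge_tol Tolerance for the shared-total-charge invariant (e).
#' @return An object of class `"quantum_center"`.
#' @seealso [build_hamiltonian()], [pmm_diagonalize()], [read_quantum_center()]
#' @export
quantum_center <- function(states, transition_dipoles, atoms = NULL,
                           mode_sets = NULL, charge_tol = 1e-9) {
  if (!is.list(states) || length(states) < 2L)
    stop("need at least two unperturbed states", call. = FALSE)
  if (!all(vapply(states, inherits, logical(1), "unperturbed_state")))
    stop("states must be unperturbed_state objects", call. = FALSE)
  n <- length(states)
  labels <- vapply(states, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("state labels must be unique", call. = FALSE)

  n_atoms <- length(states[[1L]]$charges)
  for (s in states)
    if (length(s$charges) != n_atoms)
      stop("all states must carry one charge per atom", call. = FALSE)
  qtot <- vapply(states, function(s) sum(s$charges), numeric(1))
  if (max(qtot) - min(qtot) > charge_tol)
    stop("total charge differs across states beyond tolerance", call. = FALSE)

  td <- transition_dipoles
  if (!is.array(td) || !identical(dim(td), c(n, n, 3L)))
    stop("transition_dipoles must be an (n, n, 3) array", call. = FALSE)
  .assert_finite(td, "transition_dipoles")
  for (k in 1:3)
    if (max(abs(td[, , k] - t(td[, , k]))) > 1e-10)
      stop("transition dipole matrix must be symmetric", call. = FALSE)
  for (j in seq_len(n))
    if (max(abs(td[j, j, ] - states[[j]]$diagonal_dipole)) > 1e-10)
      stop("diagonal of transition_dipoles must equal diagonal dipoles",
           call. = FALSE)

  if (!is.null(atoms)) {
    stopifnot(is.data.frame(atoms),
              all(c("element", "mass", "x", "y", "z") %in% names(atoms)))
    if (nrow(atoms) != n_atoms)
      stop("atoms table does not match charge-list length", call. = FALSE)
  }
  if (!is.null(mode_sets)) {
    if (is.null(names(mode_sets)) || !all(names(mode_sets) %in% labels))
      stop("mode_sets must be named by state label", call. = FALSE)
  }

  structure(
    list(states = states, labels = labels, transition_dipoles = td,
         atoms = atoms, mode_sets = mode_sets, n_states = n,
         n_atoms = n_atoms),
    class = "quantum_center")
}

#' @export
print.quantum_center <- function(x, ...) {
  cat("Quantum center:", x$n_states, "electronic states,",
      x$n_atoms, "atoms\n")
  e <- vapply(x$states, `[[`, numeric(1), "energy")
  cat(sprintf("  %-8s %12s %10s\n", "label", "energy kJ/mol", "|mu| e nm"))
  for (j in seq_len(x$n_states)) {
    mu <- sqrt(sum(x$states[[j]]$diagonal_dipole^2))
    cat(sprintf("  %-8s %12.3f %10.4f\n", x$labels[j], e[j], mu))
  }
  invisible(x)
}

#' One frame of the classical perturbation
#'
#' The state of the environment at one time point: the electric potential at
#' every quantum-center atom position, the electric field at the reference
#' point (typically the center of mass), and a state-independent scalar
#' offset collecting higher-order diagonal terms (it cancels in every energy
#' gap and defaults to 0).
#'
#' @param time Time, fs.
#' @param site_potentials Potential at each atom, kJ mol^-1 e^-1.
#' @param field Field 3-vector at the reference point, kJ mol^-1 e^-1 nm^-1.
#' @param offset Scalar diagonal offset, kJ/mol.
#' @return An object of class `"perturbation_frame"`.
#' @export
perturbation_frame <- function(time, site_potentials, field, offset = 0) {
  .assert_scalar(time, "time")
  .assert_finite(site_potentials, "site_potentials")
  .assert_finite(field, "field")
  if (length(field) != 3L) stop("field must be a 3-vector", call. = FALSE)
  .assert_scalar(offset, "offset")
  structure(
    list(time = time, site_potentials = as.numeric(site_potentials),
         field = as.numeric(field), offset = offset),
    class = "perturbation_frame")
}
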