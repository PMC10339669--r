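#' Build the perturbed electronic Hamiltonian matrix
#'
#' Represents the electronic Hamiltonian of the quantum center in the basis
#' of its unperturbed eigenstates under electrostatic embedding.  Diagonal
#' element \eqn{j} is the unperturbed energy plus the interaction of the
#' state's atomic point charges with the instantaneous site potentials
#' (plus the state-independent offset); off-diagonal element \eqn{(j,l)} is
#' the dipolar coupling \eqn{-\mathbf{E}(\mathbf{r}_0)\cdot
#' \boldsymbol{\mu}^0_{j,l}} with the field at the reference point.
#'
#' @param qc A [quantum_center()].
#' @param frame A [perturbation_frame()] with one potential per atom.
#' @return Real symmetric `n_states` x `n_states` matrix, kJ/mol, with the
#'   state labels as dimnames.
#' @examples
#' qc <- gen_toy_qc(3, 5, seed = 1)
#' fr <- perturbation_frame(0, rep(0, 5), c(0, 0, 0))
#' build_hamiltonian(qc, fr)  # diagonal: the unperturbed energies
#' @export
build_hamiltonian <- function(qc, frame) {
  stopifnot(inherits(qc, "quantum_center"), inherits(frame, "perturbation_frame"))
  if (length(frame$site_potentials) != qc$n_atoms)
    stop("site_potentials length does not match quantum-center atom count",
         call. = FALSE)
  n <- qc$n_states
  H <- matrix(0, n, n, dimnames = list(qc$labels, qc$labels))
  for (j in seq_len(n)) {
    s <- qc$states[[j]]
    H[j, j] <- s$energy + sum(s$charges * frame$site_potentials) + frame$offset
  }
  for (j in seq_len(n)) for (l in seq_len(n)) {
    if (j != l) H[j, l] <- -sum(frame$field * qc$transition_dipoles[j, l, ])
  }
  H
}

#' Diagonalize a perturbed Hamiltonian
#'
#' Eigen-decomposition of the perturbed electronic Hamiltonian with
#' eigenvalues in ascending order, plus the perturbed transition dipoles
#' from the perturbed ground state, obtained by rotating the unperturbed
#' dipole matrix with the eigenvector coefficients:
#' \eqn{\boldsymbol{\mu}_{0,i} = \sum_{j,l} c_{j0} c_{li}
#' \boldsymbol{\mu}^0_{j,l}}.
#'
#' @param H Real symmetric matrix from [build_hamiltonian()] (kJ/mol).
#' @param qc The [quantum_center()] the Hamiltonian was built from.
#' @param sym_tol Tolerance on the symmetry check, kJ/mol.
#' @return Object of class `"perturbed_state"`: list with `energies`
#'   (ascending, kJ/mol), `coefficients` (columns are perturbed states in
#'   the unperturbed basis), `transition_dipoles` (3-vectors, rows are
#'   perturbed states \eqn{0 \to i}, e nm) and `labels` (unperturbed basis
#'   labels).
#' @export
pmm_diagonalize <- function(H, qc, sym_tol = 1e-8) {
  stopifnot(is.matrix(H), nrow(H) == ncol(H))
  if (max(abs(H - t(H))) > sym_tol)
    stop("Hamiltonian must be symmetric", call. = FALSE)
  stopifnot(inherits(qc, "quantum_center"), nrow(H) == qc$n_states)
  es <- eigen(H, symmetric = TRUE)
  ord <- order(es$values)            # eigen() returns decreasing order
  vals <- es$values[ord]
  vecs <- es$vectors[, ord, drop = FALSE]
  # fix sign convention: largest-|.| component positive
  for (i in seq_len(ncol(vecs))) {
    k <- which.max(abs(vecs[, i]))
    if (vecs[k, i] < 0) vecs[, i] <- -vecs[, i]
  }
  n <- nrow(H)
  mu <- matrix(0, n, 3)
  c0 <- vecs[, 1L]
  for (k in 1:3) {
    Mk <- qc$transition_dipoles[, , k]
    mu[, k] <- as.numeric(crossprod(vecs, Mk %*% c0))  # c0' Mk ci for each i
  }
  structure(
    list(energies = vals, coefficients = vecs, transition_dipoles = mu,
         labels = qc$labels),
    class = "perturbed_state")
}

#' @export
print.perturbed_state <- function(x, ...) {
  cat("Perturbed electronic states (kJ/mol):\n")
  for (i in seq_along(x$energies)) {
    a <- assign_diabatic_character(i, x)
    cat(sprintf("  %d: %12.4f  ~ %-8s (weight %.3f)\n",
                i - 1L, x$energies[i], a$label, a$weight))
  }
  invisible(x)
}

#' Assign diabatic character to a perturbed state
#'
#' Maps perturbed state `i` back onto the unperturbed (diabatic) basis.  The
#' default metric picks the basis state with the largest squared eigenvector
#' coefficient; the `"dipole"` metric instead compares the perturbed
#' transition dipole direction against the unperturbed ones (cosine
#' similarity of \eqn{0 \to i} dipoles), which mirrors identifying states by
#' their distinguishable diagonal/transition dipoles.
#'
#' @param state_index 1-based index of the perturbed state.
#' @param ps A `"perturbed_state"` from [pmm_diagonalize()].
#' @param method `"coefficient"` (default) or `"dipole"`.
#' @param qc Required for `method = "dipole"`: the [quantum_center()].
#' @param tie_tol Two winning weights closer than this flag a tie; the
#'   lower-energy (lower-index) label is returned.
#' @return List with `label`, `weight` (winning squared coefficient or
#'   squared cosine), `index` (unperturbed index) and logical `tie`.
#' @export
assign_diabatic_character <- function(state_index, ps,
                                      method = c("coefficient", "dipole"),
                                      qc = NULL, tie_tol = 1e-12) {
  method <- match.arg(method)
  stopifnot(inherits(ps, "perturbed_state"))
  i <- as.integer(state_index)
  stopifnot(i >= 1L, i <= length(ps$energies))
  if (method == "coefficient") {
    w <- ps$coefficients[, i]^2
  } else {
    if (is.null(qc)) stop("dipole method needs the quantum center", call. = FALSE)
    mu_i <- ps$transition_dipoles[i, ]
    ni <- sqrt(sum(mu_i^2))
    w <- vapply(seq_along(ps$labels), function(j) {
      mu_j <- qc$transition_dipoles[1L, j, ]
      nj <- sqrt(sum(mu_j^2))
      if (ni < 1e-14 || nj < 1e-14) return(0)
      (sum(mu_i * mu_j) / (ni * nj))^2
    }, numeric(1))
  }
  best <- max(w)
  idx <- which(w >= best - tie_tol)
  list(label = ps$labels[idx[1L]], weight = w[idx[1L]],
       index = idx[1L], tie = length(idx) > 1L)
}

#' Diabatic transition energy (gap) for one frame
#'
#' The reactant-to-product diabatic energy difference provided by the
#' diagonal elements of the perturbed Hamiltonian,
#' \eqn{[H]_{PP} - [H]_{RR}}, plus the configured vibronic correction
#' difference of the two states.  Positive means the product diabat lies
#' above the reactant one; its first zero along a trajectory is a diabatic
#' crossing.
#'
#' @param qc A [quantum_center()].
#' @param frame A [perturbation_frame()].
#' @param R,P Reactant and product state labels.
#' @param apply_correction Include the states' `vibronic_correction`
#'   difference (default TRUE).
#' @return Gap in kJ/mol.
#' @export
diabatic_gap <- function(qc, frame, R, P, apply_correction = TRUE) {
  stopifnot(inherits(qc, "quantum_center"))
  if (identical(R, P)) stop("R and P must differ", call. = FALSE)
  iR <- match(R, qc$labels); iP <- match(P, qc$labels)
  if (is.na(iR) || is.na(iP))
    stop("unknown state label", call. = FALSE)
  H <- build_hamiltonian(qc, frame)
  g <- H[iP, iP] - H[iR, iR]
  if (apply_correction)
    g <- g + qc$states[[iP]]$vibronic_correction -
      qc$states[[iR]]$vibronic_correction
  unname(g)
}

#' Per-frame PMM sweep over a list of perturbation frames
#'
#' Convenience driver: builds and diagonalizes the perturbed Hamiltonian at
#' every frame and collects energies, first-excited-state diabatic
#' assignment and a chosen diabatic gap.
#'
#' @param qc A [quantum_center()].
#' @param frames List of [perturbation_frame()] objects.
#' @param gap Optional character pair `c(R, P)` of labels whose diabatic gap
#'   is recorded per frame.
#' @return Data frame with one row per frame: `time`, `E0..E(n-1)`
#'   (perturbed energies), `state1_label`, `state1_weight` and, when `gap`
#'   is given, `gap_RP`.
#' @export
pmm_sweep <- function(qc, frames, gap = NULL) {
  stopifnot(is.list(frames), length(frames) > 0L)
  n <- qc$n_states
  out <- vector("list", length(frames))
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    H <- build_hamiltonian(qc, fr)
    ps <- pmm_diagonalize(H, qc)
    a <- assign_diabatic_character(2L, ps)
    row <- c(time = fr$time, stats::setNames(ps$energies, paste0("E", 0:(n - 1))))
    rec <- as.list(row)
    rec$state1_label <- a$label
    rec$state1_weight <- a$weight
    if (!is.null(gap))
      rec$gap <- diabatic_gap(qc, fr, gap[1L], gap[2L])
    out[[f]] <- rec
  }
  df <- do.call(rbind.data.frame, c(out, stringsAsFactors = FALSE))
  if (!is.null(gap))
    names(df)[names(df) == "gap"] <- paste0("gap_", gap[1L], "_", gap[2L])
  df
}
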