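# 2x2 matrix exponential, robust to the degenerate (critically damped) case
.expm2 <- function(A) {
  es <- eigen(A)
  if (abs(es$values[1L] - es$values[2L]) > 1e-10) {
    V <- es$vectors
    Re(V %*% diag(exp(es$values)) %*% solve(V))
  } else {
    lam <- Re(es$values[1L])
    exp(lam) * (diag(2) + (A - lam * diag(2)))
  }
}

# symmetric PSD square root (tolerates tiny negative eigenvalues and exact
# zeros, e.g. degenerate field components)
.psd_sqrt <- function(Q, tol = 1e-10) {
  Q <- (Q + t(Q)) / 2
  es <- eigen(Q, symmetric = TRUE)
  lam <- es$values
  if (any(lam < -tol * max(abs(lam), 1)))
    stop("covariance must be positive semidefinite", call. = FALSE)
  es$vectors %*% (sqrt(pmax(lam, 0)) * t(es$vectors))
}

# Discrete transition kernel of the stationary underdamped Langevin gap
# process: position marginal N(mean, sd^2), velocity marginal N(0, sd_v^2).
.gap_kernel <- function(sd, sd_v, gamma, dt) {
  w0 <- sd_v / sd
  A <- matrix(c(0, 1, -w0^2, -gamma), 2L, 2L, byrow = TRUE)
  M <- .expm2(A * dt)
  Sinf <- diag(c(sd^2, sd_v^2))
  Q <- Sinf - M %*% Sinf %*% t(M)
  list(M = M, L = .psd_sqrt(Q), Sinf = Sinf, w0 = w0)
}

#' Ensemble of stationary Langevin gap trajectories
#'
#' Simulates `n_traj` independent realizations of a second-order
#' (underdamped) Langevin process whose stationary position marginal is
#' Gaussian(`mean`, `sd`^2) and whose velocity marginal is Gaussian(0,
#' `sd_v`^2) — the differentiable stationary Gaussian surrogate for a
#' diabatic transition-energy trajectory.  The update uses the exact
#' Gaussian transition kernel of the discretized process (no step-size
#' bias); trajectories start from the stationary distribution.
#'
#' @param n_traj Number of trajectories.
#' @param n_steps Number of time steps (trajectory has `n_steps + 1`
#'   samples).
#' @param mean Stationary mean gap, kJ/mol.
#' @param sd Stationary gap standard deviation, kJ/mol (> 0).
#' @param sd_v Stationary gap-speed standard deviation, kJ mol^-1 fs^-1.
#' @param dt Time step, fs (default 1).
#' @param gamma Friction, fs^-1; default equals the oscillator frequency
#'   `sd_v/sd` (moderately underdamped).  The velocity correlation time is
#'   about `2/gamma`; `dt` must resolve it (>= 20 samples), else an error
#'   is thrown.
#' @param seed Stream seed (expanded via [expand_seed()]).
#' @return List with matrices `gap` and `deriv` (`n_steps + 1` rows,
#'   `n_traj` columns), `times` and the spec fields.
#' @seealso [gen_gap_trace()] for a single [gap_trace()].
#' @export
gen_gap_ensemble <- function(n_traj, n_steps, mean, sd, sd_v, dt = 1,
                             gamma = NULL, seed = 1L) {
  .assert_scalar(sd, "sd", positive = TRUE)
  .assert_scalar(sd_v, "sd_v", positive = TRUE)
  .assert_scalar(dt, "dt", positive = TRUE)
  if (is.null(gamma)) gamma <- sd_v / sd
  .assert_scalar(gamma, "gamma", positive = TRUE)
  tau_c <- 2 / gamma
  if (dt > tau_c / 20)
    stop(sprintf(paste0("time step %.3g fs too coarse for correlation time",
                        " %.3g fs (need >= 20 samples per correlation time)"),
                 dt, tau_c), call. = FALSE)
  ker <- .gap_kernel(sd, sd_v, gamma, dt)
  set.seed(expand_seed(seed, "gap"))
  X <- matrix(0, n_steps + 1L, n_traj)
  V <- matrix(0, n_steps + 1L, n_traj)
  z0 <- matrix(stats::rnorm(2L * n_traj), 2L)
  s0 <- .psd_sqrt(ker$Sinf) %*% z0
  X[1L, ] <- mean + s0[1L, ]
  V[1L, ] <- s0[2L, ]
  M <- ker$M; L <- ker$L
  for (t in seq_len(n_steps)) {
    e <- L %*% matrix(stats::rnorm(2L * n_traj), 2L)
    x <- X[t, ] - mean
    X[t + 1L, ] <- mean + M[1L, 1L] * x + M[1L, 2L] * V[t, ] + e[1L, ]
    V[t + 1L, ] <- M[2L, 1L] * x + M[2L, 2L] * V[t, ] + e[2L, ]
  }
  list(gap = X, deriv = V, times = (0:n_steps) * dt,
       mean = mean, sd = sd, sd_v = sd_v, dt = dt, gamma = gamma,
       seed = seed)
}

#' Single stationary Langevin gap trace
#'
#' One realization of the process of [gen_gap_ensemble()], returned as a
#' [gap_trace()] carrying the exactly simulated velocity.
#'
#' @inheritParams gen_gap_ensemble
#' @param duration Trace length, fs.
#' @return A [gap_trace()].
#' @examples
#' tr <- gen_gap_trace(3.62, 7.1, 0.4, duration = 500, seed = 7)
#' @export
gen_gap_trace <- function(mean, sd, sd_v, dt = 1, duration = 1000,
                          gamma = NULL, seed = 1L) {
  n_steps <- ceiling(duration / dt)
  ens <- gen_gap_ensemble(1L, n_steps, mean, sd, sd_v, dt = dt,
                          gamma = gamma, seed = seed)
  gap_trace(ens$times, ens$gap[, 1L], deriv = ens$deriv[, 1L])
}

#' Reactant-side start frames from an equilibrium trace
#'
#' Mirrors the nonequilibrium start-selection protocol: the trace is split
#' into `n` equal blocks; within each block frames are drawn at random and
#' discarded until one with a positive gap is found.  Blocks with no
#' positive-gap frame are skipped with a warning.
#'
#' @param trace A [gap_trace()].
#' @param n Number of starts (blocks).
#' @param seed Stream seed.
#' @return Integer vector of start indices (length <= n).
#' @export
gen_reactant_starts <- function(trace, n, seed = 1L) {
  stopifnot(inherits(trace, "gap_trace"))
  n <- as.integer(n)
  nf <- length(trace$gap)
  if (nf < n) stop("trace shorter than the number of blocks", call. = FALSE)
  set.seed(expand_seed(seed, "starts"))
  bounds <- floor(seq(0L, nf, length.out = n + 1L))
  starts <- integer(0)
  skipped <- 0L
  for (b in seq_len(n)) {
    idx <- (bounds[b] + 1L):bounds[b + 1L]
    idx <- idx[sample.int(length(idx))]
    hit <- idx[trace$gap[idx] > 0]
    if (length(hit)) starts <- c(starts, hit[1L]) else skipped <- skipped + 1L
  }
  if (skipped > 0L)
    warning(sprintf("%d block(s) had no positive-gap frame and were skipped",
                    skipped))
  starts
}

#' Random but physically consistent toy quantum center
#'
#' Generates a [quantum_center()] with neutral per-state charge sets, a
#' symmetric transition-dipole matrix, ascending state energies and
#' per-state vibronic mode sets whose frequencies span the classical and
#' quantum regimes at the given temperature.  Intended for exercising the
#' PMM and spectra machinery without any electronic-structure input.
#'
#' @param n_states Number of electronic states (>= 2).
#' @param n_atoms Number of atoms.
#' @param seed Stream seed.
#' @param temperature K (mode classification).
#' @return A [quantum_center()] with labels `GS`, `Lb`, `piSigma`, `La`,
#'   `S4`, ... (in ascending energy order).
#' @export
gen_toy_qc <- function(n_states, n_atoms, seed = 1L, temperature = 300) {
  stopifnot(n_states >= 2L, n_atoms >= 2L)
  set.seed(expand_seed(seed, "qc"))
  base_labels <- c("GS", "Lb", "piSigma", "La")
  labels <- if (n_states <= 4L) base_labels[seq_len(n_states)] else
    c(base_labels, paste0("S", 4:(n_states - 1L)))
  energies <- c(0, sort(stats::runif(n_states - 1L, 350, 480)))

  mk_charges <- function() {
    q <- stats::runif(n_atoms, -0.4, 0.4)
    q - mean(q)                       # neutral
  }
  states <- vector("list", n_states)
  dip <- array(0, c(n_states, n_states, 3L))
  for (j in seq_len(n_states)) {
    mu_d <- stats::rnorm(3L, 0, 0.05)
    states[[j]] <- unperturbed_state(labels[j], energies[j], mk_charges(), mu_d)
    dip[j, j, ] <- mu_d
  }
  for (j in seq_len(n_states)) for (l in seq_len(n_states)) {
    if (l > j) {
      mu_t <- stats::rnorm(3L, 0, 0.03)
      dip[j, l, ] <- mu_t
      dip[l, j, ] <- mu_t
    }
  }

  kBT <- .kB * temperature
  w_split <- kBT / .hbar                 # classical/quantum frequency split
  mode_sets <- stats::setNames(vector("list", n_states), labels)
  for (j in seq_len(n_states)) {
    w <- c(stats::runif(2L, 0.2 * w_split, 0.8 * w_split),   # classical
           stats::runif(3L, 2 * w_split, 10 * w_split))      # quantum
    S_target <- stats::runif(5L, 0.05, 0.8)
    d <- sqrt(2 * .hbar * S_target / (w * .amu_nm2_fs2))
    mode_sets[[j]] <- vibronic_mode_set(w, d, temperature)
  }

  atoms <- data.frame(element = rep("C", n_atoms),
                      mass = rep(12.011, n_atoms),
                      x = stats::rnorm(n_atoms, 0, 0.15),
                      y = stats::rnorm(n_atoms, 0, 0.15),
                      z = stats::rnorm(n_atoms, 0, 0.05))
  quantum_center(states, dip, atoms = atoms, mode_sets = mode_sets)
}

#' Ornstein-Uhlenbeck perturbation-frame stream
#'
#' Samples site potentials and the reference-point field as a stationary
#' multivariate AR(1) (exact OU discretization): component i decorrelates
#' as \eqn{\exp(-\Delta t / \tau_i)} and the joint stationary covariance is
#' `cov`.  The innovation covariance \eqn{Q = \Sigma - \Phi\Sigma\Phi} must
#' be positive semidefinite (guaranteed for a common correlation time; an
#' error is raised otherwise).
#'
#' @param n Number of frames.
#' @param n_atoms Number of site potentials (components `1:n_atoms`; the
#'   final 3 components are the field vector).
#' @param mean Stationary mean vector, length `n_atoms + 3` (potentials in
#'   kJ mol^-1 e^-1, field in kJ mol^-1 e^-1 nm^-1), or a scalar.
#' @param cov Stationary covariance matrix (`n_atoms + 3` square, PSD) or
#'   a variance vector (diagonal covariance) or scalar.
#' @param tau_c Correlation time(s), fs: scalar or per component.
#' @param dt Frame spacing, fs.
#' @param seed Stream seed.
#' @return List of [perturbation_frame()] objects of length `n`.
#' @export
gen_field_frames <- function(n, n_atoms, mean = 0, cov = 1, tau_c = 50,
                             dt = 1, seed = 1L) {
  p <- n_atoms + 3L
  if (length(mean) == 1L) mean <- rep(mean, p)
  stopifnot(length(mean) == p)
  if (!is.matrix(cov)) {
    if (length(cov) == 1L) cov <- rep(cov, p)
    stopifnot(length(cov) == p)
    cov <- diag(cov, p)
  }
  stopifnot(nrow(cov) == p, ncol(cov) == p)
  if (length(tau_c) == 1L) tau_c <- rep(tau_c, p)
  stopifnot(length(tau_c) == p, all(tau_c > 0))
  phi <- exp(-dt / tau_c)
  Q <- cov - (phi %o% phi) * cov
  LQ <- .psd_sqrt(Q)                   # errors if not PSD
  L0 <- .psd_sqrt(cov)
  set.seed(expand_seed(seed, "fields"))
  x <- mean + as.numeric(L0 %*% stats::rnorm(p))
  frames <- vector("list", n)
  for (t in seq_len(n)) {
    frames[[t]] <- perturbation_frame(
      time = (t - 1L) * dt,
      site_potentials = x[seq_len(n_atoms)],
      field = x[(n_atoms + 1L):p])
    x <- mean + phi * (x - mean) + as.numeric(LQ %*% stats::rnorm(p))
  }
  frames
}
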