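#' Transition-energy (diabatic gap) trace
#'
#' A uniformly sampled time series of the reactant-to-product diabatic
#' energy difference \eqn{\Delta U(t)} and its time derivative \eqn{v(t)}.
#' When no derivative is supplied it is computed by central finite
#' differences (one-sided at the ends).
#'
#' @param times Strictly increasing, uniformly spaced times, fs.
#' @param gap Gap values, kJ/mol.
#' @param deriv Optional gap time derivative, kJ mol^-1 fs^-1.
#' @param step_tol Relative tolerance on step uniformity.
#' @return Object of class `"gap_trace"`: list with `times`, `gap`,
#'   `deriv`, `dt`.
#' @export
gap_trace <- function(times, gap, deriv = NULL, step_tol = 1e-6) {
  .assert_finite(times, "times"); .assert_finite(gap, "gap")
  if (length(times) < 3L) stop("trace too short", call. = FALSE)
  if (length(times) != length(gap))
    stop("times and gap must align", call. = FALSE)
  dt <- diff(times)
  if (any(dt <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if ((max(dt) - min(dt)) > step_tol * mean(dt))
    stop("times must be uniformly spaced", call. = FALSE)
  dt <- mean(dt)
  if (is.null(deriv)) {
    n <- length(gap)
    deriv <- c(gap[2L] - gap[1L],
               (gap[3:n] - gap[1:(n - 2L)]) / 2,
               gap[n] - gap[n - 1L]) / dt
  } else {
    .assert_finite(deriv, "deriv")
    if (length(deriv) != length(gap))
      stop("deriv must align with gap", call. = FALSE)
  }
  structure(list(times = times, gap = gap, deriv = deriv, dt = dt),
            class = "gap_trace")
}

#' First diabatic crossing of a gap trace
#'
#' Scans a reactant-side trace (positive initial gap) for the first sign
#' change.  The crossing time is linearly interpolated between the
#' bracketing samples and the crossing speed is the absolute slope of the
#' bracketing interval.
#'
#' @param trace A [gap_trace()] with `gap[1] > 0`.
#' @return `NULL` when the gap never changes sign; otherwise a list of class
#'   `"crossing_event"` with `time` (fs), `v_cr` (kJ mol^-1 fs^-1) and
#'   `index` (last reactant-side sample).
#' @examples
#' tr <- gap_trace(0:10, 5 - (0:10))
#' detect_first_crossing(tr)  # crossing at t = 5, speed 1
#' @export
detect_first_crossing <- function(trace) {
  stopifnot(inherits(trace, "gap_trace"))
  if (trace$gap[1L] <= 0)
    stop("trace must start on the reactant side (positive gap); re-select the start frame",
         call. = FALSE)
  s <- which(trace$gap <= 0)
  if (length(s) == 0L) return(NULL)
  i <- s[1L] - 1L
  g0 <- trace$gap[i]; g1 <- trace$gap[i + 1L]
  frac <- if (g0 == g1) 0 else g0 / (g0 - g1)
  structure(
    list(time = trace$times[i] + frac * trace$dt,
         v_cr = abs(g1 - g0) / trace$dt,
         index = i),
    class = "crossing_event")
}

#' Survival curve of a first-crossing ensemble
#'
#' Fraction of trajectories whose first crossing has not yet occurred at
#' each grid time.  Trajectories without a crossing (right-censored at the
#' horizon) count as surviving throughout.
#'
#' @param crossing_times Numeric vector of first-crossing times (fs), `NA`
#'   for trajectories that never crossed.
#' @param horizon Observation horizon, fs.
#' @param grid Optional evaluation times (default 200 points over the
#'   horizon).
#' @return Data frame with columns `time` and `survival`.
#' @export
survival_trace <- function(crossing_times, horizon, grid = NULL) {
  stopifnot(length(crossing_times) >= 1L)
  .assert_scalar(horizon, "horizon", positive = TRUE)
  if (is.null(grid)) grid <- seq(0, horizon, length.out = 201L)
  tt <- crossing_times
  surv <- vapply(grid, function(t) mean(is.na(tt) | tt > t), numeric(1))
  data.frame(time = grid, survival = surv)
}

#' Biexponential fit of a survival curve
#'
#' Least-squares fit of \eqn{S(t) = n_1 e^{-t/\tau_1} + n_2 e^{-t/\tau_2}}
#' with \eqn{n_1 + n_2 = 1} and all parameters positive, giving the mean
#' lifetime \eqn{\tau_0 = n_1\tau_1 + n_2\tau_2} used as the fully
#' adiabatic attempt lifetime.  When the two fitted time scales are within
#' a factor of two of each other the model falls back to a single
#' exponential (the nested case).
#'
#' @param surv Data frame from [survival_trace()] (columns `time`,
#'   `survival`).
#' @param ratio_band Range of \eqn{\tau_1/\tau_2} triggering the
#'   single-exponential fallback (default `c(0.5, 2)`).
#' @return Object of class `"survival_fit"`: list with `n1`, `tau1`, `n2`,
#'   `tau2`, `tau0`, `model` (`"biexponential"` or `"exponential"`),
#'   `sse`, `converged`.
#' @export
fit_survival <- function(surv, ratio_band = c(0.5, 2)) {
  stopifnot(is.data.frame(surv), all(c("time", "survival") %in% names(surv)))
  t <- surv$time; S <- surv$survival
  if (min(S) >= max(S) - 1e-12)
    stop("survival curve never decreases; nothing to fit", call. = FALSE)

  # initial scale: time at which S first drops below 1/e (or extrapolate)
  tau_init <- if (any(S <= exp(-1))) t[which(S <= exp(-1))[1L]] else
    max(t) / max(1e-3, -log(min(S)))
  tau_init <- max(tau_init, .Machine$double.eps)

  sse_bi <- function(p) {
    n1 <- stats::plogis(p[1L]); tau1 <- exp(p[2L]); tau2 <- exp(p[3L])
    sum((n1 * exp(-t / tau1) + (1 - n1) * exp(-t / tau2) - S)^2)
  }
  fit <- stats::optim(c(0, log(tau_init / 2), log(tau_init * 2)), sse_bi,
                      method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  n1 <- stats::plogis(fit$par[1L])
  tau1 <- exp(fit$par[2L]); tau2 <- exp(fit$par[3L])
  ratio <- tau1 / tau2
  model <- "biexponential"; converged <- fit$convergence == 0L

  if (!converged || (ratio >= ratio_band[1L] && ratio <= ratio_band[2L])) {
    sse_1 <- function(p) sum((exp(-t / exp(p)) - S)^2)
    f1 <- stats::optimize(sse_1, log(tau_init) + c(-8, 8))
    if (!converged)
      warning("biexponential fit did not converge; single-exponential fallback")
    n1 <- 1; tau1 <- exp(f1$minimum); tau2 <- tau1
    model <- "exponential"; converged <- TRUE
    sse <- f1$objective
  } else sse <- fit$value

  structure(
    list(n1 = n1, tau1 = tau1, n2 = 1 - n1, tau2 = tau2,
         tau0 = n1 * tau1 + (1 - n1) * tau2,
         model = model, sse = sse, converged = converged),
    class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("%s survival fit: tau0 = %.4g fs\n", x$model, x$tau0))
  if (x$model == "biexponential")
    cat(sprintf("  n1 = %.3f, tau1 = %.4g fs; n2 = %.3f, tau2 = %.4g fs\n",
                x$n1, x$tau1, x$n2, x$tau2))
  invisible(x)
}

#' Landau-Zener electronic adiabatic fraction
#'
#' Probability of remaining on the lower adiabatic surface (i.e. hopping
#' between diabats) at a crossing traversed at speed `v_cr` with mean
#' electronic coupling `coupling`:
#' \eqn{\chi_e = 1 - \exp[-2\pi |\bar H|^2 / (\hbar v_{cr})]}.
#'
#' @param coupling Electronic coupling \eqn{|\bar H_{e,R,P}|}, kJ/mol
#'   (vectorized).
#' @param v_cr Crossing speed, kJ mol^-1 fs^-1, > 0 (vectorized).
#' @return \eqn{\chi_e \in [0, 1]}.
#' @examples
#' lz_adiabatic_fraction(0.1, 0.4)
#' @export
lz_adiabatic_fraction <- function(coupling, v_cr) {
  .assert_finite(coupling, "coupling")
  .assert_finite(v_cr, "v_cr")
  if (any(v_cr <= 0)) stop("v_cr must be positive", call. = FALSE)
  1 - exp(-2 * pi * coupling^2 / (.hbar * v_cr))
}

#' Squared vibrational overlap sum traversed in a reaction event
#'
#' \eqn{\Omega = \sum_{i=0}^{n_P - 1} \xi_i^2}: the cumulative
#' Franck-Condon weight of the product vibronic surfaces irreversibly
#' traversed during one crossing event.  Bounded by
#' \eqn{\xi_0^2 \le \Omega \le 1}.
#'
#' @param xi2 Vector of Franck-Condon factors \eqn{\xi_i^2} for
#'   \eqn{i = 0, 1, \ldots} (see [fc_factor()]).
#' @param n_P Number of traversed product vibronic surfaces, >= 1.
#' @return \eqn{\Omega}.
#' @examples
#' omega_overlap(fc_factor(0.5, 0:10), 2)  # e^-0.5 * 1.5
#' @export
omega_overlap <- function(xi2, n_P) {
  .assert_finite(xi2, "xi2")
  n_P <- as.integer(n_P)
  stopifnot(n_P >= 1L)
  if (any(xi2 < 0) || sum(xi2) > 1 + 1e-9)
    stop("xi2 must be probabilities summing to at most 1", call. = FALSE)
  sum(xi2[seq_len(min(n_P, length(xi2)))])
}

#' Transmission coefficient from explicitly sampled crossing events
#'
#' \eqn{\alpha_G \approx 1 - \langle (1 - \chi_e)^{\Omega} \rangle},
#' averaged over the sampled first crossings, with a seeded bootstrap
#' standard error.
#'
#' @param chi_e Electronic adiabatic fractions per event, in \[0, 1\].
#' @param omega Vibrational overlap sums per event, in (0, 1\] (recycled if
#'   scalar).
#' @param n_boot Bootstrap resamples for the standard error (default 1000;
#'   0 disables).
#' @param seed Bootstrap seed.
#' @return List with `alpha_G`, `se`, `n_events`.
#' @export
transmission_explicit <- function(chi_e, omega, n_boot = 1000L, seed = 1L) {
  if (length(chi_e) == 0L) stop("no crossing events", call. = FALSE)
  if (length(omega) == 1L) omega <- rep(omega, length(chi_e))
  stopifnot(length(omega) == length(chi_e))
  if (any(chi_e < 0 | chi_e > 1)) stop("chi_e outside [0,1]", call. = FALSE)
  if (any(omega <= 0 | omega > 1)) stop("omega outside (0,1]", call. = FALSE)
  x <- 1 - (1 - chi_e)^omega
  se <- NA_real_
  if (n_boot > 0L && length(x) > 1L) {
    set.seed(expand_seed(seed, "bootstrap"))
    bs <- replicate(n_boot, mean(x[sample.int(length(x), replace = TRUE)]))
    se <- stats::sd(bs)
  }
  list(alpha_G = mean(x), se = se, n_events = length(x))
}

#' Transmission coefficient from the mean-event approximation
#'
#' \eqn{\alpha_G \approx 1 - (1 - \alpha_e)^{\langle\Omega\rangle}} with
#' \eqn{\alpha_e = \langle\chi_e\rangle}.  For dark-state channels where
#' only the first crossing is accessible the conventional choice is
#' \eqn{\langle\Omega\rangle = \xi_0^2}; \eqn{\langle\Omega\rangle = 1}
#' recovers \eqn{\alpha_G = \alpha_e}.
#'
#' @param alpha_e Electronic transmission coefficient, in \[0, 1\].
#' @param mean_omega \eqn{\langle\Omega\rangle}, in (0, 1\].
#' @return \eqn{\alpha_G}.
#' @export
transmission_approx <- function(alpha_e, mean_omega) {
  .assert_scalar(alpha_e, "alpha_e"); .assert_scalar(mean_omega, "mean_omega")
  if (alpha_e < 0 || alpha_e > 1) stop("alpha_e outside [0,1]", call. = FALSE)
  if (mean_omega <= 0 || mean_omega > 1)
    stop("mean_omega outside (0,1]", call. = FALSE)
  1 - (1 - alpha_e)^mean_omega
}

#' Reactant-ensemble gap statistics
#'
#' Mean and standard deviation of the gap plus the mean absolute gap speed
#' over an equilibrium reactant-ensemble trace — the three inputs of the
#' Gaussian-approximation attempt rate.
#'
#' @param trace A [gap_trace()], or a numeric gap vector with `deriv`
#'   supplied.
#' @param deriv Gap time derivative when `trace` is a plain vector.
#' @return List of class `"gap_statistics"`: `mean`, `sd`, `mean_speed`,
#'   `mode` (kernel-density mode, diagnostic), `n`.
#' @export
gap_statistics <- function(trace, deriv = NULL) {
  if (inherits(trace, "gap_trace")) {
    g <- trace$gap; v <- trace$deriv
  } else {
    g <- .assert_finite(trace, "gap"); v <- .assert_finite(deriv, "deriv")
  }
  d <- stats::density(g)
  structure(
    list(mean = mean(g), sd = stats::sd(g), mean_speed = mean(abs(v)),
         mode = d$x[which.max(d$y)], n = length(g)),
    class = "gap_statistics")
}

#' Gaussian-approximation attempt rate and fully adiabatic lifetime
#'
#' When explicit crossing sampling is not feasible, the attempt (fully
#' adiabatic) rate is estimated from the equilibrium reactant ensemble by
#' assuming Gaussian transition-energy fluctuations: the unidirectional
#' flux through the crossing is half the mean gap speed times the Gaussian
#' density at zero gap,
#' \deqn{k^0 = \tfrac{1}{2} \langle v \rangle_{R_A}\,
#'   \rho(0;\ \langle\Delta U\rangle_{R_A}, \sigma_{R_A}),}
#' which coincides with Rice's level-downcrossing rate for a stationary
#' differentiable Gaussian process.  The fully adiabatic lifetime is
#' \eqn{\tau_0 = 1/k^0}.
#'
#' @param stats A `"gap_statistics"` object, or the mean gap (kJ/mol) when
#'   `sd` and `mean_speed` are given separately.
#' @param sd Gap standard deviation, kJ/mol.
#' @param mean_speed Mean absolute gap speed, kJ mol^-1 fs^-1.
#' @param use_mode Use the distribution mode instead of the mean as the
#'   Gaussian centre (they coincide under the Gaussian assumption).
#' @return Object of class `"rate_estimate"`: list with `tau0` (fs), `k0`
#'   (fs^-1), `method = "gaussian"`.
#' @examples
#' gaussian_rate(3.62, 7.1, 0.4)$tau0  # ~ 1e2 fs
#' @export
gaussian_rate <- function(stats, sd = NULL, mean_speed = NULL,
                          use_mode = FALSE) {
  if (inherits(stats, "gap_statistics")) {
    m <- if (use_mode) stats$mode else stats$mean
    s <- stats$sd; v <- stats$mean_speed
  } else {
    m <- .assert_scalar(stats, "mean gap")
    s <- sd; v <- mean_speed
  }
  .assert_scalar(s, "sd", positive = TRUE)
  .assert_scalar(v, "mean_speed", positive = TRUE)
  if (m <= 0)
    stop("mean gap must be positive (reactant side)", call. = FALSE)
  k0 <- v * stats::dnorm(0, mean = m, sd = s) / 2
  structure(list(tau0 = 1 / k0, k0 = k0, alpha_G = NA_real_, tau = NA_real_,
                 method = "gaussian"),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("rate estimate (%s): tau0 = %.4g fs", x$method, x$tau0))
  if (is.finite(x$alpha_G)) cat(sprintf(", alpha_G = %.3g", x$alpha_G))
  if (is.finite(x$tau)) cat(sprintf(", tau = %.4g fs", x$tau))
  cat("\n")
  invisible(x)
}

#' Reaction lifetime from attempt lifetime and transmission coefficient
#'
#' Each approach to the transition region offers two hop opportunities
#' (inbound and outbound traversal), each succeeding with probability
#' \eqn{\alpha_G}, so the per-approach reaction probability is
#' \eqn{1 - (1 - \alpha_G)^2} and
#' \deqn{\tau = \frac{\tau_0}{1 - (1 - \alpha_G)^2}.}
#' The fully adiabatic limit \eqn{\alpha_G = 1} returns \eqn{\tau_0}.
#'
#' @param tau0 Fully adiabatic (attempt) mean lifetime (any time unit).
#' @param alpha_G Transmission coefficient in (0, 1\].
#' @return Reaction mean lifetime in the unit of `tau0`; `NA` when
#'   `alpha_G` is 0 (no reactive flux).
#' @examples
#' reaction_lifetime(176, 0.295)  # ~ 350 fs
#' @export
reaction_lifetime <- function(tau0, alpha_G) {
  .assert_scalar(tau0, "tau0", positive = TRUE)
  .assert_scalar(alpha_G, "alpha_G")
  if (alpha_G < 0 || alpha_G > 1) stop("alpha_G outside [0,1]", call. = FALSE)
  if (alpha_G == 0) return(NA_real_)
  tau0 / (1 - (1 - alpha_G)^2)
}

#' Coupling geometry for the crossing-mean-coupling approximation
#'
#' Fixes the dipolar-approximation geometry of a diabatic crossing: the
#' unit vector \eqn{\eta_\parallel} along the diagonal-dipole difference
#' \eqn{\Delta\mu^0 = \mu_R^0 - \mu_P^0}, the in-plane orthogonal unit
#' vector \eqn{\eta_\perp} (in the plane of \eqn{\Delta\mu^0} and the mean
#' transition dipole \eqn{\bar\mu_{R,P}^0}), and the parallel field
#' component \eqn{E_\parallel} enforced by the crossing condition: within
#' the dipolar approximation the gap
#' \eqn{\Delta U = \Delta\epsilon^0 + E_\parallel |\Delta\mu^0|} is linear
#' in \eqn{E_\parallel} and vanishes at the crossing, so
#' \eqn{E_\parallel = -\Delta\epsilon^0 / |\Delta\mu^0|}.
#'
#' @param mu_R,mu_P Diagonal dipole 3-vectors of the reactant and product
#'   diabatic states, e nm.
#' @param mu_bar Mean reactant-product transition dipole 3-vector, e nm.
#' @param gap0 Unperturbed transition energy \eqn{\Delta\epsilon^0}
#'   (product minus reactant, including any vibronic correction), kJ/mol.
#' @param E_perp_mean \eqn{\langle E_\perp \rangle} over the equilibrium
#'   reactant ensemble, kJ mol^-1 e^-1 nm^-1.
#' @param E_perp_sq_mean \eqn{\langle E_\perp^2 \rangle} over the same
#'   ensemble.
#' @return Object of class `"coupling_geometry"`.
#' @export
coupling_geometry <- function(mu_R, mu_P, mu_bar, gap0,
                              E_perp_mean, E_perp_sq_mean) {
  .assert_finite(mu_R, "mu_R"); .assert_finite(mu_P, "mu_P")
  .assert_finite(mu_bar, "mu_bar")
  stopifnot(length(mu_R) == 3L, length(mu_P) == 3L, length(mu_bar) == 3L)
  .assert_scalar(gap0, "gap0")
  .assert_scalar(E_perp_mean, "E_perp_mean")
  .assert_scalar(E_perp_sq_mean, "E_perp_sq_mean")
  if (E_perp_sq_mean < E_perp_mean^2 - 1e-9)
    stop("E_perp_sq_mean below squared mean", call. = FALSE)
  dmu <- mu_R - mu_P
  nd <- sqrt(sum(dmu^2))
  if (nd < 1e-9)
    stop("diagonal dipole difference vanishes; crossing condition undefined",
         call. = FALSE)
  eta_par <- dmu / nd
  mu_par <- sum(mu_bar * eta_par)
  res <- mu_bar - mu_par * eta_par
  nr <- sqrt(sum(res^2))
  if (nr > 1e-12) {
    eta_perp <- res / nr
  } else {
    # mu_bar parallel to eta_par: any orthonormal direction works, the
    # perpendicular dipole projection is zero either way
    b <- if (abs(eta_par[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    eta_perp <- b - sum(b * eta_par) * eta_par
    eta_perp <- eta_perp / sqrt(sum(eta_perp^2))
  }
  structure(
    list(eta_par = eta_par, eta_perp = eta_perp,
         E_par = -gap0 / nd,
         mu_bar = mu_bar,
         mu_par = mu_par, mu_perp = sum(mu_bar * eta_perp),
         E_perp_mean = E_perp_mean, E_perp_sq_mean = E_perp_sq_mean,
         dmu_norm = nd, gap0 = gap0),
    class = "coupling_geometry")
}

#' Electronic transmission coefficient from equilibrium field statistics
#'
#' Crossing-mean-coupling estimate of \eqn{\alpha_e}: at a crossing the
#' coupling is \eqn{\bar H = -(E_\parallel\, \bar\mu\cdot\eta_\parallel +
#' E_\perp\, \bar\mu\cdot\eta_\perp)} with \eqn{E_\parallel} pinned by the
#' crossing condition, so its mean square over the equilibrium reactant
#' ensemble is
#' \deqn{\langle|\bar H|^2\rangle = (E_\parallel \bar\mu_\parallel)^2 +
#'   2 E_\parallel \bar\mu_\parallel \bar\mu_\perp \langle E_\perp\rangle +
#'   \bar\mu_\perp^2 \langle E_\perp^2\rangle,}
#' and \eqn{\alpha_e = 1 - \exp[-2\pi \langle|\bar H|^2\rangle /
#' (\hbar \langle v_{cr}\rangle)]} with the equilibrium mean speed standing
#' in for the crossing speed.
#'
#' @param geom A [coupling_geometry()].
#' @param mean_speed \eqn{\langle v \rangle_{R_A}}, kJ mol^-1 fs^-1.
#' @return List with `alpha_e`, `H2_mean` (kJ^2/mol^2), `method`.
#' @export
mean_coupling_alpha_e <- function(geom, mean_speed) {
  stopifnot(inherits(geom, "coupling_geometry"))
  .assert_scalar(mean_speed, "mean_speed", positive = TRUE)
  H2 <- (geom$E_par * geom$mu_par)^2 +
    2 * geom$E_par * geom$mu_par * geom$mu_perp * geom$E_perp_mean +
    geom$mu_perp^2 * geom$E_perp_sq_mean
  H2 <- max(H2, 0)
  list(alpha_e = 1 - exp(-2 * pi * H2 / (.hbar * mean_speed)),
       H2_mean = H2, method = "mean_coupling")
}

#' Full kinetic chain for one diabatic transition channel
#'
#' Convenience wrapper combining an attempt lifetime with a transmission
#' coefficient into a reaction lifetime, tagged by method.
#'
#' @param tau0 Attempt lifetime, fs.
#' @param alpha_G Transmission coefficient.
#' @param method Tag: `"explicit"`, `"gaussian"` or `"mean_coupling"`.
#' @param se Optional named numeric of standard errors (`tau0`,
#'   `alpha_G`); the lifetime SE is propagated first order.
#' @return A `"rate_estimate"` with `tau0`, `alpha_G`, `tau` and `se`.
#' @export
rate_estimate <- function(tau0, alpha_G, method = "explicit", se = NULL) {
  .assert_scalar(tau0, "tau0", positive = TRUE)
  tau <- reaction_lifetime(tau0, alpha_G)
  out <- list(tau0 = tau0, k0 = 1 / tau0, alpha_G = alpha_G, tau = tau,
              method = method)
  if (!is.null(se)) {
    pick <- function(nm) if (nm %in% names(se)) se[[nm]] else 0
    d <- .delta_se(function(x) {
      v <- reaction_lifetime(x[["tau0"]], x[["alpha_G"]])
      if (is.na(v)) 0 else v
    }, c(tau0 = tau0, alpha_G = alpha_G),
    c(pick("tau0"), pick("alpha_G")))
    out$se <- c(se, tau = d$se)
  }
  structure(out, class = "rate_estimate")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
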