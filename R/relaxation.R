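#' Reaction free energy from the two equilibrium ensembles
#'
#' Two-sided linear-response estimate of the bright-state interconversion
#' free energy from the mean transition energy evaluated in each
#' equilibrium ensemble:
#' \deqn{\Delta A = \tfrac{1}{2}\left(\langle\Delta U\rangle_{Lb} +
#'   \langle\Delta U\rangle_{La}\right),}
#' with both averages taken for the same (Lb to La) gap sign convention:
#' positive means La above Lb.  A Gaussian-fluctuation alternative
#' subtracts the variance asymmetry,
#' \eqn{\Delta A = \bar m - (\sigma_{Lb}^2 - \sigma_{La}^2)/(4 k_B T)}.
#'
#' @param mean_gap_R Mean Lb-to-La transition energy in the Lb (reactant)
#'   ensemble, kJ/mol.
#' @param mean_gap_P Mean Lb-to-La transition energy in the La (product)
#'   ensemble, kJ/mol (typically negative).
#' @param estimator `"linear"` (default, mean of means) or `"gaussian"`.
#' @param sd_R,sd_P Gap standard deviations, needed for
#'   `estimator = "gaussian"`.
#' @param temperature K (Gaussian estimator only).
#' @return \eqn{\Delta A} in kJ/mol (Lb to La; negative favours La).
#' @examples
#' free_energy_from_ensembles(3.62, -13.15)
#' @export
free_energy_from_ensembles <- function(mean_gap_R, mean_gap_P,
                                       estimator = c("linear", "gaussian"),
                                       sd_R = NULL, sd_P = NULL,
                                       temperature = 300) {
  estimator <- match.arg(estimator)
  .assert_scalar(mean_gap_R, "mean_gap_R")
  .assert_scalar(mean_gap_P, "mean_gap_P")
  m <- (mean_gap_R + mean_gap_P) / 2
  if (estimator == "linear") return(m)
  .assert_scalar(sd_R, "sd_R", positive = TRUE)
  .assert_scalar(sd_P, "sd_P", positive = TRUE)
  m - (sd_R^2 - sd_P^2) / (4 * .kB * temperature)
}

#' Equilibrium constant and state fractions
#'
#' \eqn{K_{eq} = \exp[-\Delta A / (k_B T)]},
#' \eqn{f_a = K_{eq} / (1 + K_{eq})}, \eqn{f_b = 1 - f_a}.
#'
#' @param dA Reaction free energy \eqn{\Delta A} (Lb to La), kJ/mol.
#' @param temperature K.
#' @return List with `K_eq`, `f_b`, `f_a`.
#' @examples
#' equilibrium_fractions(-5.01, 300)
#' @export
equilibrium_fractions <- function(dA, temperature = 300) {
  .assert_scalar(dA, "dA")
  .assert_scalar(temperature, "temperature", positive = TRUE)
  K <- exp(-dA / (.kB * temperature))
  f_a <- K / (1 + K)
  list(K_eq = K, f_b = 1 - f_a, f_a = f_a)
}

#' Population-weighted combined lifetime of a fast-equilibrium mixture
#'
#' Harmonic (rate-additive) combination
#' \eqn{\tau = (f_b/\tau_b + f_a/\tau_a)^{-1}}, valid when the two
#' populations interconvert much faster than either decay channel.
#'
#' @param f_b,f_a Equilibrium fractions (must sum to 1 within 1e-9).
#' @param tau_b,tau_a Component lifetimes (same unit, positive).
#' @return Combined lifetime, same unit.
#' @examples
#' combined_lifetime(0.118, 56, 0.882, 20)  # ~ 22 ns
#' @export
combined_lifetime <- function(f_b, tau_b, f_a, tau_a) {
  .assert_scalar(f_b, "f_b"); .assert_scalar(f_a, "f_a")
  if (abs(f_b + f_a - 1) > 1e-9)
    stop("fractions must sum to 1", call. = FALSE)
  .assert_scalar(tau_b, "tau_b", positive = TRUE)
  .assert_scalar(tau_a, "tau_a", positive = TRUE)
  1 / (f_b / tau_b + f_a / tau_a)
}

#' Fluorescence lifetime and quantum yield
#'
#' \eqn{1/\tau_F = 1/\tau_r + 1/\tau_{nr}} and \eqn{\Phi = \tau_F/\tau_r}.
#' An optional intersystem-crossing channel (externally supplied rate) is
#' added to the nonradiative side first:
#' \eqn{1/\tau_{nr}' = 1/\tau_{nr} + 1/\tau_{ISC}}.
#'
#' @param tau_r Radiative lifetime, ns.
#' @param tau_nr Nonradiative lifetime, ns (may be `Inf`).
#' @param tau_ISC Optional ISC lifetime, ns.
#' @return List with `tau_F`, `Phi`, `tau_nr_eff`.
#' @examples
#' fluorescence_observables(22, 4.0)
#' @export
fluorescence_observables <- function(tau_r, tau_nr, tau_ISC = NULL) {
  .assert_scalar(tau_r, "tau_r", positive = TRUE)
  if (!(is.numeric(tau_nr) && length(tau_nr) == 1L && tau_nr > 0))
    stop("tau_nr must be a positive scalar (Inf allowed)", call. = FALSE)
  k_nr <- 1 / tau_nr
  if (!is.null(tau_ISC)) {
    .assert_scalar(tau_ISC, "tau_ISC", positive = TRUE)
    k_nr <- k_nr + 1 / tau_ISC
  }
  tau_nr_eff <- if (k_nr > 0) 1 / k_nr else Inf
  tau_F <- 1 / (1 / tau_r + k_nr)
  list(tau_F = tau_F, Phi = tau_F / tau_r, tau_nr_eff = tau_nr_eff)
}

#' Bright-state relaxation scheme
#'
#' The full kinetic network of the first excited-state population: a fast
#' Lb = La pre-equilibrium (fractions from \eqn{\Delta A}) whose mixture
#' decays radiatively (component lifetimes `tau_r_b`, `tau_r_a`) and
#' nonradiatively into the irreversible dark channel (component lifetimes
#' `tau_b`, `tau_a`), with an optional parallel intersystem-crossing
#' channel.  All component inputs may carry standard errors; derived
#' quantities get first-order (delta-method) uncertainties.
#'
#' @param dA Lb-to-La reaction free energy, kJ/mol.
#' @param tau_r_b,tau_r_a Radiative component lifetimes, ns.
#' @param tau_b,tau_a Nonradiative (to dark state) component lifetimes, ns.
#' @param tau_ISC Optional ISC lifetime, ns.
#' @param temperature K.
#' @param se Optional named list/vector of standard errors for any of
#'   `dA`, `tau_r_b`, `tau_r_a`, `tau_b`, `tau_a`.
#' @return Object of class `"relaxation_scheme"` with the inputs plus
#'   `K_eq`, `f_b`, `f_a`, `tau_r`, `tau_nr`, `tau_F`, `Phi` and, when
#'   `se` is given, a `se` element with propagated standard errors.
#' @examples
#' sc <- relaxation_scheme(dA = -5.01, tau_r_b = 56, tau_r_a = 20,
#'                         tau_b = 11.0, tau_a = 3.7)
#' sc$tau_F
#' @export
relaxation_scheme <- function(dA, tau_r_b, tau_r_a, tau_b, tau_a,
                              tau_ISC = NULL, temperature = 300, se = NULL) {
  .assert_scalar(dA, "dA")
  for (v in list(tau_r_b, tau_r_a, tau_b, tau_a))
    .assert_scalar(v, "component lifetime", positive = TRUE)

  chain <- function(x) {
    fr <- equilibrium_fractions(x[["dA"]], temperature)
    tau_r <- combined_lifetime(fr$f_b, x[["tau_r_b"]], fr$f_a, x[["tau_r_a"]])
    tau_nr <- combined_lifetime(fr$f_b, x[["tau_b"]], fr$f_a, x[["tau_a"]])
    fo <- fluorescence_observables(tau_r, tau_nr, tau_ISC)
    c(K_eq = fr$K_eq, f_b = fr$f_b, f_a = fr$f_a, tau_r = tau_r,
      tau_nr = tau_nr, tau_nr_eff = fo$tau_nr_eff, tau_F = fo$tau_F,
      Phi = fo$Phi)
  }
  x0 <- c(dA = dA, tau_r_b = tau_r_b, tau_r_a = tau_r_a,
          tau_b = tau_b, tau_a = tau_a)
  derived <- chain(x0)

  se_out <- NULL
  if (!is.null(se)) {
    se_in <- vapply(names(x0), function(nm)
      if (nm %in% names(se)) as.numeric(se[[nm]]) else 0, numeric(1))
    se_out <- vapply(names(derived), function(nm) {
      .delta_se(function(x) chain(x)[[nm]], x0, se_in)$se
    }, numeric(1))
  }

  structure(
    c(as.list(x0),
      list(tau_ISC = tau_ISC, temperature = temperature),
      as.list(derived),
      list(se = se_out)),
    class = "relaxation_scheme")
}

#' @export
print.relaxation_scheme <- function(x, ...) {
  cat("Bright-state relaxation scheme (fast Lb <-> La pre-equilibrium)\n")
  cat(sprintf("  dA = %.3f kJ/mol at %g K -> K_eq = %.3f, f_b = %.3f, f_a = %.3f\n",
              x$dA, x$temperature, x$K_eq, x$f_b, x$f_a))
  cat(sprintf("  tau_r = %.3g ns, tau_nr = %.3g ns", x$tau_r, x$tau_nr))
  if (!is.null(x$tau_ISC))
    cat(sprintf(" (+ ISC %.3g ns -> eff. %.3g ns)", x$tau_ISC, x$tau_nr_eff))
  cat("\n")
  cat(sprintf("  tau_F = %.3g ns, quantum yield Phi = %.3g\n", x$tau_F, x$Phi))
  invisible(x)
}

#' @export
summary.relaxation_scheme <- function(object, ...) {
  network_summary(object)
}

#' Full report of a relaxation scheme
#'
#' Emits the complete derivation chain (free energy to fractions to
#' combined lifetimes to fluorescence observables) as a data frame, with
#' first-order propagated standard errors when the scheme carries input
#' uncertainties.
#'
#' @param scheme A [relaxation_scheme()].
#' @return Data frame of class `"relaxation_report"` with columns
#'   `quantity`, `value`, `se` (NA when no uncertainties were supplied)
#'   and `unit`.
#' @export
network_summary <- function(scheme) {
  stopifnot(inherits(scheme, "relaxation_scheme"))
  qty <- c("dA", "K_eq", "f_b", "f_a", "tau_r", "tau_nr", "tau_nr_eff",
           "tau_F", "Phi")
  unit <- c("kJ/mol", "", "", "", "ns", "ns", "ns", "ns", "")
  val <- vapply(qty, function(q) as.numeric(scheme[[q]]), numeric(1))
  se <- rep(NA_real_, length(qty))
  if (!is.null(scheme$se)) {
    for (i in seq_along(qty))
      if (qty[i] %in% names(scheme$se)) se[i] <- scheme$se[[qty[i]]]
  }
  out <- data.frame(quantity = qty, value = val, se = se, unit = unit,
                    row.names = NULL)
  class(out) <- c("relaxation_report", "data.frame")
  out
}

#' Three-state master-equation lifetimes (sensitivity tool)
#'
#' Relaxes the irreversibility assumption: solves the linear kinetics of
#' the Lb/La/dark populations including the (slow) dark-to-bright back
#' transitions and the radiative sinks, and returns the amplitude-weighted
#' mean emission lifetime for comparison with the fast-pre-equilibrium
#' result.  Populations start in Lb (the post-excitation condition).
#'
#' @param scheme A [relaxation_scheme()].
#' @param tau_ba Lb <-> La interconversion lifetimes, ns: `c(b_to_a,
#'   a_to_b)`.
#' @param tau_back Dark-to-bright back-transition lifetimes, ns:
#'   `c(dark_to_b, dark_to_a)`; `Inf` (default) keeps the dark channel
#'   irreversible.
#' @return List with `tau_F` (amplitude-weighted mean emission lifetime,
#'   ns), `eigen_lifetimes` (ns) and `amplitudes`.
#' @export
master_equation_lifetimes <- function(scheme, tau_ba,
                                      tau_back = c(Inf, Inf)) {
  stopifnot(inherits(scheme, "relaxation_scheme"), length(tau_ba) == 2L)
  kba <- 1 / tau_ba[1L]; kab <- 1 / tau_ba[2L]
  kdb <- 1 / tau_back[1L]; kda <- 1 / tau_back[2L]
  krb <- 1 / scheme$tau_r_b; kra <- 1 / scheme$tau_r_a
  kb <- 1 / scheme$tau_b; ka <- 1 / scheme$tau_a
  kisc <- if (is.null(scheme$tau_ISC)) 0 else 1 / scheme$tau_ISC
  # states: Lb, La, dark; losses: radiative + ISC leave the system
  M <- matrix(c(-(kba + krb + kb + kisc), kab,                    kdb,
                kba,                      -(kab + kra + ka + kisc), kda,
                kb,                       ka,                     -(kdb + kda)),
              3L, 3L, byrow = TRUE)
  es <- eigen(M)
  lam <- Re(es$values); V <- Re(es$vectors)
  p0 <- c(1, 0, 0)
  a <- solve(V, p0)
  # emission intensity I(t) = krb pb(t) + kra pa(t)
  w <- as.numeric(c(krb, kra, 0) %*% V) * a
  ok <- lam < -1e-12
  tauF <- sum(w[ok] / lam[ok]^2) / sum(-w[ok] / lam[ok])
  list(tau_F = tauF, eigen_lifetimes = -1 / lam[ok], amplitudes = w[ok])
}
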