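#' Vibronic mode set for a displaced-oscillator model
#'
#' Harmonic modes shared by the two electronic states of a transition, with
#' the vibrational wave functions of corresponding modes differing only in
#' their minimum positions (no Duschinsky mixing, identical frequencies).
#' Each mode is classified as quantum when its quantum exceeds the thermal
#' energy (\eqn{\hbar\omega > k_B T}) and classical-like otherwise; only
#' quantum modes enter Franck-Condon progressions, while classical modes
#' contribute ensemble broadening.
#'
#' @param frequencies Angular frequencies \eqn{\omega}, fs^-1.
#' @param displacements Reduced-mass-weighted displacements between the two
#'   minima, amu^1/2 nm.
#' @param temperature Temperature for the quantum/classical split, K.
#' @return Object of class `"vibronic_mode_set"` with elements `omega`,
#'   `displacement`, `S` (Huang-Rhys factors), `quantum` (logical) and
#'   `temperature`.
#' @export
vibronic_mode_set <- function(frequencies, displacements, temperature = 300) {
  .assert_finite(frequencies, "frequencies")
  .assert_finite(displacements, "displacements")
  if (any(frequencies <= 0)) stop("frequencies must be positive", call. = FALSE)
  if (length(frequencies) != length(displacements))
    stop("frequencies and displacements must align", call. = FALSE)
  .assert_scalar(temperature, "temperature", positive = TRUE)
  S <- frequencies * displacements^2 * .amu_nm2_fs2 / (2 * .hbar)
  structure(
    list(omega = as.numeric(frequencies),
         displacement = as.numeric(displacements),
         S = S,
         quantum = (.hbar * frequencies) > (.kB * temperature),
         temperature = temperature),
    class = "vibronic_mode_set")
}

#' Franck-Condon factor of a displaced harmonic mode
#'
#' Squared overlap \eqn{\xi_n^2 = |\langle \phi_{R,0} | \phi_{P,n}
#' \rangle|^2} between the reactant vibrational ground state and the n-th
#' product level of a mode with identical frequency and displaced minimum:
#' a Poisson distribution in the Huang-Rhys factor,
#' \eqn{\xi_n^2 = e^{-S} S^n / n!}.  The Huang-Rhys factor of a mode with
#' angular frequency \eqn{\omega} and mass-weighted displacement d is
#' \eqn{S = \omega d^2 / (2\hbar)}.
#'
#' @param S Huang-Rhys factor (dimensionless, >= 0).
#' @param n Vibrational quantum number(s), integer >= 0 (vectorized).
#' @return \eqn{\xi_n^2}, same length as `n`.
#' @examples
#' fc_factor(1, 0:4)
#' sum(fc_factor(0.5, 0:50))  # completeness
#' @export
fc_factor <- function(S, n) {
  .assert_scalar(S, "S")
  if (S < 0) stop("Huang-Rhys factor must be nonnegative", call. = FALSE)
  if (any(n < 0) || any(n != floor(n)))
    stop("n must be nonnegative integers", call. = FALSE)
  stats::dpois(n, S)
}

#' Enumerate multi-mode Franck-Condon transitions
#'
#' Products of per-mode Poisson factors over the quantum modes of a
#' [vibronic_mode_set()], with each transition's energy shift
#' \eqn{\sum_m n_m \hbar\omega_m}.  Per mode, levels are kept until the
#' cumulative factor reaches `1 - cum_tol`; modes are then combined by
#' weight-ordered outer products pruned to the `max_terms` heaviest terms,
#' so spectra with well over a million raw vibronic transitions stay
#' tractable.
#'
#' @param modes A [vibronic_mode_set()].
#' @param cum_tol Per-mode truncation tail mass (default 1e-6).
#' @param max_terms Cap on retained multi-mode terms (default 1e6).
#' @param quantum_only Use only quantum-classified modes (default TRUE).
#' @return Data frame with `shift` (kJ/mol, >= 0: energy of the final
#'   vibrational excitation) and `weight`, sorted by decreasing weight.
#' @export
fc_transitions <- function(modes, cum_tol = 1e-6, max_terms = 1e6,
                           quantum_only = TRUE) {
  stopifnot(inherits(modes, "vibronic_mode_set"))
  keep <- if (quantum_only) which(modes$quantum) else seq_along(modes$S)
  out <- data.frame(shift = 0, weight = 1)
  for (m in keep) {
    S <- modes$S[m]
    nmax <- 0L
    while (stats::ppois(nmax, S) < 1 - cum_tol) nmax <- nmax + 1L
    lev <- data.frame(shift = (0:nmax) * .hbar * modes$omega[m],
                      weight = fc_factor(S, 0:nmax))
    out <- data.frame(
      shift = rep(out$shift, each = nrow(lev)) + rep(lev$shift, nrow(out)),
      weight = rep(out$weight, each = nrow(lev)) * rep(lev$weight, nrow(out)))
    if (nrow(out) > max_terms) {
      out <- out[order(out$weight, decreasing = TRUE)[1:max_terms], ]
    }
  }
  out[order(out$weight, decreasing = TRUE), , drop = FALSE]
}

#' Ensemble broadening from classical-like modes
#'
#' Gaussian width of the vertical-transition energy fluctuation carried by
#' the classical-like (thermally populated) modes: with classical
#' reorganization energy \eqn{\lambda_{cl} = \sum_m S_m \hbar\omega_m} over
#' the classical modes, the high-temperature variance is
#' \eqn{\sigma^2 = 2 \lambda_{cl} k_B T}.
#'
#' @param modes A [vibronic_mode_set()].
#' @param temperature K; defaults to the mode set's own.
#' @return Standard deviation, kJ/mol (0 if no classical modes).
#' @export
classical_broadening <- function(modes, temperature = modes$temperature) {
  stopifnot(inherits(modes, "vibronic_mode_set"))
  lam <- sum(modes$S[!modes$quantum] * .hbar * modes$omega[!modes$quantum])
  sqrt(2 * lam * .kB * temperature)
}

#' Vertical electronic spectrum from an ensemble of frames
#'
#' Histogram reconstruction of an absorption or emission band: vertical
#' transition energies are binned; each bin, weighted by its frame fraction
#' \eqn{n(\nu_{ref})/N_f} and its mean squared transition dipole, contributes
#' a Gaussian of width `sigma` centred on the bin reference energy.  The
#' frequency prefactor is \eqn{\nu} for absorption and \eqn{\nu^3} for
#' spontaneous emission, evaluated on the output grid.
#'
#' @param gaps Vertical transition energies per frame, kJ/mol.
#' @param dipoles Transition dipoles per frame: an n x 3 matrix (e nm) or a
#'   numeric vector of squared norms (e^2 nm^2).
#' @param bin_width Histogram bin width, kJ/mol (default 1).
#' @param sigma Gaussian broadening width, kJ/mol; default `bin_width`
#'   (resolution-limited) — pass [classical_broadening()] of the relevant
#'   mode set for physical broadening.
#' @param kind `"emission"` or `"absorption"`.
#' @param grid Optional output energy grid, kJ/mol (strictly increasing).
#' @param normalization `"absolute"` (default), `"area"` or `"peak"`.
#' @return Object of class `"pmm_spectrum"`: list with `grid`, `intensity`,
#'   `kind`, `normalization`, `bins` (data frame: `nu_ref`, `n`, `mu2`),
#'   `sigma`, `bin_width`, `n_frames`.
#' @export
vertical_spectrum <- function(gaps, dipoles, bin_width = 1, sigma = NULL,
                              kind = c("emission", "absorption"),
                              grid = NULL, normalization = "absolute") {
  kind <- match.arg(kind)
  if (length(gaps) == 0L) {
    return(structure(list(grid = numeric(0), intensity = numeric(0),
                          kind = kind, normalization = normalization,
                          bins = NULL, sigma = sigma, bin_width = bin_width,
                          n_frames = 0L),
                     class = "pmm_spectrum"))
  }
  .assert_finite(gaps, "gaps")
  .assert_scalar(bin_width, "bin_width", positive = TRUE)
  if (is.matrix(dipoles)) {
    stopifnot(nrow(dipoles) == length(gaps), ncol(dipoles) == 3L)
    mu2 <- rowSums(dipoles^2)
  } else {
    stopifnot(length(dipoles) == length(gaps))
    mu2 <- as.numeric(dipoles)
  }
  if (is.null(sigma)) sigma <- bin_width
  .assert_scalar(sigma, "sigma", positive = TRUE)

  lo <- floor(min(gaps) / bin_width) * bin_width
  hi <- ceiling(max(gaps) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  idx <- findInterval(gaps, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  nb <- tabulate(idx, nbins = length(centers))
  used <- which(nb > 0L)
  mu2_bin <- vapply(used, function(b) mean(mu2[idx == b]), numeric(1))
  bins <- data.frame(nu_ref = centers[used], n = nb[used], mu2 = mu2_bin)

  if (is.null(grid))
    grid <- seq(lo - 4 * sigma, hi + 4 * sigma, length.out = 1024L)
  intensity <- .bins_to_intensity(bins, length(gaps), grid, sigma, kind)
  sp <- structure(
    list(grid = grid, intensity = intensity, kind = kind,
         normalization = "absolute", bins = bins, sigma = sigma,
         bin_width = bin_width, n_frames = length(gaps)),
    class = "pmm_spectrum")
  normalize_spectrum(sp, normalization)
}

# Shared kernel: weighted Gaussians times the kind-dependent frequency
# prefactor, including the physical constants of the spontaneous-emission
# (Einstein A) and absorption line strengths in package units.
.bins_to_intensity <- function(bins, n_frames, grid, sigma, kind) {
  p <- if (kind == "emission") 3 else 1
  I <- numeric(length(grid))
  for (b in seq_len(nrow(bins))) {
    w <- bins$n[b] / n_frames * bins$mu2[b]
    I <- I + w * stats::dnorm(grid, bins$nu_ref[b], sigma)
  }
  I * pmax(grid, 0)^p * .spectrum_prefactor(kind)
}

# Einstein-A-style prefactor converting (E/kJmol)^3 |mu|^2(e^2 nm^2) into a
# rate density (ns^-1 per kJ/mol) for emission; absorption uses the line
# strength prefactor of the integrated cross-section, reported in nm^2 per
# kJ/mol so that relative band shapes and areas are physically scaled.
.spectrum_prefactor <- function(kind) {
  if (kind == "emission") {
    # A(E) = 16 pi^3 nu^3 |mu|^2 / (3 eps0 h c^3), nu = E * 1000 / (NA h)
    nu_per_E <- 1000 / (.NA_SI * .h_SI)              # Hz per kJ/mol
    mu2_SI <- (.e_SI * 1e-9)^2                       # (C m)^2 per e^2 nm^2
    a <- 16 * pi^3 * nu_per_E^3 * mu2_SI /
      (3 * .eps0_SI * .h_SI * .c_SI^3)               # s^-1 per (kJ/mol)^3 e^2nm^2
    a * 1e-9                                          # ns^-1
  } else {
    # integrated cross-section prefactor 4 pi^2 nu |mu|^2 / (3 hbar c 4 pi eps0)
    nu_per_E <- 1000 / (.NA_SI * .h_SI)
    mu2_SI <- (.e_SI * 1e-9)^2
    a <- 4 * pi^2 * nu_per_E * mu2_SI /
      (3 * (.h_SI / (2 * pi)) * .c_SI * 4 * pi * .eps0_SI)  # m^2 per kJ/mol...
    a * 1e18                                          # nm^2
  }
}

#' Renormalize a spectrum
#'
#' @param sp A `"pmm_spectrum"`.
#' @param normalization `"absolute"`, `"area"` (unit trapezoidal area) or
#'   `"peak"` (unit maximum).
#' @return The rescaled spectrum.
#' @export
normalize_spectrum <- function(sp, normalization = c("absolute", "area", "peak")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(sp, "pmm_spectrum"))
  if (normalization == "area" && length(sp$grid) > 1L) {
    a <- sum(diff(sp$grid) * (utils::head(sp$intensity, -1) +
                                utils::tail(sp$intensity, -1)) / 2)
    if (a > 0) sp$intensity <- sp$intensity / a
  } else if (normalization == "peak" && length(sp$intensity) > 0L) {
    m <- max(sp$intensity)
    if (m > 0) sp$intensity <- sp$intensity / m
  }
  sp$normalization <- normalization
  sp
}

#' @export
print.pmm_spectrum <- function(x, ...) {
  cat(sprintf("%s spectrum: %d grid points", x$kind, length(x$grid)))
  if (length(x$grid)) {
    pk <- x$grid[which.max(x$intensity)]
    cat(sprintf(", peak at %.1f kJ/mol (%s-normalized)", pk, x$normalization))
  }
  cat("\n")
  invisible(x)
}

#' Shift a reference frequency to a vibronic line position
#'
#' Places the m-th vibronic replica of a vertical bin: the bin reference
#' energy plus the offset of the unperturbed m-th vibronic transition from
#' the unperturbed vertical electronic transition,
#' \eqn{\nu_{ref}^m = \nu_{ref} + (\nu_m^0 - \nu_{el}^0)}.  All arguments
#' share one energy/frequency unit.
#'
#' @param nu_ref Bin reference value(s).
#' @param nu_m0 Unperturbed m-th vibronic transition value (possibly
#'   corrected to the experimental gas-phase 0-0 position).
#' @param nu_el0 Unperturbed vertical electronic transition value.
#' @return Shifted reference value(s).
#' @export
vibronic_shift <- function(nu_ref, nu_m0, nu_el0) {
  .assert_finite(nu_ref, "nu_ref")
  .assert_scalar(nu_m0, "nu_m0")
  .assert_scalar(nu_el0, "nu_el0")
  nu_ref + (nu_m0 - nu_el0)
}

#' Vibronic spectrum: vertical band dressed with Franck-Condon structure
#'
#' Each vertical bin is replicated over the multi-mode Franck-Condon
#' progression of the quantum modes: replica m is shifted by the vibronic
#' offset (downward in energy for emission, upward for absorption) plus any
#' constant 0-0 correction, and weighted by its Franck-Condon factor.
#'
#' @inheritParams vertical_spectrum
#' @param modes A [vibronic_mode_set()] for the electronic transition.
#' @param correction Constant energy correction added to every line, kJ/mol
#'   (e.g. an experimental-gas-phase 0-0 matching shift); default 0.
#' @param cum_tol,max_terms Passed to [fc_transitions()].
#' @return A `"pmm_spectrum"`.
#' @export
vibronic_spectrum <- function(gaps, dipoles, modes, bin_width = 1,
                              sigma = NULL, kind = c("emission", "absorption"),
                              correction = 0, grid = NULL,
                              normalization = "absolute",
                              cum_tol = 1e-6, max_terms = 1e6) {
  kind <- match.arg(kind)
  if (is.null(sigma)) {
    s_cl <- classical_broadening(modes)
    sigma <- if (s_cl > 0) s_cl else bin_width
  }
  base <- vertical_spectrum(gaps, dipoles, bin_width = bin_width,
                            sigma = sigma, kind = kind, grid = grid)
  if (base$n_frames == 0L) return(base)
  tr <- fc_transitions(modes, cum_tol = cum_tol, max_terms = max_terms)
  sgn <- if (kind == "emission") -1 else 1
  pos <- c(outer(base$bins$nu_ref, sgn * tr$shift + correction, `+`))
  if (is.null(grid))
    grid <- seq(min(pos) - 4 * sigma, max(pos) + 4 * sigma,
                length.out = 2048L)
  I <- numeric(length(grid))
  for (t in seq_len(nrow(tr))) {
    b <- base$bins
    b$nu_ref <- vibronic_shift(b$nu_ref, sgn * tr$shift[t] + correction, 0)
    I <- I + tr$weight[t] *
      .bins_to_intensity(b, base$n_frames, grid, sigma, kind)
  }
  sp <- structure(
    list(grid = grid, intensity = I, kind = kind, normalization = "absolute",
         bins = base$bins, sigma = sigma, bin_width = bin_width,
         n_frames = base$n_frames),
    class = "pmm_spectrum")
  normalize_spectrum(sp, normalization)
}

#' Weighted mixture of spectra on a common grid
#'
#' Pointwise weighted sum of component spectra after linear interpolation
#' onto the union grid (zero outside each component's support), e.g. the
#' equilibrium-weighted average of the Lb and La emissions.
#'
#' @param spectra List of `"pmm_spectrum"` objects.
#' @param weights Nonnegative weights summing to 1 (tolerance 1e-9).
#' @return A `"pmm_spectrum"` on the union grid.
#' @export
assemble_spectrum <- function(spectra, weights) {
  stopifnot(is.list(spectra), length(spectra) == length(weights))
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9)
    stop("weights must sum to 1", call. = FALSE)
  grids <- lapply(spectra, `[[`, "grid")
  grid <- sort(unique(unlist(grids)))
  I <- numeric(length(grid))
  for (k in seq_along(spectra)) {
    sp <- spectra[[k]]
    if (length(sp$grid) == 0L || weights[k] == 0) next
    Ik <- stats::approx(sp$grid, sp$intensity, xout = grid, rule = 1)$y
    Ik[is.na(Ik)] <- 0
    I <- I + weights[k] * Ik
  }
  structure(
    list(grid = grid, intensity = I, kind = spectra[[1L]]$kind,
         normalization = "mixture", bins = NULL,
         sigma = spectra[[1L]]$sigma, bin_width = spectra[[1L]]$bin_width,
         n_frames = sum(vapply(spectra, `[[`, numeric(1), "n_frames"))),
    class = "pmm_spectrum")
}

#' Einstein spontaneous-emission rate of one transition
#'
#' \eqn{A = 16\pi^3 \nu^3 |\mu|^2 / (3\epsilon_0 h c^3)} evaluated from a
#' transition energy in kJ/mol and a squared dipole in e^2 nm^2.
#'
#' @param energy Transition energy, kJ/mol (vectorized).
#' @param mu2 Squared transition dipole norm, e^2 nm^2 (vectorized).
#' @return Rate in ns^-1.
#' @export
einstein_A <- function(energy, mu2) {
  .assert_finite(energy, "energy")
  .assert_finite(mu2, "mu2")
  nu <- energy * 1000 / (.NA_SI * .h_SI)              # Hz
  mu2_SI <- mu2 * (.e_SI * 1e-9)^2                    # (C m)^2
  A <- 16 * pi^3 * nu^3 * mu2_SI / (3 * .eps0_SI * .h_SI * .c_SI^3)
  A * 1e-9
}

#' Radiative lifetime of an emitting ensemble
#'
#' Ensemble-average spontaneous-emission rate over the sampled vertical
#' transitions (\eqn{\nu^3 |\mu|^2} times the Einstein-A constant), inverted
#' to a lifetime.
#'
#' @param energies Vertical emission energies, kJ/mol.
#' @param mu2 Squared transition dipole norms, e^2 nm^2.
#' @param weights Optional frame weights (default uniform).
#' @return Lifetime in ns, or `NA` when every dipole is zero.
#' @examples
#' radiative_lifetime(427, 0.043)  # ~ one strong UV transition
#' @export
radiative_lifetime <- function(energies, mu2, weights = NULL) {
  stopifnot(length(energies) == length(mu2), length(energies) > 0L)
  if (is.null(weights)) weights <- rep(1, length(energies))
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  rate <- sum(weights * einstein_A(energies, mu2)) / sum(weights)
  if (rate <= 0) return(NA_real_)
  1 / rate
}
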