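# ---- small helpers ---------------------------------------------------------

# FNV-1a hash of a deparsed object; stable provenance stamp for headers
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 2166136261
  for (ch in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), ch)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

.header_lines <- function(extra = NULL) {
  c(sprintf("# package: pmmkin %s",
            as.character(utils::packageVersion("pmmkin"))),
    extra)
}

.write_table <- function(df, path, extra_header = NULL, digits = 10) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.header_lines(extra_header), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  for (i in seq_len(nrow(df))) {
    row <- vapply(df[i, , drop = FALSE], function(v) {
      if (is.numeric(v)) .fmt_num(v, digits) else as.character(v)
    }, character(1))
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(path)
}

.read_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

# ---- quantum center --------------------------------------------------------

#' Write / read a quantum center as structured JSON
#'
#' Serializes every field of a [quantum_center()] (states, charges, dipole
#' matrices, mode sets, atoms) to a JSON document; `read_quantum_center()`
#' re-validates through the constructor on load.
#'
#' @param qc A [quantum_center()].
#' @param path File path.
#' @return `write_quantum_center()` the path, invisibly;
#'   `read_quantum_center()` the validated [quantum_center()].
#' @export
write_quantum_center <- function(qc, path) {
  stopifnot(inherits(qc, "quantum_center"))
  doc <- list(
    states = lapply(qc$states, function(s)
      list(label = s$label, energy = s$energy, charges = s$charges,
           diagonal_dipole = s$diagonal_dipole,
           vibronic_correction = s$vibronic_correction)),
    transition_dipoles = qc$transition_dipoles,
    atoms = qc$atoms,
    mode_sets = if (is.null(qc$mode_sets)) NULL else
      lapply(qc$mode_sets, function(m)
        list(omega = m$omega, displacement = m$displacement,
             temperature = m$temperature)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_quantum_center
#' @export
read_quantum_center <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  states <- lapply(seq_len(nrow(doc$states)), function(i) {
    s <- doc$states[i, ]
    unperturbed_state(s$label, s$energy, unlist(s$charges),
                      unlist(s$diagonal_dipole), s$vibronic_correction)
  })
  n <- length(states)
  td <- array(as.numeric(doc$transition_dipoles), c(n, n, 3L))
  ms <- NULL
  if (!is.null(doc$mode_sets) && length(doc$mode_sets)) {
    ms <- lapply(doc$mode_sets, function(m)
      vibronic_mode_set(unlist(m$omega), unlist(m$displacement),
                        m$temperature))
  }
  atoms <- if (is.null(doc$atoms) || !length(doc$atoms)) NULL else
    as.data.frame(doc$atoms)
  quantum_center(states, td, atoms = atoms, mode_sets = ms)
}

# ---- perturbation frames & gap traces --------------------------------------

#' Write / read perturbation frames as a delimited table
#'
#' One row per frame: `time`, one potential column per atom (`V1..Vn`),
#' the field components `Ex`, `Ey`, `Ez` and the scalar `offset`.  On
#' reading, malformed (non-finite) rows are skipped with a counted
#' warning; more than `max_bad` fraction of bad rows aborts.
#'
#' @param frames List of [perturbation_frame()]s.
#' @param path File path.
#' @param max_bad Abort threshold for the malformed-row fraction (default
#'   0.01).
#' @return The path / the list of frames.
#' @export
write_frames <- function(frames, path) {
  stopifnot(is.list(frames), length(frames) > 0L)
  na <- length(frames[[1L]]$site_potentials)
  df <- do.call(rbind, lapply(frames, function(f)
    c(f$time, f$site_potentials, f$field, f$offset)))
  df <- as.data.frame(df)
  names(df) <- c("time", paste0("V", seq_len(na)), "Ex", "Ey", "Ez", "offset")
  .write_table(df, path, extra_header = sprintf("# n_atoms: %d", na))
}

#' @rdname write_frames
#' @export
read_frames <- function(path, max_bad = 0.01) {
  df <- .read_table(path)
  na <- length(grep("^V[0-9]+$", names(df)))
  if (na == 0L) stop("no potential columns found", call. = FALSE)
  for (j in seq_along(df)) df[[j]] <- suppressWarnings(as.numeric(df[[j]]))
  good <- apply(df, 1L, function(r) all(is.finite(as.numeric(r))))
  n_bad <- sum(!good)
  if (n_bad > 0L) {
    if (n_bad / nrow(df) > max_bad)
      stop(sprintf("%d of %d rows malformed", n_bad, nrow(df)), call. = FALSE)
    warning(sprintf("skipped %d malformed row(s)", n_bad))
    df <- df[good, , drop = FALSE]
  }
  lapply(seq_len(nrow(df)), function(i)
    perturbation_frame(df$time[i],
                       as.numeric(df[i, paste0("V", seq_len(na))]),
                       c(df$Ex[i], df$Ey[i], df$Ez[i]),
                       df$offset[i]))
}

#' Write / read a gap trace as a delimited table
#'
#' Columns `time`, `gap`, `deriv` with a `#` header block.
#'
#' @param trace A [gap_trace()].
#' @param path File path.
#' @return The path / the [gap_trace()].
#' @export
write_gap_trace <- function(trace, path) {
  stopifnot(inherits(trace, "gap_trace"))
  .write_table(data.frame(time = trace$times, gap = trace$gap,
                          deriv = trace$deriv), path)
}

#' @rdname write_gap_trace
#' @export
read_gap_trace <- function(path) {
  df <- .read_table(path)
  gap_trace(df$time, df$gap, df$deriv)
}

#' Write a spectrum as a two-column table
#'
#' Energy (kJ/mol) and intensity, preceded by a `#` header recording kind,
#' normalization, broadening and bin width.
#'
#' @param sp A `"pmm_spectrum"`.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_spectrum <- function(sp, path) {
  stopifnot(inherits(sp, "pmm_spectrum"))
  hdr <- c(sprintf("# kind: %s", sp$kind),
           sprintf("# normalization: %s", sp$normalization),
           sprintf("# sigma_kJmol: %s", .fmt_num(sp$sigma %||% NA)),
           sprintf("# bin_width_kJmol: %s", .fmt_num(sp$bin_width %||% NA)),
           sprintf("# n_frames: %d", sp$n_frames))
  .write_table(data.frame(energy = sp$grid, intensity = sp$intensity),
               path, extra_header = hdr)
}

# ---- configuration & pipeline drivers --------------------------------------

#' Read a run configuration
#'
#' YAML configuration with defaults filled in: `temperature` 300 K, time
#' `step` 1 fs, `n_starts` 500, `seed` 1, `bin_width` 1 kJ/mol.  Any field
#' can be overridden through `...`.
#'
#' @param path Optional YAML file.
#' @param ... Named overrides.
#' @return Named list of class `"run_config"`.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(temperature = 300, step = 1, n_starts = 500, seed = 1L,
              bin_width = 1, horizon = NULL, broadening = NULL)
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

.cfg_header <- function(cfg) {
  c(sprintf("# config_hash: %s", .config_hash(unclass(cfg))),
    sprintf("# seed: %s", as.character(cfg$seed)))
}

#' Per-frame PMM pipeline
#'
#' Reads a quantum center and a perturbation-frame stream, sweeps the PMM
#' per frame (energies, first-excited diabatic assignment, requested gap)
#' and writes the result as a delimited table with a provenance header.
#' Rerunning an identical configuration yields a byte-identical file.
#'
#' @param cfg A [run_config()] with `qc_file`, `frames_file`, optional
#'   `gap` (character pair of labels) and `out_file`.
#' @return The output table (data frame), invisibly if written.
#' @export
run_pmm <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  qc <- read_quantum_center(cfg$qc_file)
  frames <- read_frames(cfg$frames_file)
  gap <- cfg$gap
  out <- pmm_sweep(qc, frames, gap = gap)
  if (!is.null(cfg$out_file)) {
    .write_table(out, cfg$out_file, extra_header = .cfg_header(cfg))
    return(invisible(out))
  }
  out
}

#' Crossing-kinetics pipeline
#'
#' Computes per-channel attempt lifetimes, transmission coefficients and
#' reaction lifetimes.  With gap-trace files available the explicit route
#' is used (first-crossing detection, survival fit, event-wise
#' transmission); otherwise the Gaussian + crossing-mean-coupling route
#' runs from ensemble statistics.
#'
#' @param cfg A [run_config()].  Explicit route: `trace_files` (character
#'   vector), `coupling` (kJ/mol), `mean_omega`.  Statistics route:
#'   `stats` = list(mean, sd, mean_speed), `alpha_e` or (`geometry` =
#'   [coupling_geometry()]), `mean_omega`.  Common: `channel` name,
#'   optional `out_file`, `horizon`.
#' @return Data frame (one row per channel): `channel`, `tau0`, `alpha_e`,
#'   `alpha_G`, `tau`, `method`.
#' @export
run_kinetics <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  channel <- cfg$channel %||% "R->P"
  if (!is.null(cfg$trace_files)) {
    traces <- lapply(cfg$trace_files, read_gap_trace)
    horizon <- cfg$horizon %||% max(vapply(traces, function(t)
      max(t$times), numeric(1)))
    ev <- lapply(traces, detect_first_crossing)
    times <- vapply(ev, function(e) if (is.null(e)) NA_real_ else e$time,
                    numeric(1))
    surv <- survival_trace(times, horizon)
    fit <- fit_survival(surv)
    v_cr <- vapply(ev[!is.na(times)], `[[`, numeric(1), "v_cr")
    chi <- lz_adiabatic_fraction(cfg$coupling %||% 0, v_cr)
    om <- cfg$mean_omega %||% 1
    tr <- transmission_explicit(chi, om, seed = cfg$seed)
    est <- rate_estimate(fit$tau0, tr$alpha_G, method = "explicit")
    alpha_e <- mean(chi)
  } else if (!is.null(cfg$stats)) {
    s <- cfg$stats
    gr <- gaussian_rate(s$mean, s$sd, s$mean_speed)
    if (!is.null(cfg$alpha_e)) {
      alpha_e <- cfg$alpha_e
    } else if (!is.null(cfg$geometry)) {
      alpha_e <- mean_coupling_alpha_e(cfg$geometry, s$mean_speed)$alpha_e
    } else stop("need alpha_e or geometry for the statistics route",
                call. = FALSE)
    aG <- transmission_approx(alpha_e, cfg$mean_omega %||% 1)
    est <- rate_estimate(gr$tau0, aG, method = "gaussian+mean_coupling")
  } else stop("need either trace_files or stats", call. = FALSE)
  out <- data.frame(channel = channel, tau0 = est$tau0, alpha_e = alpha_e,
                    alpha_G = est$alpha_G, tau = est$tau,
                    method = est$method, stringsAsFactors = FALSE)
  if (!is.null(cfg$out_file)) {
    .write_table(out, cfg$out_file, extra_header = .cfg_header(cfg))
    return(invisible(out))
  }
  out
}

#' Relaxation-network pipeline
#'
#' Runs the full observable chain (free energy -> fractions -> combined
#' lifetimes -> fluorescence observables) from component lifetimes and
#' either a free energy or the two ensemble gap means, with optional ISC.
#'
#' @param cfg A [run_config()] with `tau_r_b`, `tau_r_a`, `tau_b`,
#'   `tau_a` (ns) and either `dA` (kJ/mol) or `mean_gap_R`/`mean_gap_P`;
#'   optional `tau_ISC`, `se` (named list), `out_file`.
#' @return The [network_summary()] data frame.
#' @export
run_relax <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dA <- cfg$dA %||%
    free_energy_from_ensembles(cfg$mean_gap_R, cfg$mean_gap_P)
  sc <- relaxation_scheme(dA, cfg$tau_r_b, cfg$tau_r_a, cfg$tau_b,
                          cfg$tau_a, tau_ISC = cfg$tau_ISC,
                          temperature = cfg$temperature, se = cfg$se)
  rep <- network_summary(sc)
  if (!is.null(cfg$out_file)) {
    .write_table(rep, cfg$out_file, extra_header = .cfg_header(cfg))
    return(invisible(rep))
  }
  rep
}
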