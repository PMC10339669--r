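test_that("first-crossing detection interpolates the bracketing interval", {
  # linear ramp: gap = 5 - t, crossing at t = 5 with unit speed
  tr <- gap_trace(0:10, 5 - (0:10))
  e <- detect_first_crossing(tr)
  expect_equal(e$time, 5)
  expect_equal(e$v_cr, 1)
  # monotone positive trace never crosses
  expect_null(detect_first_crossing(gap_trace(0:10, 10 + (0:10))))
  # reactant-side precondition
  expect_error(detect_first_crossing(gap_trace(0:10, -1 + 0 * (0:10))),
               "positive")
})

test_that("sinusoid crossing matches the analytic root within half a step", {
  w <- 2 * pi / 180; phi <- 0.4
  t <- seq(0, 300, by = 1)
  tr <- gap_trace(t, 3.62 + 7.1 * sin(w * t + phi))
  # first root of sin(w t + phi) = -3.62/7.1 after t = 0
  asr <- asin(-3.62 / 7.1)              # in (-pi/2, 0)
  t_exact <- ((pi - asr) - phi) / w     # descending branch root
  e <- detect_first_crossing(tr)
  expect_lt(abs(e$time - t_exact), 0.5)
  expect_equal(e$v_cr, abs(7.1 * w * cos(w * e$time + phi)), tolerance = 0.05)
})

test_that("central-difference velocities are second-order accurate", {
  t <- seq(0, 100, by = 0.5)
  tr <- gap_trace(t, sin(0.2 * t))
  interior <- 2:(length(t) - 1)
  expect_lt(max(abs(tr$deriv[interior] - 0.2 * cos(0.2 * t[interior]))), 1e-3)
})

test_that("survival curves census crossings with right censoring", {
  s <- survival_trace(rep(25, 10), horizon = 100, grid = c(0, 24, 26, 100))
  expect_equal(s$survival, c(1, 1, 0, 0))
  s2 <- survival_trace(rep(NA_real_, 5), horizon = 100)
  expect_true(all(s2$survival == 1))
  # censored trajectories keep surviving through the horizon
  s3 <- survival_trace(c(10, NA, NA, NA), horizon = 50, grid = c(0, 20, 50))
  expect_equal(s3$survival, c(1, 0.75, 0.75))
})

test_that("survival fitting recovers exponential and biexponential lifetimes", {
  set.seed(101)
  # pure exponential: nested model, tau0 within 2 %
  x <- rexp(2000, rate = 1 / 150)
  fit <- fit_survival(survival_trace(x, horizon = 1500))
  expect_lt(abs(fit$tau0 / 150 - 1), 0.02)

  # planted mixture 0.4 exp(-t/50) + 0.6 exp(-t/300): tau0 = 200 within 5 %
  comp <- runif(4000) < 0.4
  x2 <- ifelse(comp, rexp(4000, 1 / 50), rexp(4000, 1 / 300))
  fit2 <- fit_survival(survival_trace(x2, horizon = 3000,
                                      grid = seq(0, 3000, by = 5)))
  expect_equal(fit2$model, "biexponential")
  expect_lt(abs(fit2$tau0 / 200 - 1), 0.05)

  # constant survival exercises the error path
  expect_error(fit_survival(data.frame(time = 0:10, survival = rep(1, 11))),
               "never decreases")
})

test_that("Landau-Zener adiabatic fraction has the right limits and value", {
  expect_equal(lz_adiabatic_fraction(0, 0.4), 0)
  expect_gt(lz_adiabatic_fraction(0.5, 1e-9), 1 - 1e-12)  # adiabatic limit
  hbar <- pmm_constants()$hbar
  expect_equal(lz_adiabatic_fraction(0.1, 0.4),
               1 - exp(-2 * pi * 0.01 / (hbar * 0.4)), tolerance = 1e-12)
  expect_equal(lz_adiabatic_fraction(0.1, 0.4), 2.470e-3, tolerance = 1e-3)
  expect_error(lz_adiabatic_fraction(0.1, 0), "positive")
})

test_that("vibrational overlap sums are bounded partial Poisson sums", {
  xi2 <- fc_factor(0.5, 0:30)
  expect_equal(omega_overlap(xi2, 1), exp(-0.5))
  expect_equal(omega_overlap(xi2, 2), exp(-0.5) * 1.5, tolerance = 1e-12)
  expect_equal(omega_overlap(xi2, 31), 1, tolerance = 1e-9)
  expect_true(omega_overlap(xi2, 5) >= xi2[1])
})

test_that("explicit transmission averages event probabilities", {
  expect_equal(transmission_explicit(rep(1, 5), 1, n_boot = 0)$alpha_G, 1)
  chi <- c(0.2, 0.5, 0.8)
  expect_equal(transmission_explicit(chi, 1, n_boot = 0)$alpha_G, mean(chi))
  two <- transmission_explicit(c(0.5, 0.5), c(1, 0.5), n_boot = 0)
  expect_equal(two$alpha_G, 1 - (0.5 + 0.5^0.5) / 2, tolerance = 1e-12)
  expect_error(transmission_explicit(numeric(0), 1), "no crossing events")
  # bootstrap SE is reproducible and positive for heterogeneous events
  set.seed(9); chi50 <- runif(50)
  b1 <- transmission_explicit(chi50, 0.7, seed = 3)
  b2 <- transmission_explicit(chi50, 0.7, seed = 3)
  expect_gt(b1$se, 0)
  expect_identical(b1$se, b2$se)
})

test_that("approximate transmission matches its limits and example", {
  expect_equal(transmission_approx(0.3, 1), 0.3)
  expect_equal(transmission_approx(1, 0.4), 1)
  expect_equal(transmission_approx(0.3, 0.5), 1 - 0.7^0.5, tolerance = 1e-12)
  expect_error(transmission_approx(1.2, 0.5), "outside")
  expect_error(transmission_approx(0.5, 0), "outside")
})

test_that("explicit and approximate transmissions coincide for degenerate events", {
  for (chi in c(0.1, 0.5, 0.9)) for (om in c(0.2, 0.7, 1)) {
    expl <- transmission_explicit(rep(chi, 20), om, n_boot = 0)$alpha_G
    appr <- transmission_approx(chi, om)
    expect_equal(expl, appr, tolerance = 1e-12)
  }
})

test_that("transmission is monotone in alpha_e and omega and confined to [0,1]", {
  ae <- seq(0.05, 0.95, by = 0.1)
  om <- seq(0.1, 1, by = 0.1)
  for (o in om) {
    v <- vapply(ae, transmission_approx, numeric(1), mean_omega = o)
    expect_true(all(diff(v) > 0))
    expect_true(all(v >= 0 & v <= 1))
  }
  for (a in ae) {
    v <- vapply(om, function(o) transmission_approx(a, o), numeric(1))
    expect_true(all(diff(v) > 0))
  }
})

test_that("the Gaussian attempt rate reproduces the tabulated lifetimes", {
  # printed reactant-ensemble statistics, rounded to 2 significant figures
  expect_lt(abs(gaussian_rate(3.62, 7.1, 0.4)$tau0 / 105 - 1), 0.05)
  expect_lt(abs(gaussian_rate(13.15, 6.5, 0.4)$tau0 / 614 - 1), 0.05)
  expect_error(gaussian_rate(-1, 7.1, 0.4), "positive")
  expect_error(gaussian_rate(3.62, 0, 0.4), "positive")
})

test_that("the Gaussian attempt rate is Rice's downcrossing rate", {
  # for Gaussian velocity, <|v|> = sd_v sqrt(2/pi) and
  # k0 = rho(0) sd_v / sqrt(2 pi)
  for (m in c(3, 10)) for (s in c(5, 8)) for (sv in c(0.3, 1)) {
    k0 <- gaussian_rate(m, s, sv * sqrt(2 / pi))$k0
    rice <- dnorm(0, m, s) * sv / sqrt(2 * pi)
    expect_equal(k0, rice, tolerance = 1e-12)
  }
})

test_that("reaction lifetimes allow two hop opportunities per approach", {
  expect_equal(reaction_lifetime(176, 0.295), 350, tolerance = 0.01)
  expect_equal(reaction_lifetime(1727, 0.422), 2593, tolerance = 0.01)
  expect_equal(reaction_lifetime(100, 1), 100)
  expect_true(is.na(reaction_lifetime(100, 0)))
  # strictly decreasing in alpha_G
  a <- seq(0.05, 1, by = 0.05)
  taus <- vapply(a, reaction_lifetime, numeric(1), tau0 = 100)
  expect_true(all(diff(taus) < 0))
  expect_true(all(taus >= 100))
})

test_that("coupling geometry enforces the dipolar crossing condition", {
  mu_R <- c(0.1, 0, 0); mu_P <- c(0.25, 0, 0)   # dmu along -x, |dmu| = 0.15
  mu_bar <- c(0.02, 0.03, 0)
  g <- coupling_geometry(mu_R, mu_P, mu_bar, gap0 = 30,
                         E_perp_mean = 5, E_perp_sq_mean = 40)
  expect_equal(sum(g$eta_par * g$eta_perp), 0, tolerance = 1e-12)
  expect_equal(sqrt(sum(g$eta_par^2)), 1, tolerance = 1e-12)
  expect_equal(sqrt(sum(g$eta_perp^2)), 1, tolerance = 1e-12)
  expect_equal(g$E_par, -30 / 0.15)
  # the gap, linear in E_par, vanishes at the crossing:
  # gap(E) = gap0 + E_par * |dmu|
  expect_equal(g$gap0 + g$E_par * g$dmu_norm, 0, tolerance = 1e-12)
  expect_error(coupling_geometry(mu_R, mu_R, mu_bar, 30, 5, 40), "vanishes")
})

test_that("mean-coupling alpha_e: null geometry and zero-variance limits", {
  mu_R <- c(0.1, 0, 0); mu_P <- c(0.25, 0, 0)
  # vanishing mean transition dipole: no coupling, alpha_e = 0
  g0 <- coupling_geometry(mu_R, mu_P, c(0, 0, 0), 30, 5, 40)
  expect_equal(mean_coupling_alpha_e(g0, 0.4)$alpha_e, 0)
  # degenerate E_perp statistics reduce to a single deterministic coupling
  e <- 4
  gd <- coupling_geometry(mu_R, mu_P, c(0.02, 0.03, 0), 30,
                          E_perp_mean = e, E_perp_sq_mean = e^2)
  H <- abs(gd$E_par * gd$mu_par + e * gd$mu_perp)
  expect_equal(mean_coupling_alpha_e(gd, 0.4)$alpha_e,
               lz_adiabatic_fraction(H, 0.4), tolerance = 1e-12)
})

test_that("mean-coupling alpha_e agrees with brute-force crossing averaging", {
  # small couplings: <exp(-a H^2)> ~ exp(-a <H^2>), so the equilibrium
  # statistics route must match explicit averaging within 10 %
  mu_R <- c(0.12, 0.02, 0); mu_P <- c(0.3, -0.04, 0)
  mu_bar <- c(0.01, 0.015, 0.005)
  v <- 1.7
  set.seed(202)
  E_perp <- rnorm(20000, mean = 2, sd = 4)
  g <- coupling_geometry(mu_R, mu_P, mu_bar, gap0 = 120,
                         E_perp_mean = mean(E_perp),
                         E_perp_sq_mean = mean(E_perp^2))
  H <- g$E_par * g$mu_par + E_perp * g$mu_perp
  hbar <- pmm_constants()$hbar
  alpha_brute <- 1 - mean(exp(-2 * pi * H^2 / (hbar * v)))
  alpha_mc <- mean_coupling_alpha_e(g, v)$alpha_e
  expect_lt(abs(alpha_mc / alpha_brute - 1), 0.10)
})

test_that("rate estimates propagate standard errors first order", {
  est <- rate_estimate(176, 0.295, method = "explicit",
                       se = c(tau0 = 8, alpha_G = 0.02))
  expect_equal(est$tau, 350, tolerance = 0.01)
  # analytic gradient check: dtau/dtau0 = tau/tau0
  num <- est$se[["tau"]]
  dta <- est$tau / 176 * 8
  dag <- abs((reaction_lifetime(176, 0.295 + 1e-6) -
                reaction_lifetime(176, 0.295 - 1e-6)) / 2e-6) * 0.02
  expect_equal(num, sqrt(dta^2 + dag^2), tolerance = 1e-4)
})
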