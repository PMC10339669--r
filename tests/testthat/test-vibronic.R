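test_that("Franck-Condon factors follow the displaced-oscillator Poisson law", {
  expect_equal(fc_factor(0, 0), 1)
  expect_equal(fc_factor(0, 1:5), rep(0, 5))
  expect_equal(fc_factor(1, 1), exp(-1))
  expect_error(fc_factor(-0.1, 0), "nonnegative")
  # completeness to 1e-10 with adaptive truncation
  for (S in c(0.05, 0.5, 1, 3, 8)) {
    nmax <- 0
    while (ppois(nmax, S) < 1 - 1e-12) nmax <- nmax + 1
    expect_lt(abs(sum(fc_factor(S, 0:nmax)) - 1), 1e-10)
  }
})

test_that("Huang-Rhys factors come out dimensionless and sane", {
  # omega = 0.2 fs^-1, d chosen for S = 0.5 exactly
  S_target <- 0.5
  d <- sqrt(2 * pmm_constants()$hbar * S_target /
              (0.2 * pmm_constants()$amu_nm2_fs2))
  ms <- vibronic_mode_set(0.2, d)
  expect_equal(ms$S, 0.5, tolerance = 1e-12)
  expect_true(ms$quantum)  # hbar*0.2 = 12.7 kJ/mol >> kBT
  ms2 <- vibronic_mode_set(0.01, d)
  expect_false(ms2$quantum)  # 0.635 kJ/mol < kBT at 300 K
})

test_that("multi-mode FC transitions are products of per-mode factors", {
  hbar <- pmm_constants()$hbar
  S <- c(0.3, 0.7); w <- c(0.2, 0.35)
  d <- sqrt(2 * hbar * S / (w * pmm_constants()$amu_nm2_fs2))
  ms <- vibronic_mode_set(w, d)
  tr <- fc_transitions(ms, cum_tol = 1e-9)
  expect_lt(abs(sum(tr$weight) - 1), 1e-6)
  # the (n1=1, n2=2) line: weight and shift by direct evaluation
  target_shift <- hbar * (1 * w[1] + 2 * w[2])
  i <- which(abs(tr$shift - target_shift) < 1e-9)
  expect_length(i, 1L)
  expect_equal(tr$weight[i], fc_factor(S[1], 1) * fc_factor(S[2], 2),
               tolerance = 1e-12)
})

test_that("vertical spectrum handles degenerate inputs", {
  expect_equal(length(vertical_spectrum(numeric(0), numeric(0))$grid), 0L)
  sp0 <- vertical_spectrum(400, 0)
  expect_true(all(sp0$intensity == 0))
  expect_error(vertical_spectrum(c(400, 401), c(1, 1), bin_width = 0),
               "positive")
})

test_that("identical frames give one Gaussian with N-independent area", {
  area <- function(sp) sum(diff(sp$grid) *
                             (head(sp$intensity, -1) + tail(sp$intensity, -1)) / 2)
  grid <- seq(380, 420, length.out = 2001)
  sp1 <- vertical_spectrum(rep(400.5, 3), rep(0.02, 3), sigma = 2, grid = grid)
  sp2 <- vertical_spectrum(rep(400.5, 300), rep(0.02, 300), sigma = 2,
                           grid = grid)
  expect_equal(area(sp1), area(sp2), tolerance = 1e-9)
  expect_equal(sp1$intensity, sp2$intensity, tolerance = 1e-12)
  # single bin, so the shape is the prefactor times one Gaussian
  expect_equal(sp1$grid[which.max(sp1$intensity)], 400.5, tolerance = 0.1)
})

test_that("two-bin toy reproduces hand binning and the nu^3 peak ratio", {
  gaps <- c(400.5, 420.5)
  sp <- vertical_spectrum(gaps, c(0.02, 0.02), bin_width = 1, sigma = 1,
                          kind = "emission")
  expect_equal(sp$bins$n, c(1L, 1L))
  expect_equal(sp$bins$nu_ref, c(400.5, 420.5))
  i1 <- sp$intensity[which.min(abs(sp$grid - 400.5))]
  i2 <- sp$intensity[which.min(abs(sp$grid - 420.5))]
  expect_equal(i2 / i1, (420.5 / 400.5)^3, tolerance = 1e-3)
  # absorption weighting uses nu^1
  spa <- vertical_spectrum(gaps, c(0.02, 0.02), bin_width = 1, sigma = 1,
                           kind = "absorption")
  a1 <- spa$intensity[which.min(abs(spa$grid - 400.5))]
  a2 <- spa$intensity[which.min(abs(spa$grid - 420.5))]
  expect_equal(a2 / a1, 420.5 / 400.5, tolerance = 1e-3)
})

test_that("spectrum area is stable under bin-width refinement", {
  set.seed(11)
  gaps <- rnorm(4000, 420, 5)
  mu2 <- rep(0.02, 4000)
  grid <- seq(380, 460, length.out = 2001)
  area <- function(bw) {
    sp <- vertical_spectrum(gaps, mu2, bin_width = bw, sigma = 3, grid = grid)
    sum(diff(sp$grid) * (head(sp$intensity, -1) + tail(sp$intensity, -1)) / 2)
  }
  expect_lt(abs(area(1) / area(2) - 1), 0.01)
  expect_lt(abs(area(0.5) / area(1) - 1), 0.01)
})

test_that("vibronic shifts place replicas at nu_ref + (nu_m0 - nu_el0)", {
  expect_equal(vibronic_shift(400, 350, 350), 400)
  expect_equal(vibronic_shift(c(400, 410), 320, 350), c(370, 380))
  # a constant 0-0 correction moves every replica rigidly
  corr <- -0.32 * pmm_constants()$eV
  expect_equal(vibronic_shift(400, 350 + corr, 350), 400 + corr)
})

test_that("emission progression peaks at nu0 - n*hbar*omega with Poisson weights", {
  hbar <- pmm_constants()$hbar
  w <- 10 / hbar                       # hbar*omega = 10 kJ/mol
  S <- 0.5
  d <- sqrt(2 * hbar * S / (w * pmm_constants()$amu_nm2_fs2))
  ms <- vibronic_mode_set(w, d)
  grid <- seq(300, 440, length.out = 4001)
  sp <- vibronic_spectrum(rep(400.5, 10), rep(0.02, 10), ms, sigma = 1,
                          kind = "emission", grid = grid)
  at <- function(x) sp$intensity[which.min(abs(sp$grid - x))]
  # line n=2 sits 20 kJ/mol below the 0-0 line
  r_obs <- at(400.5 - 20) / at(400.5)
  r_exp <- (fc_factor(S, 2) / fc_factor(S, 0)) * ((400.5 - 20) / 400.5)^3
  expect_equal(r_obs, r_exp, tolerance = 0.01)
})

test_that("spectrum mixtures behave like convex combinations", {
  grid <- seq(350, 450, length.out = 1001)
  spA <- vertical_spectrum(rnorm(500, 420, 3), rep(0.02, 500), sigma = 2,
                           grid = grid)
  spB <- vertical_spectrum(rnorm(500, 390, 3), rep(0.03, 500), sigma = 2,
                           grid = grid)
  expect_equal(assemble_spectrum(list(spA, spB), c(1, 0))$intensity,
               spA$intensity, tolerance = 1e-12)
  mixAA <- assemble_spectrum(list(spA, spA), c(0.3, 0.7))
  expect_equal(mixAA$intensity, spA$intensity, tolerance = 1e-12)
  expect_error(assemble_spectrum(list(spA, spB), c(0.5, 0.6)), "sum to 1")
  # monotone interpolation between the components
  m25 <- assemble_spectrum(list(spA, spB), c(0.25, 0.75))$intensity
  m75 <- assemble_spectrum(list(spA, spB), c(0.75, 0.25))$intensity
  lohi <- pmin(spA$intensity, spB$intensity)
  uphi <- pmax(spA$intensity, spB$intensity)
  expect_true(all(m25 >= lohi - 1e-12 & m25 <= uphi + 1e-12))
  expect_true(all(m75 >= lohi - 1e-12 & m75 <= uphi + 1e-12))
})

test_that("a minority high-energy band leaves the mixture peak at the majority band", {
  grid <- seq(340, 460, length.out = 2001)
  spLb <- vertical_spectrum(rnorm(800, 430, 2), rep(0.01, 800), sigma = 2,
                            grid = grid)
  spLa <- vertical_spectrum(rnorm(800, 380, 2), rep(0.04, 800), sigma = 2,
                            grid = grid)
  mix <- assemble_spectrum(list(spLb, spLa), c(0.118, 0.882))
  peak_mix <- mix$grid[which.max(mix$intensity)]
  peak_La <- spLa$grid[which.max(spLa$intensity)]
  expect_equal(peak_mix, peak_La, tolerance = 1)
})

test_that("radiative rates follow the Einstein-A scaling laws", {
  # doubling |mu|^2 halves the lifetime
  expect_equal(radiative_lifetime(420, 0.02),
               2 * radiative_lifetime(420, 0.04), tolerance = 1e-12)
  # nu^3 law: doubling the frequency gives 8x the rate
  expect_equal(einstein_A(840, 0.02) / einstein_A(420, 0.02), 8,
               tolerance = 1e-12)
  # all dipoles dark: no finite lifetime
  expect_true(is.na(radiative_lifetime(c(400, 410), c(0, 0))))
})

test_that("Einstein A matches an independent SI evaluation for 1 D at 280 nm", {
  cst <- pmm_constants()
  # SI oracle, assembled directly from CODATA constants
  nu <- cst$c_SI / 280e-9
  mu <- cst$debye_SI
  A_SI <- 16 * pi^3 * nu^3 * mu^2 / (3 * cst$eps0_SI * cst$h_SI * cst$c_SI^3)
  # package route: energy in kJ/mol, dipole in e nm
  E_kJmol <- cst$h_SI * nu * cst$NA_SI / 1000
  mu2_enm <- (mu / (cst$e_SI * 1e-9))^2
  expect_equal(einstein_A(E_kJmol, mu2_enm) * 1e9, A_SI, tolerance = 1e-6)
})
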