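test_that("AR(1) simulation reproduces its closed-form lag-1 autocorrelation", {
  x0 <- simulate_ar1(0, 10000, seed = 71)
  expect_lt(abs(stats::acf(x0, plot = FALSE)$acf[2]), 3 / sqrt(10000))

  x9 <- simulate_ar1(0.9, 10000, seed = 72)
  expect_lt(abs(stats::acf(x9, plot = FALSE)$acf[2] - 0.9), 0.03)

  expect_error(simulate_ar1(1, 100), "causal")
  expect_error(simulate_ar1(-1.2, 100), "causal")
})

test_that("negative-phi AR(1) concentrates power near Nyquist", {
  x <- simulate_ar1(-0.5, 8192, seed = 73)
  pg <- periodogram(x, fs = 1)
  hi <- band_power(pg, c(0.25, 0.5))
  lo <- band_power(pg, c(0, 0.25))
  expect_gt(hi, lo)
  # and the closed-form AR(1) spectrum is maximized at the Nyquist side
  f <- ar_spectrum(-0.5, seq(0, 0.5, length.out = 201))
  expect_equal(which.max(f), 201L)
})

test_that("AR(2) band targeting puts the theoretical spectral peak in band", {
  grid <- seq(0.1, 499.9, by = 0.1)
  peak_of <- function(bname, rho) {
    x <- simulate_ar2_band(bname, fs = 1000, n_samples = 100,
                           pole_modulus = rho, seed = 74)
    grid[which.max(ar_spectrum(attr(x, "ar"), grid, fs = 1000))]
  }
  # at the default modulus the mid/high bands hold their peaks
  for (bname in c("alpha", "beta", "gamma")) {
    b <- eeg_bands()[[bname]]
    p <- peak_of(bname, 0.95)
    expect_gte(p, b$lo_hz)
    expect_lte(p, b$hi_hz)
  }
  # the very low bands need poles closer to the unit circle: an AR(2) peak
  # sits below its pole angle and collapses onto DC unless 1 - rho is small
  # relative to the angle, so delta/theta use a sharper modulus
  for (bname in c("delta", "theta")) {
    b <- eeg_bands()[[bname]]
    p <- peak_of(bname, 0.995)
    expect_gte(p, b$lo_hz)
    expect_lte(p, b$hi_hz)
  }
  expect_error(simulate_ar2_band(c(900, 1100), fs = 1000, n_samples = 100),
               "midpoint")
})

test_that("delta-band AR(2) carries most of its band-power in delta", {
  x <- simulate_ar2_band("delta", fs = 1000, n_samples = 8192, seed = 75)
  pg <- periodogram(x, fs = 1000)
  bp <- vapply(eeg_bands(), function(b) band_power(pg, b), numeric(1))
  expect_equal(names(which.max(bp)), "delta")
})

test_that("pole modulus near zero degenerates the AR(2) to white noise", {
  x <- simulate_ar2_band("alpha", fs = 1000, n_samples = 5000,
                         pole_modulus = 1e-4, seed = 76)
  expect_lt(max(abs(attr(x, "ar"))), 1e-3)
  expect_lt(abs(stats::var(x) - 1), 0.1)
  expect_lt(max(abs(stats::acf(x, plot = FALSE)$acf[2:5])), 3 / sqrt(5000))
})

test_that("AR series are variance-stable across halves (stationarity check)", {
  ok <- 0
  for (s in 1:20) {
    x <- simulate_ar1(0.9, 10000, seed = 200 + s)
    v1 <- stats::var(x[1:5000])
    v2 <- stats::var(x[5001:10000])
    ok <- ok + (max(v1, v2) / min(v1, v2) < 3)
  }
  expect_gte(ok / 20, 0.95)
})

test_that("the epoch mixture has the prescribed group structure", {
  spec <- ar_mixture_spec(n_epochs = 30, n_samples = 500, group1_size = 18,
                          seed = 77)
  ef <- simulate_mixture_groups(spec)
  expect_equal(dim(ef$x), c(30L, 500L))
  expect_equal(as.integer(table(ef$group)), c(18L, 12L))
  expect_true(all(abs(attr(ef, "phi1")) < 1))
  expect_true(all(abs(attr(ef, "phi2")) < 1))
  # group 2 weights concentrate at zero
  expect_lt(max(abs(attr(ef, "a2")[19:30])), 0.2)

  # zero jitter freezes the AR coefficients across epochs
  ef0 <- simulate_mixture_groups(
    ar_mixture_spec(n_epochs = 6, n_samples = 64, group1_size = 3,
                    coeff_jitter_var = 0, seed = 78))
  expect_equal(attr(ef0, "phi1"), rep(0.9, 6))
  expect_equal(attr(ef0, "phi2"), rep(-0.5, 6))

  expect_error(ar_mixture_spec(n_epochs = 10, group1_size = 11),
               "group sizes")
})

test_that("group spectra show one dominant region vs two elevated regions", {
  ef <- simulate_mixture_groups(ar_mixture_spec(seed = 79))
  mean_pg <- function(rows) {
    Reduce(`+`, lapply(rows, function(r)
      periodogram(ef$x[r, ], fs = ef$fs)$power)) / length(rows)
  }
  p1 <- mean_pg(1:120)
  p2 <- mean_pg(121:220)
  frac_hi <- function(p) sum(p[251:501]) / sum(p)
  # group 1 keeps both mixture components, so it carries a visibly larger
  # share of power in the upper half of the axis than group 2, whose second
  # component is switched off
  expect_gt(frac_hi(p1), 2 * frac_hi(p2))
  # group 2's remaining component (phi = 0.9) peaks near zero frequency
  expect_lte(which.max(p2), 10L)
})

test_that("curve families honor the case formulas and determinism", {
  # noise-free identical case: both families equal the deterministic mean
  spec0 <- curve_family_spec("identical", between_curve_var = 0,
                             within_curve_var = 0, seed = 80)
  f0 <- simulate_curve_families(spec0)
  expect_identical(f0$family1$values, f0$family2$values)
  expect_equal(nrow(f0$family1$values), 50)

  # appreciable case: family-mean separation at k = 60 is 2*60/3 = 40
  specA <- curve_family_spec("appreciable", between_curve_var = 0,
                             within_curve_var = 0, seed = 81)
  fA <- simulate_curve_families(specA)
  expect_equal(fA$family2$values[1, 60] - fA$family1$values[1, 60], 40,
               tolerance = 1e-10)

  # fixed seed gives byte-identical output
  s1 <- simulate_curve_families(curve_family_spec("slight", seed = 82))
  s2 <- simulate_curve_families(curve_family_spec("slight", seed = 82))
  expect_identical(s1$family1$values, s2$family1$values)
  expect_identical(s1$family2$values, s2$family2$values)

  # custom mean functions are honored
  sc <- curve_family_spec("identical", between_curve_var = 0,
                          within_curve_var = 0,
                          f1 = function(w) 0 * w, f2 = function(w) 0 * w + 1,
                          seed = 83)
  fc <- simulate_curve_families(sc)
  expect_equal(unique(as.vector(fc$family2$values - fc$family1$values)), 1)

  expect_error(curve_family_spec(smoothing_window = 4), "odd")
})

test_that("simulators leave the caller's RNG stream untouched when seeded", {
  set.seed(84)
  before <- .Random.seed
  invisible(simulate_ar1(0.5, 100, seed = 1))
  invisible(simulate_curve_families(curve_family_spec(seed = 2)))
  expect_identical(.Random.seed, before)
})
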