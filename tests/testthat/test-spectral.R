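test_that("periodogram matches the closed-form DFT of a pure cosine", {
  T <- 64
  A <- 2
  k0 <- 5
  x <- A * cos(2 * pi * k0 * (0:(T - 1)) / T)
  pg <- periodogram(x, fs = T)
  expect_equal(pg$power[k0 + 1], A^2 * T / 4, tolerance = 1e-10)
  expect_lt(max(pg$power[-(k0 + 1)]), 1e-8)
  expect_equal(pg$freq[k0 + 1], k0)
})

test_that("periodogram satisfies Parseval's identity and handles degenerate input", {
  set.seed(11)
  for (T in c(64, 257, 1000)) {
    x <- rnorm(T)
    pg <- periodogram(x)
    xd <- x - mean(x)
    # rebuild the full two-sided grid by even symmetry
    K <- length(pg$power)
    expect_equal(K, T %/% 2 + 1)
    interior <- if (T %% 2 == 0) pg$power[2:(K - 1)] else pg$power[2:K]
    full <- c(pg$power, rev(interior))
    expect_equal(length(full), T)
    expect_equal(sum(full) / T, mean(xd^2), tolerance = 1e-8)
  }
  expect_warning(pg0 <- periodogram(rep(3.7, 32)), "constant")
  expect_true(all(pg0$power == 0))
  expect_true(pg0$constant)
  expect_error(periodogram(rnorm(5)), "at least 8")
})

test_that("band power integrates correctly and bands partition the axis", {
  set.seed(12)
  pg <- periodogram(rnorm(1000), fs = 1000)
  total <- band_power(pg, c(0, 500))
  expect_equal(total, sum(pg$power) * pg$fs / pg$T)
  expect_equal(band_power(pg, c(0, 123.4)) + band_power(pg, c(123.4, 500)),
               total)
  # the five conventional bands never double-count shared edges
  bp <- vapply(eeg_bands(), function(b) band_power(pg, b), numeric(1))
  expect_equal(sum(bp), band_power(pg, c(0, 50)))
  expect_error(band_power(pg, c(100, 600)), "outside")
  expect_error(band_power(pg, c(200.1, 200.9)), "no frequency bins")
})

test_that("alpha-band AR(2) epochs put most power in the alpha band", {
  hits <- 0
  for (s in 1:200) {
    x <- simulate_ar2_band("alpha", fs = 1000, n_samples = 4000, seed = s)
    pg <- periodogram(x, fs = 1000)
    bp <- vapply(eeg_bands(), function(b) band_power(pg, b), numeric(1))
    hits <- hits + (names(which.max(bp)) == "alpha")
  }
  expect_gte(hits / 200, 0.95)
})

test_that("boxcar smoothing follows the even-reflection rule", {
  pg <- fake_periodogram(c(1, 2, 3, 4))
  # hand computation under I(w_-k) = I(w_k), I(w_{T/2+j}) = I(w_{T/2-j}):
  # (2+1+2)/3, (1+2+3)/3, (2+3+4)/3, (3+4+3)/3
  expect_equal(boxcar_smooth(pg, 1)$power, c(5 / 3, 2, 3, 10 / 3))
  expect_equal(boxcar_smooth(pg, 0)$power, pg$power)
  cst <- fake_periodogram(rep(2.5, 9))
  for (p in 0:4) {
    expect_equal(boxcar_smooth(cst, p)$power, rep(2.5, 9))
  }
  w <- boxcar_smooth(pg, 1)$weights
  expect_equal(sum(w), 1)
  expect_equal(w, rev(w))
  expect_error(boxcar_smooth(pg, 3), "span halfwidth")
})

test_that("smoothing preserves nonnegativity and near-preserves total mass", {
  set.seed(13)
  pg <- periodogram(rnorm(512), fs = 1)
  for (p in c(1, 5, 20)) {
    sm <- boxcar_smooth(pg, p)
    expect_true(all(sm$power >= 0))
    expect_lt(abs(sum(sm$power) - sum(pg$power)),
              2 * p * max(pg$power))
  }
})

test_that("GCV deviance matches a term-by-term oracle and guards degeneracy", {
  I <- c(2, 1, 3, 5, 4)
  pg <- fake_periodogram(I)
  p <- 1
  # independent term-by-term evaluation of the deviance display
  fhat <- c(mean(I[c(2, 1, 2)]), mean(I[1:3]), mean(I[2:4]), mean(I[3:5]),
            mean(I[c(4, 5, 4)]))
  M <- 5
  q <- c(0.5, 1, 1, 1, 0.5)
  dev <- q * (-log(I / fhat) + (I - fhat) / fhat)
  expected <- sum(dev) / M / (1 - 1 / 3)^2
  expect_equal(gcv_deviance(pg, p), expected, tolerance = 1e-12)

  cst <- fake_periodogram(rep(3, 9))
  expect_equal(gcv_deviance(cst, 2), 0)       # I == fhat: deviance vanishes
  expect_identical(gcv_deviance(cst, 0), Inf) # degenerate denominator
})

test_that("span selection returns the grid minimizer and favors wide spans on flat truth", {
  set.seed(14)
  pg <- periodogram(rnorm(256))
  expect_equal(select_span(pg, p_grid = 3)$p, 3)
  sel <- select_span(pg)
  expect_equal(min(sel$scores), gcv_deviance(pg, sel$p))

  # flat (white-noise) truth should tolerate at least as much smoothing as a
  # sharply peaked AR(2) spectrum: paired comparison of selected spans
  p_white <- p_peak <- integer(100)
  for (s in 1:100) {
    set.seed(s)
    p_white[s] <- select_span(periodogram(rnorm(512), fs = 1000))$p
    xa <- simulate_ar2_band("alpha", fs = 1000, n_samples = 512, seed = s)
    p_peak[s] <- select_span(periodogram(xa, fs = 1000))$p
  }
  expect_gte(median(p_white), median(p_peak))
})

test_that("log bias correction removes the Jensen bias of the log periodogram", {
  expect_equal(log_bias_correct(exp(1))$values, 1.57721)
  set.seed(15)
  draws <- rexp(1e5)
  expect_lt(abs(mean(log(draws)) + 0.57721), 0.01)
  expect_warning(lc <- log_bias_correct(c(0, 1, 2)), "floored")
  expect_true(all(is.finite(lc$values)))
  expect_error(log_bias_correct(c(0, 0)), "all ordinates are zero")
  expect_error(log_bias_correct(c(-1, 2)), "nonnegative")
})

test_that("log periodogram variance is near pi^2/6 for white noise", {
  set.seed(16)
  v <- replicate(20, {
    pg <- periodogram(rnorm(4096))
    var(log(pg$power[2:2048]))
  })
  expect_lt(abs(mean(v) - pi^2 / 6) / (pi^2 / 6), 0.05)
})

test_that("line-noise repair flattens the spike and touches only its window", {
  pg <- fake_periodogram(rep(1, 129), fs = 256)  # T = 256, bins 1 Hz apart
  spike <- which(pg$freq == 60)
  pg$power[spike] <- 100
  rp <- repair_line_noise(pg, 60)
  expect_equal(rp$power[spike], 1)
  untouched <- setdiff(seq_along(pg$power), rp$repaired_bins)
  expect_equal(rp$power[untouched], pg$power[untouched])
  expect_length(rp$repaired_bins, 3)
  expect_error(repair_line_noise(pg, 200), "inside")
})

test_that("smoothed log spectra converge to the true AR(1) log spectrum", {
  ise <- function(T, seed) {
    x <- simulate_ar1(0.5, T, seed = seed)
    sel <- select_span(periodogram(x))
    est <- log_bias_correct(sel$spectrum)$values
    truth <- log(ar_spectrum(0.5, sel$spectrum$freq))
    interior <- 2:(length(est) - 1)
    mean((est[interior] - truth[interior])^2)
  }
  short <- vapply(1:50, function(s) ise(256, s), numeric(1))
  long <- vapply(1:50, function(s) ise(4096, 1000 + s), numeric(1))
  expect_lt(mean(long), mean(short))
})

test_that("spectral_curves builds one finite log curve per epoch in both modes", {
  set.seed(17)
  ef <- epoch_family(matrix(rnorm(12 * 128), 12, 128), fs = 128)
  for (mode in c("smooth-then-log", "log-then-smooth")) {
    cf <- spectral_curves(ef, log_mode = mode)
    expect_s3_class(cf, "curve_family")
    expect_equal(dim(cf$values), c(12, 65))
    expect_true(all(is.finite(cf$values)))
    expect_length(attr(cf, "spans"), 12)
    expect_true(all(attr(cf, "spans") >= 1))
  }
  cf3 <- spectral_curves(ef, span = 3)
  expect_true(all(attr(cf3, "spans") == 3))
})
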