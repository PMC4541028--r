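test_that("positions of a family against itself spread over {1/n, ..., 1}", {
  set.seed(2)  # a draw whose leave-out depths are tie-free
  v <- matrix(rnorm(10 * 20), 10, 20)
  R <- rank_positions(v, v)
  expect_setequal(round(sort(R), 10), round((1:10) / 10, 10))
  # with ties the positions are still valid probabilities reaching 1
  expect_true(all(R > 0 & R <= 1))
  expect_equal(max(R), 1)
})

test_that("a curve far outside the reference envelope gets minimal position", {
  set.seed(62)
  ref <- matrix(rnorm(10 * 20), 10, 20)
  far <- matrix(100, 1, 20)
  expect_lte(rank_positions(far, ref), 2 / 10)
})

test_that("rank conservation: the two families' rank sums partition N(N+1)/2", {
  set.seed(63)
  for (i in 1:10) {
    n <- sample(5:15, 1)
    m <- sample(5:15, 1)
    a <- matrix(rnorm(n * 12), n, 12)
    b <- matrix(rnorm(m * 12), m, 12) + runif(1, -2, 2)
    t2 <- rank_sum_test(a, b, method = "normal")$statistic
    t1 <- rank_sum_test(b, a, method = "normal",
                        depth_scope = "reference")$statistic
    # recompute family-1 ranks directly from the same positions
    R1 <- rank_positions(a, a)
    R2 <- rank_positions(b, a)
    rk <- rank(c(R1, R2))
    expect_equal(sum(rk[seq_len(n)]) + sum(rk[n + seq_len(m)]),
                 (n + m) * (n + m + 1) / 2)
    expect_equal(sum(rk[n + seq_len(m)]), t2)
  }
})

test_that("the Monte Carlo null has the closed-form moments of sampling without replacement", {
  n <- 12; m <- 9; N <- n + m
  set.seed(64)
  draws <- replicate(20000, sum(sample.int(N, m)))
  mu <- m * (N + 1) / 2
  s2 <- n * m * (N + 1) / 12
  expect_lt(abs(mean(draws) - mu), 3 * sqrt(s2 / 20000))
  expect_lt(abs(var(draws) - s2) / s2, 0.05)
})

test_that("Monte Carlo, normal and exact p-values agree", {
  set.seed(65)
  a <- matrix(rnorm(50 * 30), 50, 30)
  b <- matrix(rnorm(50 * 30), 50, 30) + 0.4
  p_mc <- rank_sum_test(a, b, method = "montecarlo", n_null_draws = 1e5,
                        seed = 1)$p.value
  p_n <- rank_sum_test(a, b, method = "normal")$p.value
  expect_lt(abs(p_mc - p_n), 0.02)

  sm1 <- matrix(rnorm(6 * 8), 6, 8)
  sm2 <- matrix(rnorm(6 * 8), 6, 8)
  p_ex <- rank_sum_test(sm1, sm2, method = "exact")$p.value
  p_mc2 <- rank_sum_test(sm1, sm2, method = "montecarlo",
                         n_null_draws = 2e4, seed = 2)$p.value
  expect_lt(abs(p_ex - p_mc2), 0.03)
  expect_error(rank_sum_test(a, b, method = "exact"), "n \\+ m <= 12")
})

test_that("identical families are rejected at about the nominal rate", {
  set.seed(66)
  rej <- 0
  for (i in 1:200) {
    a <- matrix(rnorm(15 * 20), 15, 20)
    b <- matrix(rnorm(15 * 20), 15, 20)
    rej <- rej + rank_sum_test(a, b, method = "normal")$reject
  }
  expect_lte(rej / 200, 0.10)  # nominal 0.05 plus binomial slack
  expect_gte(rej, 1)           # and the test is not degenerate
})

test_that("Monte Carlo p-values respect their attainable range and seeding", {
  set.seed(67)
  a <- matrix(rnorm(8 * 10), 8, 10)
  b <- matrix(rnorm(8 * 10), 8, 10) + 50
  r <- rank_sum_test(a, b, method = "montecarlo", n_null_draws = 999,
                     seed = 5)
  expect_gte(r$p.value, 1 / 1000)
  r2 <- rank_sum_test(a, b, method = "montecarlo", n_null_draws = 999,
                      seed = 5)
  expect_identical(r$p.value, r2$p.value)
})

test_that("stationarity screen is calibrated under the null and powered under change", {
  set.seed(68)
  n_chan <- 20
  chans <- lapply(seq_len(n_chan), function(i) {
    t(sapply(1:30, function(j) simulate_ar1(0.5, 128)))
  })
  names(chans) <- paste0("ch", seq_len(n_chan))
  scr <- stationarity_screen(chans, split = list(early = 1:15, late = 16:30),
                             span = 3, method = "normal")
  expect_equal(nrow(scr$results), n_chan)
  expect_equal(scr$bonferroni_alpha, 0.05 / n_chan)
  expect_lte(sum(scr$results$significant), 5)
  expect_equal(sum(scr$results$significant_bonferroni), 0)
  expect_true(all(scr$results$significant_bonferroni <=
                    scr$results$significant))

  # a channel whose late phase changes its AR coefficient survives Bonferroni
  hits <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    chans2 <- lapply(1:8, function(i) {
      early <- t(sapply(1:15, function(j) simulate_ar1(0.2, 128)))
      phi_late <- if (i == 3) 0.9 else 0.2
      late <- t(sapply(1:15, function(j) simulate_ar1(phi_late, 128)))
      rbind(early, late)
    })
    names(chans2) <- paste0("ch", 1:8)
    scr2 <- stationarity_screen(chans2,
                                split = list(early = 1:15, late = 16:30),
                                span = 3, method = "normal")
    hits <- hits + scr2$results$significant_bonferroni[3]
  }
  expect_gte(hits, 9)

  expect_error(
    stationarity_screen(chans, split = list(early = 1:16, late = 16:30)),
    "overlap")
})

test_that("channels with missing epochs are excluded with a warning", {
  set.seed(69)
  chans <- list(a = matrix(rnorm(20 * 64), 20, 64),
                b = matrix(rnorm(20 * 64), 20, 64))
  chans$b[3, 5] <- NA
  expect_warning(
    scr <- stationarity_screen(chans, split = list(early = 1:10, late = 11:20),
                               span = 2, method = "normal"),
    "excluded")
  expect_equal(scr$results$channel, "a")
})

test_that("region averaging is exact for trivial regions and improves SNR", {
  set.seed(70)
  a <- matrix(rnorm(5 * 32), 5, 32)
  out <- region_average(list(c1 = a), c(c1 = "solo"))
  expect_equal(out$solo, a)

  out2 <- region_average(list(c1 = a, c2 = a), c(c1 = "r", c2 = "r"))
  expect_equal(out2$r, a)

  expect_warning(
    region_average(list(c1 = a), data.frame(channel_id = c("c1", "zz"),
                                            region = c("r1", "r2"))),
    "no matching channels")
  expect_error(
    region_average(list(c1 = a), data.frame(channel_id = c("c1", "c1"),
                                            region = c("r1", "r2"))),
    "at most one region")

  # averaging k independent noise channels divides the noise floor by ~k
  k <- 8
  chans <- lapply(1:k, function(i) matrix(rnorm(4 * 256), 4, 256))
  names(chans) <- paste0("c", 1:k)
  avg <- region_average(chans, stats::setNames(rep("all", k), names(chans)))$all
  floor_single <- mean(periodogram(chans[[1]][1, ])$power)
  floor_avg <- mean(periodogram(avg[1, ])$power)
  expect_lt(floor_avg / floor_single, 0.3)
})
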