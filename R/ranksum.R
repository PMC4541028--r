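# Depth-based rank-sum inference for families of curves or surfaces.

#' Depth positions of curves with respect to a reference family
#'
#' Places each query curve on the reference family's depth scale: the
#' position `R(y)` is the fraction of reference curves whose depth is no
#' larger than the query's depth, where all depths are measured with respect
#' to the reference sample. A query identical in distribution to the
#' reference gets positions spread over `{1/k, ..., 1}`; a query far outside
#' the reference envelope gets positions near 0.
#'
#' With the default `depth_scope = "reference"`, the depth of every curve --
#' reference member or query -- is its average coverage by bands delimited by
#' pairs of *other* reference curves (members' own delimiter pairs are
#' excluded), so member and query depths are the same functional and the two
#' samples are exchangeable under the null. The alternative
#' `depth_scope = "pooled"` measures all depths within the pooled
#' query-plus-reference family instead; it is retained for comparison but is
#' not recommended, because pooled depth cannot separate two internally
#' coherent families (see the package vignette).
#'
#' @param x Query curves ([curve_family()], [surface_family()] or matrix).
#' @param reference Reference family on the same grid, at least 3 curves.
#' @param depth_scope `"reference"` (default) or `"pooled"`.
#' @return Numeric vector of positions in `[0, 1]`, one per query curve.
#' @export
rank_positions <- function(x, reference,
                           depth_scope = c("reference", "pooled")) {
  depth_scope <- match.arg(depth_scope)
  q <- as_value_matrix(x)
  ref <- as_value_matrix(reference)
  if (ncol(q) != ncol(ref)) {
    stop("query and reference families must share the grid")
  }
  if (depth_scope == "reference") {
    dref <- member_depth_loo(ref)
    dq <- if (identical(dim(q), dim(ref)) && all(q == ref)) {
      dref
    } else {
      depth_wrt(q, ref)
    }
  } else {
    pooled <- rbind(ref, q)
    d <- modified_band_depth(pooled)$depths
    dref <- d[seq_len(nrow(ref))]
    dq <- d[nrow(ref) + seq_len(nrow(q))]
  }
  vapply(dq, function(t) mean(dref <= t), numeric(1))
}

#' Depth-based rank-sum test for equality of median curves
#'
#' Tests whether two families of curves (or surfaces) share a common median
#' function. Both families' curves are placed on a common depth scale via
#' [rank_positions()] against the reference sample (the first family by
#' default); the pooled positions are ranked 1..n+m with midranks for ties,
#' and the statistic `T` is the sum of the second family's ranks. Under the
#' null of equal medians the families are exchangeable, so `T` is
#' distributed as the sum of `m` ranks drawn without replacement from
#' `1, ..., n+m`, with mean `m(n+m+1)/2` and variance `nm(n+m+1)/12`. A
#' family whose curves sit systematically outside the reference envelope
#' collects extreme ranks and drives `T` away from its null mean.
#'
#' The two-sided p-value is evaluated by Monte Carlo draws from the null
#' (default, `n_null_draws` draws with the add-one correction, so the
#' attainable minimum is `1/(n_null_draws+1)`), by a normal approximation
#' (accurate for `n, m >= 5`... and essentially exact by `n = m = 50`), or
#' by exhaustive enumeration (`method = "exact"`, feasible for
#' `n + m <= 12`).
#'
#' @param x,y The two families ([curve_family()], [surface_family()] or
#'   matrices on a common grid). `x` is the reference sample by default.
#' @param alpha Significance level recorded (and used for the `reject` flag).
#' @param method `"montecarlo"`, `"normal"`, or `"exact"`.
#' @param n_null_draws Monte Carlo draws for `method = "montecarlo"`.
#' @param seed Optional seed for the Monte Carlo null; the caller's RNG
#'   stream is left untouched when a seed is given.
#' @param depth_scope Passed to [rank_positions()].
#' @return Object of class `rank_sum_test`: `statistic` (T), `n`, `m`,
#'   `p.value`, `reject`, `alpha`, `method`, `n_null_draws`, `seed`,
#'   `null_mean`, `null_var`, `positions` (list with one vector per family).
#' @export
#' @examples
#' a <- matrix(rnorm(20 * 30), 20, 30)
#' b <- matrix(rnorm(20 * 30), 20, 30) + 3
#' rank_sum_test(a, b, method = "normal")
rank_sum_test <- function(x, y, alpha = 0.05,
                          method = c("montecarlo", "normal", "exact"),
                          n_null_draws = 10000, seed = NULL,
                          depth_scope = c("reference", "pooled")) {
  method <- match.arg(method)
  depth_scope <- match.arg(depth_scope)
  vx <- as_value_matrix(x)
  vy <- as_value_matrix(y)
  n <- nrow(vx)
  m <- nrow(vy)
  if (n == 0L || m == 0L) {
    stop("both families must be nonempty")
  }
  if (method == "normal" && (n < 5L || m < 5L)) {
    stop("normal approximation needs at least 5 curves per family")
  }
  R1 <- rank_positions(vx, vx, depth_scope = depth_scope)
  R2 <- rank_positions(vy, vx, depth_scope = depth_scope)
  rk <- rank(c(R1, R2))  # midranks for ties
  T_stat <- sum(rk[n + seq_len(m)])
  N <- n + m
  mu <- m * (N + 1) / 2
  s2 <- n * m * (N + 1) / 12

  p <- switch(
    method,
    montecarlo = with_seed(seed, {
      draws <- vapply(seq_len(n_null_draws),
                      function(i) sum(sample.int(N, m)), numeric(1))
      p_le <- (1 + sum(draws <= T_stat)) / (n_null_draws + 1)
      p_ge <- (1 + sum(draws >= T_stat)) / (n_null_draws + 1)
      min(1, 2 * min(p_le, p_ge))
    }),
    normal = 2 * stats::pnorm(-abs((T_stat - mu) / sqrt(s2))),
    exact = {
      if (N > 12L) {
        stop("exact enumeration is limited to n + m <= 12")
      }
      sums <- utils::combn(N, m, sum)
      min(1, 2 * min(mean(sums <= T_stat), mean(sums >= T_stat)))
    }
  )

  structure(
    list(statistic = T_stat, n = n, m = m, p.value = p,
         reject = p < alpha, alpha = alpha, method = method,
         n_null_draws = if (method == "montecarlo") n_null_draws else NA_integer_,
         seed = seed, null_mean = mu, null_var = s2,
         positions = list(R1, R2), depth_scope = depth_scope),
    class = "rank_sum_test"
  )
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat("\n\tDepth-based rank-sum test for equality of median curves\n\n")
  cat(sprintf("T = %g (null mean %g, sd %.3f), n = %d, m = %d\n",
              x$statistic, x$null_mean, sqrt(x$null_var), x$n, x$m))
  cat(sprintf("p-value = %.4g  [%s%s]\n", x$p.value, x$method,
              if (x$method == "montecarlo") {
                sprintf(", %d null draws", x$n_null_draws)
              } else {
                ""
              }))
  cat(sprintf("H0 %s at alpha = %g\n\n",
              if (x$reject) "rejected" else "not rejected", x$alpha))
  invisible(x)
}

#' Size/power study of the rank-sum test on simulated curve families
#'
#' Repeatedly simulates two families from the two-family curve model of
#' [simulate_curve_families()] and records the rejection rate of
#' [rank_sum_test()] at level `alpha`. With `case = "identical"` this
#' measures the empirical size of the test; the deviation cases measure
#' power. The replicate loop draws from one seeded stream, so the study is
#' reproducible as a whole.
#'
#' @param case Mean-function scenario passed to [curve_family_spec()]:
#'   `"identical"`, `"slight"` or `"appreciable"`.
#' @param n_rep Number of replicates.
#' @param alpha Significance level.
#' @param spec A [curve_family_spec()]; its `seed` is ignored in favor of
#'   `seed` below.
#' @param method Null evaluation method for [rank_sum_test()]; the normal
#'   approximation is the default here since at 50 curves per family it
#'   agrees with Monte Carlo to well under the binomial noise of the study.
#' @param seed Seed for the whole study.
#' @return List of class `power_study`: `reject_rate`, `p_values`, `case`,
#'   `n_rep`, `alpha`, `method`.
#' @export
rank_sum_power <- function(case = c("identical", "slight", "appreciable"),
                           n_rep = 1000, alpha = 0.05,
                           spec = curve_family_spec(case = case),
                           method = "normal", seed = NULL) {
  case <- match.arg(case)
  spec$case <- case
  spec$seed <- NULL
  p_values <- with_seed(seed, {
    vapply(seq_len(n_rep), function(r) {
      fams <- simulate_curve_families(spec)
      rank_sum_test(fams$family1, fams$family2, alpha = alpha,
                    method = method)$p.value
    }, numeric(1))
  })
  structure(
    list(reject_rate = mean(p_values < alpha), p_values = p_values,
         case = case, n_rep = n_rep, alpha = alpha, method = method),
    class = "power_study"
  )
}

#' @export
print.power_study <- function(x, ...) {
  cat(sprintf("<power_study> case = %s: rejection rate %.1f%% (%d/%d at alpha = %g)\n",
              x$case, 100 * x$reject_rate, sum(x$p_values < x$alpha),
              x$n_rep, x$alpha))
  invisible(x)
}

#' Per-channel stationarity screen between two recording phases
#'
#' For every channel, builds the log bias-corrected spectral curve families
#' of an early and a late phase (via [spectral_curves()]) and tests equality
#' of their median curves with [rank_sum_test()]. A rejected channel
#' indicates that the spectral content of the signal evolved between the
#' phases, i.e. non-stationarity across the recording. Because the same test
#' is repeated over channels, Bonferroni-corrected calls (level
#' `alpha / n_channels`) are reported alongside the raw ones.
#'
#' @param epochs_by_channel Named list of epoch matrices or [epoch_family()]
#'   objects (identical epoch structure). Channels containing missing values
#'   are excluded with a warning.
#' @param split List with integer vectors `early` and `late` (epoch indices);
#'   default first and last `min(60, floor(n/2))` epochs. The two ranges must
#'   not overlap.
#' @param alpha Significance level.
#' @param fs Sampling rate in Hz.
#' @param span,log_mode,line_hz,p_grid Passed to [spectral_curves()].
#' @param method,n_null_draws,seed Passed to [rank_sum_test()]; channel tests
#'   draw their Monte Carlo nulls from one seeded stream.
#' @return Object of class `channel_screen`: a data frame `results` with
#'   columns `channel`, `p_value`, `significant`,
#'   `significant_bonferroni`, plus `alpha` and `bonferroni_alpha`.
#' @export
stationarity_screen <- function(epochs_by_channel, split = NULL,
                                alpha = 0.05, fs = 1,
                                span = "gcv",
                                log_mode = "smooth-then-log",
                                line_hz = NULL, p_grid = NULL,
                                method = "normal", n_null_draws = 10000,
                                seed = NULL) {
  mats <- lapply(epochs_by_channel, function(e) {
    if (inherits(e, "epoch_family")) {
      if (fs == 1 && e$fs != 1) fs <<- e$fs
      e$x
    } else {
      as.matrix(e)
    }
  })
  if (is.null(names(mats))) {
    names(mats) <- paste0("ch", seq_along(mats))
  }
  n_ep <- nrow(mats[[1]])
  if (is.null(split)) {
    half <- min(60L, n_ep %/% 2L)
    split <- list(early = seq_len(half), late = (n_ep - half + 1L):n_ep)
  }
  if (length(intersect(split$early, split$late)) > 0L) {
    stop("early and late epoch ranges overlap")
  }
  if (length(split$early) == 0L || length(split$late) == 0L ||
      max(c(split$early, split$late)) > n_ep) {
    stop("both phases must be nonempty epoch ranges within the recording")
  }
  keep <- !vapply(mats, anyNA, logical(1))
  if (any(!keep)) {
    warning("channels with missing epochs excluded: ",
            paste(names(mats)[!keep], collapse = ", "))
    mats <- mats[keep]
  }
  if (length(mats) == 0L) {
    stop("no usable channels")
  }
  p <- with_seed(seed, vapply(mats, function(m) {
    early <- spectral_curves(m[split$early, , drop = FALSE], fs = fs,
                             span = span, log_mode = log_mode,
                             line_hz = line_hz, p_grid = p_grid)
    late <- spectral_curves(m[split$late, , drop = FALSE], fs = fs,
                            span = span, log_mode = log_mode,
                            line_hz = line_hz, p_grid = p_grid)
    rank_sum_test(early, late, alpha = alpha, method = method,
                  n_null_draws = n_null_draws)$p.value
  }, numeric(1)))
  bonf <- alpha / length(p)
  structure(
    list(results = data.frame(channel = names(p), p_value = unname(p),
                              significant = unname(p < alpha),
                              significant_bonferroni = unname(p < bonf),
                              row.names = NULL),
         alpha = alpha, bonferroni_alpha = bonf, split = split),
    class = "channel_screen"
  )
}

#' @export
print.channel_screen <- function(x, ...) {
  r <- x$results
  cat(sprintf("<channel_screen> %d channels, alpha = %g (Bonferroni %g)\n",
              nrow(r), x$alpha, x$bonferroni_alpha))
  cat(sprintf(" significant: %d raw, %d after Bonferroni\n",
              sum(r$significant), sum(r$significant_bonferroni)))
  if (any(r$significant)) {
    cat(" raw-significant channels:",
        paste(r$channel[r$significant], collapse = ", "), "\n")
  }
  invisible(x)
}
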