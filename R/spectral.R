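#' Periodogram of a single epoch
#'
#' Computes the raw periodogram `I(w_k) = |sum_t X(t) exp(-i 2 pi w_k t)|^2 / T`
#' of a zero-mean stationary epoch at the Fourier frequencies
#' `w_k = k/T`, reported on the one-sided grid `k = 0, ..., floor(T/2)`.
#' The epoch is mean-detrended first (unless `demean = FALSE`). The raw
#' periodogram is approximately unbiased for the spectrum but inconsistent --
#' its variance does not shrink with `T` -- which is why it is smoothed
#' downstream by [boxcar_smooth()] with a span chosen by [select_span()].
#'
#' The full two-sided periodogram satisfies Parseval's identity: the average
#' of `I` over all `T` Fourier frequencies (reconstructed by even symmetry
#' `I(w_-k) = I(w_k)`) equals the mean square of the demeaned epoch.
#'
#' @param x Numeric epoch of length `T >= 8`.
#' @param fs Sampling rate in Hz.
#' @param demean Subtract the epoch mean before transforming.
#' @return An object of class `periodogram` with fields `power` (ordinates,
#'   length `floor(T/2) + 1`), `freq` (Hz), `T`, `fs`, and a `constant` flag
#'   set when the epoch was constant (all-zero ordinates, with a warning).
#' @export
#' @examples
#' pg <- periodogram(rnorm(256), fs = 256)
#' plot(pg)
periodogram <- function(x, fs = 1, demean = TRUE) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8L) {
    stop("epoch too short: need at least 8 samples")
  }
  if (anyNA(x)) {
    stop("epoch contains missing values")
  }
  if (demean) {
    x <- x - mean(x)
  }
  constant <- all(x == 0)
  if (constant) {
    warning("constant epoch: periodogram is identically zero")
  }
  K <- n %/% 2L + 1L
  power <- Mod(stats::fft(x))^2 / n
  power <- power[seq_len(K)]
  # clip tiny negative rounding from Mod()^2 (cannot occur mathematically)
  power[power < 0] <- 0
  structure(
    list(power = power, freq = (seq_len(K) - 1) * fs / n,
         T = n, fs = fs, constant = constant),
    class = "periodogram"
  )
}

#' @export
print.periodogram <- function(x, ...) {
  cat(sprintf("<periodogram> T = %d, fs = %g Hz, %d ordinates on [0, %g] Hz\n",
              x$T, x$fs, length(x$power), max(x$freq)))
  invisible(x)
}

#' @export
plot.periodogram <- function(x, log = "", ...) {
  graphics::plot(x$freq, x$power, type = "l", log = log,
                 xlab = "frequency (Hz)", ylab = "power", ...)
  invisible(x)
}

#' Spectral power in a frequency band
#'
#' Integrates the (one-sided) periodogram over a named band by a left Riemann
#' sum with bin width `fs/T`: ordinates whose center frequency falls in
#' `[lo, hi)` are summed and scaled. A band whose upper edge reaches the
#' Nyquist frequency is closed there, so a single band spanning
#' `[0, fs/2]` recovers the total one-sided sum.
#'
#' @param pg A [periodogram()] or smoothed spectrum.
#' @param band A [band_def()], a band name from [eeg_bands()], or `c(lo, hi)`
#'   in Hz.
#' @return Nonnegative band power.
#' @export
#' @examples
#' pg <- periodogram(rnorm(1000), fs = 1000)
#' band_power(pg, "alpha")
band_power <- function(pg, band) {
  band <- as_band(band)
  nyq <- pg$fs / 2
  if (band$lo_hz < 0 || band$hi_hz > nyq) {
    stop(sprintf("band [%g, %g) outside [0, %g] Hz", band$lo_hz, band$hi_hz, nyq))
  }
  sel <- pg$freq >= band$lo_hz &
    (pg$freq < band$hi_hz | (band$hi_hz >= nyq & pg$freq <= band$hi_hz))
  if (!any(sel)) {
    stop(sprintf("band [%g, %g) contains no frequency bins (bin width %g Hz)",
                 band$lo_hz, band$hi_hz, pg$fs / pg$T))
  }
  sum(pg$power[sel]) * pg$fs / pg$T
}

# Even-reflection padding of a one-sided spectral vector about DC and Nyquist:
# I(w_-k) = I(w_k) and I(w_{T/2+j}) = I(w_{T/2-j}). This is the true symmetry
# of the DFT periodogram, so the padded vector is what a longer two-sided
# grid would actually contain.
reflect_pad <- function(v, p) {
  K <- length(v)
  if (p == 0L) {
    return(v)
  }
  if (p > K - 1L) {
    stop("reflection span exceeds spectrum length")
  }
  c(v[(p + 1L):2L], v, v[(K - 1L):(K - p)])
}

# Boxcar moving average of a plain vector under even reflection; kernel of
# the smoothing used for both raw periodograms and log-scale curves.
boxcar_vec <- function(v, p) {
  if (p == 0L) {
    return(v)
  }
  K <- length(v)
  ext <- reflect_pad(v, p)
  cs <- cumsum(c(0, ext))
  (cs[(2L * p + 1L) + seq_len(K)] - cs[seq_len(K)]) / (2 * p + 1)
}

#' Boxcar smoothing of a periodogram
#'
#' Replaces each ordinate by the equal-weight mean of its `2p + 1` neighbors,
#' `W_{p,j} = 1/(2p+1)` for `j = -p, ..., p`. Indices falling outside the
#' one-sided grid are filled by even reflection (`I(w_-k) = I(w_k)` at DC,
#' `I(w_{T/2+j}) = I(w_{T/2-j})` at Nyquist), the symmetry the two-sided
#' periodogram actually possesses.
#'
#' @param pg A [periodogram()].
#' @param p Span halfwidth, `0 <= p <= floor(T/4)`; `p = 0` is the identity.
#' @return An object of class `smoothed_spectrum` with fields `power`, `freq`,
#'   `T`, `fs`, `p`, `weights`.
#' @seealso [select_span()] for automatic choice of `p`.
#' @export
boxcar_smooth <- function(pg, p) {
  p <- as.integer(p)
  if (length(p) != 1L || is.na(p) || p < 0L || p > pg$T %/% 4L) {
    stop(sprintf("span halfwidth p must be an integer in [0, %d]", pg$T %/% 4L))
  }
  structure(
    list(power = boxcar_vec(pg$power, p), freq = pg$freq,
         T = pg$T, fs = pg$fs, p = p,
         weights = rep(1 / (2 * p + 1), 2L * p + 1L)),
    class = c("smoothed_spectrum", "periodogram")
  )
}

#' Gamma generalized cross-validated deviance of a smoothing span
#'
#' Scores a candidate boxcar span halfwidth `p` by the generalized
#' cross-validated gamma deviance between the raw periodogram and its
#' smoothed version,
#' \deqn{GCV(p) = \frac{M^{-1} \sum_j q_j \{-\log(I_j/\hat f_j) +
#'   (I_j - \hat f_j)/\hat f_j\}}{(1 - W_{p,0})^2},}
#' with `M = floor(T/2) + 1` ordinates, half weight `q_j = 1/2` at the DC and
#' Nyquist bins (whose periodogram is chi-squared on one degree of freedom
#' rather than two), and center weight `W_{p,0} = 1/(2p+1)` standing in for
#' `tr(H_p)/M` of the boxcar smoother matrix. Zero ordinates contribute only
#' their `(I - f)/f` part (the gamma deviance's `0 log 0` convention); a zero
#' smoothed value, or `p = 0` (degenerate denominator), yields `+Inf` so such
#' spans are never selected.
#'
#' @param pg A [periodogram()].
#' @param p Candidate span halfwidth.
#' @return The deviance score (possibly `Inf`).
#' @export
gcv_deviance <- function(pg, p) {
  p <- as.integer(p)
  if (p == 0L) {
    return(Inf)
  }
  f <- boxcar_smooth(pg, p)$power
  if (any(f == 0)) {
    return(Inf)
  }
  I <- pg$power
  logterm <- ifelse(I > 0, -log(I / f), 0)
  dev <- logterm + (I - f) / f
  M <- length(I)
  q <- rep(1, M)
  q[c(1L, M)] <- 0.5
  w0 <- 1 / (2 * p + 1)
  sum(q * dev) / M / (1 - w0)^2
}

#' Automatic span selection by gamma generalized cross-validation
#'
#' Evaluates [gcv_deviance()] over a grid of candidate span halfwidths and
#' returns the minimizer (the smallest `p` on ties) together with the
#' correspondingly smoothed spectrum. Sharply peaked spectra favor small
#' spans, which preserve peaks; flat (white-noise-like) spectra favor larger
#' spans.
#'
#' @param pg A [periodogram()].
#' @param p_grid Candidate halfwidths; default `1:min(30, floor(T/4))`, which
#'   keeps the smoother well inside the half-spectrum.
#' @return List of class `span_selection`: `p` (selected halfwidth),
#'   `spectrum` (the [boxcar_smooth()] at `p`), `p_grid`, `scores`.
#' @export
select_span <- function(pg, p_grid = NULL) {
  if (is.null(p_grid)) {
    pmax_ <- min(30L, pg$T %/% 4L)
    if (pmax_ < 1L) {
      stop("epoch too short for span selection")
    }
    p_grid <- seq_len(pmax_)
  }
  if (length(p_grid) == 0L) {
    stop("p_grid must be nonempty")
  }
  scores <- vapply(p_grid, function(p) gcv_deviance(pg, p), numeric(1))
  if (all(is.infinite(scores))) {
    stop("all candidate spans have infinite GCV deviance")
  }
  best <- min(p_grid[scores == min(scores)])
  structure(
    list(p = best, spectrum = boxcar_smooth(pg, best),
         p_grid = p_grid, scores = scores),
    class = "span_selection"
  )
}

#' @export
print.span_selection <- function(x, ...) {
  cat(sprintf("<span_selection> p = %d (span %d) over grid [%d, %d], GCV = %.4g\n",
              x$p, 2L * x$p + 1L, min(x$p_grid), max(x$p_grid),
              min(x$scores)))
  invisible(x)
}

#' Log bias-corrected spectral curve
#'
#' Takes the natural log of (smoothed) periodogram ordinates and adds the
#' Euler-Mascheroni constant 0.57721. Because the periodogram at interior
#' frequencies is asymptotically a unit-mean exponential multiple of the
#' spectrum, `E log I = log f - gamma`; adding gamma removes this Jensen bias
#' so the corrected curve estimates the log spectrum. On the log scale the
#' sampling variance is constant (`pi^2/6` per unsmoothed interior ordinate),
#' which standardizes comparisons of curves across epochs and phases.
#'
#' Zero ordinates are mapped to a configurable positive floor (the smallest
#' positive ordinate times `floor_frac`) with a warning; an all-zero input is
#' an error.
#'
#' @param x A [periodogram()], smoothed spectrum, or nonnegative numeric
#'   vector.
#' @param floor_frac Fraction of the smallest positive ordinate used as the
#'   zero floor.
#' @param epoch_id Optional epoch label carried in the result.
#' @return Object of class `log_spectral_curve` with fields `values`, `freq`,
#'   `epoch_id`.
#' @export
#' @examples
#' log_bias_correct(exp(1))$values  # 1 + 0.57721
log_bias_correct <- function(x, floor_frac = 1e-6, epoch_id = NULL) {
  if (inherits(x, "periodogram")) {
    v <- x$power
    freq <- x$freq
  } else {
    v <- as.numeric(x)
    freq <- NULL
  }
  if (any(v < 0)) {
    stop("spectral ordinates must be nonnegative")
  }
  if (all(v == 0)) {
    stop("all ordinates are zero: log spectrum undefined")
  }
  if (any(v == 0)) {
    warning("zero ordinates floored before taking the log")
    v[v == 0] <- min(v[v > 0]) * floor_frac
  }
  structure(
    list(values = log(v) + EULER_GAMMA, freq = freq, epoch_id = epoch_id),
    class = "log_spectral_curve"
  )
}

#' Repair power-line contamination in a periodogram
#'
#' Replaces the ordinates in a one-bin neighborhood of the line frequency
#' (60 Hz mains by default) by the mean of the nearest untouched neighbor on
#' each side, removing the narrowband spike that line noise superimposes on
#' the spectrum while leaving all other bins unchanged.
#'
#' @param pg A [periodogram()].
#' @param line_hz Line frequency in Hz; must lie below Nyquist.
#' @return The repaired periodogram; the replaced bin indices are recorded in
#'   field `repaired_bins`.
#' @export
repair_line_noise <- function(pg, line_hz = 60) {
  if (line_hz <= 0 || line_hz >= pg$fs / 2) {
    stop("line frequency must lie strictly inside (0, fs/2)")
  }
  K <- length(pg$power)
  k0 <- round(line_hz * pg$T / pg$fs) + 1L
  win <- intersect((k0 - 1L):(k0 + 1L), seq_len(K))
  nb <- c(min(win) - 1L, max(win) + 1L)
  nb <- nb[nb >= 1L & nb <= K]
  if (length(nb) == 0L) {
    stop("no untouched neighbor bins available for line-noise repair")
  }
  pg$power[win] <- mean(pg$power[nb])
  pg$repaired_bins <- win
  pg
}

#' Per-epoch log spectral curves for a family of epochs
#'
#' The spectral stage of the pipeline: for every epoch, compute the
#' periodogram, optionally repair line noise, select the boxcar span by
#' gamma generalized cross-validation (or use a fixed span), and return the
#' family of log bias-corrected spectral curves on the shared frequency grid.
#'
#' Two orderings of smoothing and log transformation are available. The
#' default `"smooth-then-log"` selects the span by the gamma deviance on the
#' raw periodogram -- the scale on which the gamma sampling distribution
#' underlying the criterion holds -- smooths the raw ordinates, and takes the
#' bias-corrected log of the result. The alternative `"log-then-smooth"`
#' applies the same selected span as a boxcar on the log bias-corrected raw
#' curve instead.
#'
#' @param epochs An [epoch_family()] or numeric epoch matrix.
#' @param fs Sampling rate (taken from the `epoch_family` when available).
#' @param span `"gcv"` for automatic selection per epoch, or a fixed integer
#'   halfwidth.
#' @param log_mode `"smooth-then-log"` (default) or `"log-then-smooth"`.
#' @param line_hz Optional line frequency to repair (e.g. 60); `NULL` skips.
#' @param p_grid Optional candidate span grid passed to [select_span()].
#' @return A [curve_family()] of log spectral curves (rows = epochs) with the
#'   per-epoch selected spans in attribute `spans` and the epoch grouping (if
#'   any) preserved in attribute `group`.
#' @export
spectral_curves <- function(epochs, fs = NULL,
                            span = "gcv",
                            log_mode = c("smooth-then-log", "log-then-smooth"),
                            line_hz = NULL, p_grid = NULL) {
  log_mode <- match.arg(log_mode)
  if (inherits(epochs, "epoch_family")) {
    x <- epochs$x
    if (is.null(fs)) {
      fs <- epochs$fs
    }
    group <- epochs$group
  } else {
    x <- as.matrix(epochs)
    if (is.null(fs)) {
      fs <- 1
    }
    group <- NULL
  }
  n <- nrow(x)
  K <- ncol(x) %/% 2L + 1L
  values <- matrix(NA_real_, n, K)
  spans <- integer(n)
  freq <- NULL
  for (r in seq_len(n)) {
    pg <- periodogram(x[r, ], fs = fs)
    if (!is.null(line_hz)) {
      pg <- repair_line_noise(pg, line_hz)
    }
    if (identical(span, "gcv")) {
      sel <- select_span(pg, p_grid)
      p <- sel$p
    } else {
      p <- as.integer(span)
    }
    spans[r] <- p
    if (log_mode == "smooth-then-log") {
      values[r, ] <- log_bias_correct(boxcar_smooth(pg, p))$values
    } else {
      # the DC ordinate of a demeaned epoch is exactly zero, so the raw-log
      # path floors it on every epoch; silence that expected warning here
      values[r, ] <- boxcar_vec(suppressWarnings(log_bias_correct(pg))$values,
                                p)
    }
    freq <- pg$freq
  }
  fam <- curve_family(values, arg = freq,
                      ids = rownames(x) %||% seq_len(n))
  attr(fam, "spans") <- spans
  attr(fam, "group") <- group
  attr(fam, "log_mode") <- log_mode
  fam
}

`%||%` <- function(a, b) if (is.null(a)) b else a
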