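#' Define a named frequency band
#'
#' A band is a half-open frequency interval `[lo_hz, hi_hz)` on the one-sided
#' spectral axis. Adjacent bands defined this way never double-count a
#' frequency bin; a band whose upper edge reaches the Nyquist frequency is
#' closed there so that a single band can cover the whole axis.
#'
#' @param name Band label, e.g. `"alpha"`.
#' @param lo_hz,hi_hz Band edges in Hz, `0 <= lo_hz < hi_hz`.
#' @return An object of class `band_def`.
#' @seealso [eeg_bands()] for the conventional EEG rhythm bands,
#'   [band_power()] to integrate a periodogram over a band.
#' @export
#' @examples
#' band_def("alpha", 8, 16)
band_def <- function(name, lo_hz, hi_hz) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(lo_hz) || !is.numeric(hi_hz) || lo_hz < 0 || lo_hz >= hi_hz) {
    stop("band edges must satisfy 0 <= lo_hz < hi_hz")
  }
  structure(list(name = name, lo_hz = lo_hz, hi_hz = hi_hz),
            class = "band_def")
}

#' Conventional EEG rhythm bands
#'
#' The five classical EEG frequency bands: delta (0--4 Hz), theta (4--8 Hz),
#' alpha (8--16 Hz), beta (16--32 Hz) and gamma (32--50 Hz). Band limits vary
#' across the EEG literature (alpha in particular is sometimes taken as
#' 8--12 Hz); these defaults can be overridden by constructing bands with
#' [band_def()].
#'
#' @return Named list of `band_def` objects.
#' @export
#' @examples
#' names(eeg_bands())
eeg_bands <- function() {
  list(
    delta = band_def("delta", 0, 4),
    theta = band_def("theta", 4, 8),
    alpha = band_def("alpha", 8, 16),
    beta  = band_def("beta", 16, 32),
    gamma = band_def("gamma", 32, 50)
  )
}

#' @export
print.band_def <- function(x, ...) {
  cat(sprintf("<band> %s: [%g, %g) Hz\n", x$name, x$lo_hz, x$hi_hz))
  invisible(x)
}

# Coerce a band given as band_def, c(lo, hi) or a name from eeg_bands().
as_band <- function(band) {
  if (inherits(band, "band_def")) {
    return(band)
  }
  if (is.character(band) && length(band) == 1L) {
    bands <- eeg_bands()
    if (!band %in% names(bands)) {
      stop("unknown band name: ", band)
    }
    return(bands[[band]])
  }
  if (is.numeric(band) && length(band) == 2L) {
    return(band_def("band", band[1], band[2]))
  }
  stop("band must be a band_def, a band name, or c(lo_hz, hi_hz)")
}
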