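#' Band-power scalp surfaces from multichannel epochs
#'
#' For each epoch, computes the spectral power of every channel in a given
#' frequency band (via [periodogram()] and [band_power()]) and assembles the
#' per-channel values into one scalp surface over the channel site set. The
#' result is a [surface_family()] with one surface per epoch, ready for
#' depth ordering and [surface_boxplot()]. Surfaces are kept on the finite
#' channel-site set; interpolation to a smooth grid is a display concern and
#' never feeds the depth computation.
#'
#' @param epochs_by_channel Named list of epoch matrices (or
#'   [epoch_family()] objects), one per channel, identical dimensions; names
#'   are channel ids.
#' @param layout Data frame with columns `channel_id`, `x`, `y` (and
#'   optionally `region`) covering exactly the channels in
#'   `epochs_by_channel`.
#' @param band A [band_def()], band name, or `c(lo, hi)` in Hz.
#' @param epochs Optional epoch index range defining a phase (e.g. `1:60` for
#'   an early phase); default all epochs.
#' @param fs Sampling rate in Hz (taken from `epoch_family` inputs when
#'   available).
#' @return A [surface_family()]; rows are epochs, columns are channels in
#'   layout order.
#' @export
band_power_surfaces <- function(epochs_by_channel, layout, band,
                                epochs = NULL, fs = NULL) {
  mats <- lapply(epochs_by_channel, function(e) {
    if (inherits(e, "epoch_family")) {
      if (is.null(fs)) fs <<- e$fs
      e$x
    } else {
      as.matrix(e)
    }
  })
  if (is.null(fs)) {
    fs <- 1
  }
  if (!all(c("channel_id", "x", "y") %in% names(layout))) {
    stop("layout needs columns channel_id, x, y")
  }
  chan <- as.character(layout$channel_id)
  if (is.null(names(mats)) || !setequal(names(mats), chan)) {
    stop("channel/layout mismatch: list names and layout channel_id differ")
  }
  dims <- unique(vapply(mats, function(m) paste(dim(m), collapse = "x"), ""))
  if (length(dims) != 1L) {
    stop("all channels must share the same epoch structure")
  }
  mats <- mats[chan]
  n_ep <- nrow(mats[[1]])
  if (is.null(epochs)) {
    epochs <- seq_len(n_ep)
  }
  if (any(epochs < 1L | epochs > n_ep)) {
    stop("epoch range outside the recorded epochs")
  }
  band <- as_band(band)
  values <- matrix(NA_real_, length(epochs), length(chan),
                   dimnames = list(NULL, chan))
  for (j in seq_along(chan)) {
    m <- mats[[j]]
    for (i in seq_along(epochs)) {
      values[i, j] <- band_power(periodogram(m[epochs[i], ], fs = fs), band)
    }
  }
  surface_family(values, sites = layout)
}

#' Surface boxplot of a family of surfaces
#'
#' Orders the surfaces by modified volume depth and builds the surface
#' analog of the functional boxplot. The deepest surface is the median
#' (tied deepest surfaces are averaged); the pointwise envelope of the
#' `ceiling(n/2)` deepest surfaces is the 50% central region, whose border is
#' the inner envelope; fences inflate the inner envelope by `factor` times
#' the central region's pointwise height; any surface crossing a fence at any
#' site is flagged; and the outer envelope is the pointwise extreme over the
#' non-outlying surfaces (the border of the maximum non-outlying region).
#'
#' @param x A [surface_family()] or numeric matrix with at least 4 surfaces.
#' @param factor Fence inflation constant.
#' @return Object of class `surface_boxplot` with fields `median_ids`,
#'   `median_surface`, `inner_envelope_lower`/`upper`,
#'   `outer_envelope_lower`/`upper`, `fence_lower`/`fence_upper`,
#'   `outlier_ids`, `depths`, `factor`, `values`, `sites`.
#' @export
surface_boxplot <- function(x, factor = 1.5) {
  v <- as_value_matrix(x)
  if (nrow(v) < 4L) {
    stop("surface boxplot needs at least 4 surfaces")
  }
  depths <- modified_volume_depth(v)
  fb <- functional_boxplot(v, factor = factor, depths = depths)
  structure(
    list(
      median_ids = fb$median_ids,
      median_surface = fb$median,
      inner_envelope_lower = fb$central_lower,
      inner_envelope_upper = fb$central_upper,
      outer_envelope_lower = fb$nonoutlying_min,
      outer_envelope_upper = fb$nonoutlying_max,
      fence_lower = fb$fence_lower,
      fence_upper = fb$fence_upper,
      outlier_ids = fb$outlier_ids,
      depths = depths,
      factor = factor,
      values = v,
      sites = if (inherits(x, "surface_family")) x$sites else NULL
    ),
    class = "surface_boxplot"
  )
}

#' @export
print.surface_boxplot <- function(x, ...) {
  cat(sprintf("<surface_boxplot> %d surfaces over %d sites, factor = %g\n",
              nrow(x$values), ncol(x$values), x$factor))
  cat(" median surface:", paste(x$median_ids, collapse = ", "), "\n")
  if (length(x$outlier_ids)) {
    cat(" outliers:", paste(x$outlier_ids, collapse = ", "), "\n")
  } else {
    cat(" outliers: none\n")
  }
  invisible(x)
}

#' @export
plot.surface_boxplot <- function(x, main = "Median surface", ...) {
  if (is.null(x$sites)) {
    stop("no site coordinates attached to this surface family")
  }
  val <- x$median_surface
  pal <- grDevices::hcl.colors(64, "Blue-Red 3")
  idx <- cut(val, breaks = 64, labels = FALSE, include.lowest = TRUE)
  graphics::plot(x$sites$x, x$sites$y, pch = 21, cex = 2.2,
                 bg = pal[idx], xlab = "x", ylab = "y", main = main, ...)
  invisible(x)
}
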