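#' Family of time-series epochs
#'
#' Container for a set of equal-length epochs from one channel (or one
#' region-averaged signal): a numeric matrix with one row per epoch and one
#' column per sample, a common sampling rate, and an optional group label per
#' epoch. Epochs are treated as independent realizations of a stationary
#' process, the working assumption behind per-epoch spectral estimation.
#'
#' @param x Numeric matrix, epochs in rows.
#' @param fs Sampling rate in Hz.
#' @param group Optional factor/vector of per-epoch labels (recycled checks
#'   apply: length must equal `nrow(x)`).
#' @param demean If `TRUE`, subtract each epoch's mean (the standard mean
#'   detrend applied before spectral estimation).
#' @return An object of class `epoch_family` with fields `x`, `fs`, `group`.
#' @export
#' @examples
#' ef <- epoch_family(matrix(rnorm(200), 4, 50), fs = 50)
#' ef
epoch_family <- function(x, fs = 1, group = NULL, demean = FALSE) {
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x)) {
    stop("epochs must be a numeric matrix without missing values")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a positive sampling rate in Hz")
  }
  if (!is.null(group)) {
    if (length(group) != nrow(x)) {
      stop("group must have one label per epoch")
    }
    group <- as.factor(group)
  }
  if (demean) {
    x <- x - rowMeans(x)
  }
  structure(list(x = x, fs = fs, group = group), class = "epoch_family")
}

#' @export
print.epoch_family <- function(x, ...) {
  cat(sprintf("<epoch_family> %d epochs x %d samples, fs = %g Hz",
              nrow(x$x), ncol(x$x), x$fs))
  if (!is.null(x$group)) {
    cat(sprintf(", groups: %s", paste(levels(x$group), collapse = "/")))
  }
  cat("\n")
  invisible(x)
}

#' @export
as.matrix.epoch_family <- function(x, ...) x$x

#' Read an epoch matrix from a delimited text file
#'
#' Reads a rectangular numeric table with one epoch per row and one sample per
#' column. Each epoch is mean-detrended on load, the standard pre-processing
#' step before periodogram computation. Malformed files fail with the
#' offending row (and column) named.
#'
#' @param path File path.
#' @param delimiter Field separator; `","` (default) or e.g. `"\t"`.
#' @param fs Sampling rate in Hz attached to the result.
#' @param demean Mean-detrend each epoch on load (default `TRUE`).
#' @return An [epoch_family()].
#' @seealso [write_epoch_matrix()]
#' @export
read_epoch_matrix <- function(path, delimiter = ",", fs = 1, demean = TRUE) {
  if (!file.exists(path)) {
    stop("no such file: ", path)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("empty epoch file: ", path)
  }
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != nf[1])) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("ragged row %d in %s: %d fields, expected %d",
                 bad, path, nf[bad], nf[1]))
  }
  vals <- suppressWarnings(as.numeric(unlist(fields, use.names = FALSE)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    row <- (bad - 1L) %/% nf[1] + 1L
    col <- (bad - 1L) %% nf[1] + 1L
    stop(sprintf("non-numeric cell at row %d, column %d in %s", row, col, path))
  }
  m <- matrix(vals, nrow = length(lines), ncol = nf[1], byrow = TRUE)
  epoch_family(m, fs = fs, demean = demean)
}

#' Write an epoch matrix with a sidecar parameter file
#'
#' Writes the epochs as plain delimited text (rows = epochs, columns =
#' samples) and a JSON sidecar `<path>.json` recording the sampling rate,
#' dimensions and any generator parameters, so a simulated data set remains
#' reproducible from its files alone.
#'
#' @param ef An [epoch_family()] or numeric matrix.
#' @param path Output file path.
#' @param delimiter Field separator.
#' @param params Named list of generator parameters (seed included) stored in
#'   the sidecar.
#' @return Invisibly, `path`.
#' @export
write_epoch_matrix <- function(ef, path, delimiter = ",", params = list()) {
  x <- if (inherits(ef, "epoch_family")) ef$x else as.matrix(ef)
  fs <- if (inherits(ef, "epoch_family")) ef$fs else NA_real_
  utils::write.table(x, path, sep = delimiter, row.names = FALSE,
                     col.names = FALSE)
  meta <- c(list(fs = fs, n_epochs = nrow(x), n_samples = ncol(x)), params)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Average epochs over channels within regions
#'
#' Collapses a multichannel epoch set to one representative signal per scalp
#' region by taking, epoch by epoch, the pointwise mean time series across the
#' member channels. Averaging is done in the time domain, before any spectral
#' estimation, so that coherent signal adds while independent channel noise
#' averages down.
#'
#' @param epochs_by_channel Named list of epoch matrices (or `epoch_family`
#'   objects), one per channel, all with identical dimensions.
#' @param regions Either a named character vector mapping channel id to region,
#'   or a data frame with columns `channel_id` and `region`. Each channel may
#'   belong to at most one region.
#' @return Named list of epoch matrices, one per region. Regions with no
#'   matching channels are dropped with a warning.
#' @export
region_average <- function(epochs_by_channel, regions) {
  mats <- lapply(epochs_by_channel, function(e) {
    if (inherits(e, "epoch_family")) e$x else as.matrix(e)
  })
  if (is.null(names(mats)) || any(!nzchar(names(mats)))) {
    stop("epochs_by_channel must be a named list (names are channel ids)")
  }
  if (is.data.frame(regions)) {
    if (!all(c("channel_id", "region") %in% names(regions))) {
      stop("regions data frame needs columns channel_id and region")
    }
    if (anyDuplicated(regions$channel_id)) {
      stop("each channel may be assigned to at most one region")
    }
    map <- stats::setNames(as.character(regions$region),
                           as.character(regions$channel_id))
  } else {
    if (anyDuplicated(names(regions))) {
      stop("each channel may be assigned to at most one region")
    }
    map <- stats::setNames(as.character(regions), names(regions))
  }
  out <- list()
  for (reg in unique(map)) {
    chans <- names(map)[map == reg]
    chans <- chans[chans %in% names(mats)]
    if (length(chans) == 0L) {
      warning("region ", reg, " has no matching channels; excluded")
      next
    }
    out[[reg]] <- Reduce(`+`, mats[chans]) / length(chans)
  }
  out
}
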