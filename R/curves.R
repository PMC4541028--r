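#' Family of curves on a common grid
#'
#' A set of real-valued functions observed on one shared argument grid,
#' stored as a numeric matrix with one curve per row. This is the unit of
#' analysis for depth computation, functional boxplots and the rank-sum
#' test.
#'
#' @param values Numeric matrix, curves in rows; no missing values.
#' @param arg Optional grid values (e.g. frequencies in Hz), length
#'   `ncol(values)`.
#' @param ids Optional per-curve labels; default `1:n`.
#' @return Object of class `curve_family` with fields `values`, `arg`, `ids`.
#' @export
curve_family <- function(values, arg = NULL, ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values) || anyNA(values)) {
    stop("curve values must be a numeric matrix without missing values")
  }
  if (is.null(arg)) {
    arg <- seq_len(ncol(values))
  }
  if (length(arg) != ncol(values)) {
    stop("arg must have one value per grid point")
  }
  if (is.null(ids)) {
    ids <- seq_len(nrow(values))
  }
  if (length(ids) != nrow(values)) {
    stop("ids must have one label per curve")
  }
  structure(list(values = values, arg = as.numeric(arg), ids = ids),
            class = "curve_family")
}

#' @export
print.curve_family <- function(x, ...) {
  cat(sprintf("<curve_family> %d curves on %d grid points [%g, %g]\n",
              nrow(x$values), ncol(x$values), min(x$arg), max(x$arg)))
  invisible(x)
}

#' @export
as.matrix.curve_family <- function(x, ...) x$values

#' @export
plot.curve_family <- function(x, col = "grey50", ...) {
  graphics::matplot(x$arg, t(x$values), type = "l", lty = 1, col = col,
                    xlab = "argument", ylab = "value", ...)
  invisible(x)
}

#' Subset a curve family
#' @param x A [curve_family()].
#' @param i Row (curve) indices to keep.
#' @param ... Unused.
#' @return A `curve_family` of the selected curves.
#' @export
`[.curve_family` <- function(x, i, ...) {
  curve_family(x$values[i, , drop = FALSE], arg = x$arg, ids = x$ids[i])
}

#' Family of surfaces on a common site set
#'
#' A set of surfaces observed over one shared finite set of 2-D sites
#' (typically scalp channel positions), stored as a matrix with one surface
#' per row and one site per column. Surfaces are ordered by
#' [modified_volume_depth()] and summarized by [surface_boxplot()].
#'
#' @param values Numeric matrix, surfaces in rows, sites in columns.
#' @param sites Data frame of site coordinates with columns `x` and `y`
#'   (and optionally `channel_id`, `region`); one row per column of `values`.
#' @return Object of class `surface_family`.
#' @export
surface_family <- function(values, sites = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values) || anyNA(values)) {
    stop("surface values must be a numeric matrix without missing values")
  }
  if (is.null(sites)) {
    sites <- data.frame(x = seq_len(ncol(values)), y = 0)
  }
  if (nrow(sites) != ncol(values)) {
    stop("sites must have one row per surface column")
  }
  structure(list(values = values, sites = sites), class = "surface_family")
}

#' @export
print.surface_family <- function(x, ...) {
  cat(sprintf("<surface_family> %d surfaces over %d sites\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
as.matrix.surface_family <- function(x, ...) x$values
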