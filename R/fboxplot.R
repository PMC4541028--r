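#' Functional boxplot of a family of curves
#'
#' Orders the curves by modified band depth and builds the functional analog
#' of a boxplot: the deepest curve is the functional median (tied deepest
#' curves are averaged), the pointwise envelope of the deepest 50% of curves
#' (`ceiling(n/2)` of them) is the central region, and fences are obtained by
#' inflating the central region by `factor` times its pointwise height,
#' mirroring the classical 1.5 IQR rule. A curve is flagged as a potential
#' outlier if it crosses a fence at any grid point; the non-outlying extremes
#' are the pointwise min/max over the remaining curves.
#'
#' The default `factor = 1.5` matches the classical boxplot convention; for
#' spatially or temporally correlated families of curves a larger factor may
#' be appropriate, and the parameter is exposed for exactly that adjustment.
#' Increasing `factor` never enlarges the outlier set, and as
#' `factor -> Inf` no curve is flagged.
#'
#' @param x A [curve_family()] or numeric matrix with at least 4 curves.
#' @param factor Fence inflation constant (>= 0).
#' @param depths Optional precomputed `depth_vector` (or numeric vector) to
#'   order by; defaults to [modified_band_depth()] of `x`.
#' @return Object of class `functional_boxplot`: `median_ids` (indices of the
#'   deepest curve or tie group), `median` (the median curve, averaged over a
#'   tie group), `central_lower`/`central_upper`, `fence_lower`/`fence_upper`,
#'   `nonoutlying_min`/`nonoutlying_max`, `outlier_ids`, `depths`, `factor`,
#'   plus the input `values`, `arg` and `ids`.
#' @seealso [pointwise_boxplot()] for the per-frequency comparator,
#'   [surface_boxplot()] for the surface analog.
#' @export
#' @examples
#' fam <- matrix(rnorm(20 * 50), 20, 50) + outer(rnorm(20), rep(1, 50))
#' fb <- functional_boxplot(fam)
#' fb$outlier_ids
functional_boxplot <- function(x, factor = 1.5, depths = NULL) {
  v <- as_value_matrix(x)
  n <- nrow(v)
  if (n < 4L) {
    stop("functional boxplot needs at least 4 curves")
  }
  if (factor < 0) {
    stop("fence factor must be nonnegative")
  }
  ids <- if (inherits(x, "curve_family")) x$ids else seq_len(n)
  arg <- if (inherits(x, "curve_family")) x$arg else seq_len(ncol(v))
  if (is.null(depths)) {
    depths <- modified_band_depth(v)
  }
  d <- if (inherits(depths, "depth_vector")) depths$depths else as.numeric(depths)
  if (length(d) != n) {
    stop("depths must have one value per curve")
  }

  ord <- order(d, decreasing = TRUE)
  nc <- ceiling(n / 2)
  central_idx <- ord[seq_len(nc)]
  cl <- apply(v[central_idx, , drop = FALSE], 2L, min)
  cu <- apply(v[central_idx, , drop = FALSE], 2L, max)
  h <- cu - cl
  fl <- cl - factor * h
  fu <- cu + factor * h

  out <- which(apply(v, 1L, function(row) any(row > fu | row < fl)))
  keep <- setdiff(seq_len(n), out)
  med_idx <- which(d == max(d))
  med <- colMeans(v[med_idx, , drop = FALSE])

  structure(
    list(
      median_ids = ids[med_idx],
      median = med,
      central_lower = cl, central_upper = cu,
      fence_lower = fl, fence_upper = fu,
      nonoutlying_min = apply(v[keep, , drop = FALSE], 2L, min),
      nonoutlying_max = apply(v[keep, , drop = FALSE], 2L, max),
      outlier_ids = ids[out],
      depths = if (inherits(depths, "depth_vector")) depths
               else make_depth_vector(d, ids),
      factor = factor,
      values = v, arg = arg, ids = ids
    ),
    class = "functional_boxplot"
  )
}

#' @export
print.functional_boxplot <- function(x, ...) {
  cat(sprintf("<functional_boxplot> %d curves, factor = %g\n",
              nrow(x$values), x$factor))
  cat(" median curve:", paste(x$median_ids, collapse = ", "), "\n")
  if (length(x$outlier_ids)) {
    cat(" outliers:", paste(x$outlier_ids, collapse = ", "), "\n")
  } else {
    cat(" outliers: none\n")
  }
  invisible(x)
}

#' @export
plot.functional_boxplot <- function(x, main = "Functional boxplot",
                                    xlab = "argument", ylab = "value", ...) {
  rng <- range(x$values)
  graphics::plot(range(x$arg), rng, type = "n", main = main,
                 xlab = xlab, ylab = ylab, ...)
  graphics::polygon(c(x$arg, rev(x$arg)),
                    c(x$central_lower, rev(x$central_upper)),
                    col = "mistyrose", border = NA)
  out <- match(x$outlier_ids, x$ids)
  if (length(out)) {
    graphics::matlines(x$arg, t(x$values[out, , drop = FALSE]),
                       lty = 2, col = "red")
  }
  graphics::lines(x$arg, x$central_lower, col = "blue")
  graphics::lines(x$arg, x$central_upper, col = "blue")
  graphics::lines(x$arg, x$nonoutlying_min, col = "blue")
  graphics::lines(x$arg, x$nonoutlying_max, col = "blue")
  graphics::lines(x$arg, x$median, col = "black", lwd = 2)
  invisible(x)
}

#' Pointwise boxplot of a family of curves
#'
#' The classical comparator to the functional boxplot: an independent
#' boxplot at every grid point, with quartile hinges, `coef` times the IQR
#' fences, and per-point outlier flags. Connecting the pointwise medians
#' gives a "median curve" that need not coincide with any member of the
#' family -- the key interpretive difference from the functional median.
#' Because flags are local, a globally aberrant curve is typically flagged
#' only at scattered points and never identified as a whole-curve outlier.
#'
#' @param x A [curve_family()] or numeric matrix with at least 4 curves.
#' @param coef IQR fence multiplier (1.5 default).
#' @return Object of class `pointwise_boxplot`: matrices of per-point
#'   statistics (`median`, `q1`, `q3`, `fence_lower`, `fence_upper`,
#'   `whisker_lower`, `whisker_upper` -- the per-point non-outlying
#'   extremes), the logical flag matrix `flags` (curves x points), and the
#'   derived per-curve summaries `flagged_any` and `flagged_all`.
#' @export
pointwise_boxplot <- function(x, coef = 1.5) {
  v <- as_value_matrix(x)
  n <- nrow(v)
  if (n < 4L) {
    stop("pointwise boxplot needs at least 4 curves")
  }
  arg <- if (inherits(x, "curve_family")) x$arg else seq_len(ncol(v))
  ids <- if (inherits(x, "curve_family")) x$ids else seq_len(n)
  K <- ncol(v)
  med <- q1 <- q3 <- flo <- fhi <- wlo <- whi <- numeric(K)
  flags <- matrix(FALSE, n, K)
  for (k in seq_len(K)) {
    fn <- stats::fivenum(v[, k])
    q1[k] <- fn[2]
    med[k] <- fn[3]
    q3[k] <- fn[4]
    iqr <- fn[4] - fn[2]
    flo[k] <- fn[2] - coef * iqr
    fhi[k] <- fn[4] + coef * iqr
    flags[, k] <- v[, k] < flo[k] | v[, k] > fhi[k]
    inside <- v[!flags[, k], k]
    wlo[k] <- min(inside)
    whi[k] <- max(inside)
  }
  structure(
    list(median = med, q1 = q1, q3 = q3,
         fence_lower = flo, fence_upper = fhi,
         whisker_lower = wlo, whisker_upper = whi,
         flags = flags,
         flagged_any = ids[rowSums(flags) > 0],
         flagged_all = ids[rowSums(flags) == K],
         coef = coef, values = v, arg = arg, ids = ids),
    class = "pointwise_boxplot"
  )
}

#' @export
print.pointwise_boxplot <- function(x, ...) {
  cat(sprintf("<pointwise_boxplot> %d curves, coef = %g\n",
              nrow(x$values), x$coef))
  cat(sprintf(" curves flagged at >= 1 point: %d; at every point: %d\n",
              length(x$flagged_any), length(x$flagged_all)))
  invisible(x)
}

#' @export
plot.pointwise_boxplot <- function(x, main = "Pointwise boxplot",
                                   xlab = "argument", ylab = "value", ...) {
  graphics::plot(range(x$arg), range(x$values), type = "n", main = main,
                 xlab = xlab, ylab = ylab, ...)
  graphics::polygon(c(x$arg, rev(x$arg)), c(x$q1, rev(x$q3)),
                    col = "aliceblue", border = NA)
  graphics::lines(x$arg, x$whisker_lower, col = "darkgreen")
  graphics::lines(x$arg, x$whisker_upper, col = "darkgreen")
  graphics::lines(x$arg, x$median, lwd = 2)
  pts <- which(x$flags, arr.ind = TRUE)
  if (nrow(pts)) {
    graphics::points(x$arg[pts[, 2]], x$values[pts], col = "red", pch = 20,
                     cex = 0.4)
  }
  invisible(x)
}

#' Pointwise envelope of the deepest fraction of a family
#'
#' The alpha-central region of a depth-ordered family: the pointwise min/max
#' envelope of the `ceiling(alpha * n)` deepest members. The region is nested
#' in alpha -- ordering is from the center outwards, so its volume is
#' nondecreasing as alpha grows.
#'
#' @param x A [curve_family()], [surface_family()] or matrix.
#' @param alpha Central fraction in (0, 1].
#' @param depths Optional precomputed depths (defaults to
#'   [modified_band_depth()] on the rows).
#' @return List with `lower`, `upper` (envelopes) and `ids` (member indices).
#' @export
central_region <- function(x, alpha = 0.5, depths = NULL) {
  v <- as_value_matrix(x)
  if (alpha <= 0 || alpha > 1) {
    stop("alpha must lie in (0, 1]")
  }
  if (is.null(depths)) {
    depths <- modified_band_depth(v)
  }
  d <- if (inherits(depths, "depth_vector")) depths$depths else as.numeric(depths)
  ord <- order(d, decreasing = TRUE)
  idx <- ord[seq_len(ceiling(alpha * nrow(v)))]
  list(lower = apply(v[idx, , drop = FALSE], 2L, min),
       upper = apply(v[idx, , drop = FALSE], 2L, max),
       ids = idx)
}
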