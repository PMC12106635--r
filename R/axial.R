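#' Axial (sign-invariant) orientation statistics
#'
#' Vessel and fiber orientations are *axes*: a direction identified with its
#' negation (v and -v describe the same physical orientation). All statistics
#' in this file are therefore invariant under sign flips of any input.
#'
#' @name axial-statistics
NULL

#' Normalize vectors to unit axes
#'
#' @param v numeric 3-vector or an n x 3 matrix of row vectors.
#' @return unit-norm vector(s) with the same shape.
#' @keywords internal
axis_normalize <- function(v) {
  if (is.matrix(v)) {
    nrm <- sqrt(rowSums(v^2))
    if (any(!is.finite(nrm)) || any(nrm == 0)) {
      stop("zero-norm or non-finite axis", call. = FALSE)
    }
    v / nrm
  } else {
    nrm <- sqrt(sum(v^2))
    if (!is.finite(nrm) || nrm == 0) {
      stop("zero-norm or non-finite axis", call. = FALSE)
    }
    v / nrm
  }
}

#' Canonical sign for an axis
#'
#' Flips the sign so the first nonzero component is positive; used for
#' deterministic output and tie-breaking.
#' @param v 3-vector or n x 3 matrix.
#' @keywords internal
axis_canonical <- function(v) {
  if (is.matrix(v)) {
    sgn <- apply(v, 1L, function(r) {
      nz <- which(abs(r) > 1e-6)
      if (length(nz) == 0) 1 else sign(r[nz[1]])
    })
    v * sgn
  } else {
    nz <- which(abs(v) > 1e-6)
    if (length(nz) == 0) v else v * sign(v[nz[1]])
  }
}

#' Angular deviation between two axes
#'
#' The angle between two sign-ambiguous orientations, computed as the inverse
#' cosine of the absolute dot product, in degrees. The result lies in
#' \[0, 90\]: 0 for parallel or antiparallel axes, 90 for orthogonal ones.
#' The dot product is clipped to \[0, 1\] before the arccos so rounding can
#' never produce NaN.
#'
#' @param u,v unit 3-vectors, or n x 3 matrices compared row-wise (a single
#'   vector recycles against a matrix).
#' @return angle(s) in degrees, in \[0, 90\].
#' @examples
#' angular_deviation(c(1, 0, 0), c(0, 1, 0))  # 90
#' angular_deviation(c(1, 0, 0), c(-1, 0, 0)) # 0
#' @export
angular_deviation <- function(u, v) {
  if (!is.matrix(u) && !is.matrix(v)) {
    u <- axis_normalize(u); v <- axis_normalize(v)
    d <- abs(sum(u * v))
  } else {
    if (!is.matrix(u)) u <- matrix(u, nrow = if (is.matrix(v)) nrow(v) else 1,
                                   ncol = 3, byrow = TRUE)
    if (!is.matrix(v)) v <- matrix(v, nrow = nrow(u), ncol = 3, byrow = TRUE)
    u <- axis_normalize(u); v <- axis_normalize(v)
    d <- abs(rowSums(u * v))
  }
  acos(pmin(pmax(d, 0), 1)) * 180 / pi
}

#' Dyadic (outer-product) mean of axes
#'
#' The mean orientation of sign-ambiguous axes, defined as the principal
#' eigenvector of the weighted mean dyadic tensor
#' \eqn{\sum_i w_i a_i a_i^T / \sum_i w_i}. Unlike arithmetic vector
#' averaging this is invariant to flipping the sign of any input, which is
#' the defining requirement for axial data.
#'
#' @param axes n x 3 matrix of axes (rows need not be unit norm; they are
#'   normalized) or a single 3-vector.
#' @param weights optional nonnegative weights, length n, not all zero.
#' @return unit 3-vector in canonical sign, with attributes
#'   `eigenvalues` (descending eigenvalues of the mean dyadic tensor) and
#'   `degenerate` (TRUE when the two leading eigenvalues tie, i.e. the mean
#'   axis is not unique; any leading eigenvector is returned).
#' @export
dyadic_mean <- function(axes, weights = NULL) {
  if (!is.matrix(axes)) axes <- matrix(axes, ncol = 3)
  if (nrow(axes) == 0) stop("need at least one axis", call. = FALSE)
  axes <- axis_normalize(axes)
  if (is.null(weights)) weights <- rep(1, nrow(axes))
  if (length(weights) != nrow(axes)) {
    stop("weights length must match number of axes", call. = FALSE)
  }
  if (any(weights < 0) || sum(weights) == 0) {
    stop("weights must be nonnegative and not all zero", call. = FALSE)
  }
  w <- weights / sum(weights)
  tensor <- crossprod(axes * sqrt(w))  # sum_i w_i a_i a_i^T
  e <- eigen(tensor, symmetric = TRUE)
  mean_axis <- axis_canonical(axis_normalize(e$vectors[, 1]))
  attr(mean_axis, "eigenvalues") <- e$values
  attr(mean_axis, "degenerate") <- (e$values[1] - e$values[2]) < 1e-9
  mean_axis
}

#' Mean angular deviation of axes about a reference
#'
#' Arithmetic mean of the axial angular deviations of each axis from a
#' reference axis; the across-subject variability measure used for
#' population orientation maps.
#'
#' @param axes n x 3 matrix (or 3-vector).
#' @param reference unit 3-vector.
#' @return mean angle in degrees, in \[0, 90\].
#' @export
mean_angular_deviation <- function(axes, reference) {
  if (!is.matrix(axes)) axes <- matrix(axes, ncol = 3)
  if (nrow(axes) == 0) stop("need at least one axis", call. = FALSE)
  mean(angular_deviation(axes, reference))
}

#' Mean pairwise angular deviation
#'
#' Alternative dispersion measure: the mean of angular deviations over all
#' unordered pairs of axes.
#'
#' @param axes n x 3 matrix, n >= 2.
#' @return mean pairwise angle in degrees.
#' @export
pairwise_angular_deviation <- function(axes) {
  if (!is.matrix(axes) || nrow(axes) < 2) {
    stop("need at least two axes", call. = FALSE)
  }
  pairs <- utils::combn(nrow(axes), 2)
  mean(angular_deviation(axes[pairs[1, ], , drop = FALSE],
                         axes[pairs[2, ], , drop = FALSE]))
}
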