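#' Along-tract vessel-fiber angle profiles
#'
#' A streamline bundle gives one dominant fiber orientation per voxel (the
#' dominant direction of streamline tangents within the voxel). Profiles
#' compare that orientation, or point-wise tangents, with the vessel axis
#' along the bundle length, parcellated into 100 equal-arc-length segments.
#'
#' @name tract-profile
NULL

#' Construct a streamline bundle
#'
#' @param streamlines list of n x 3 matrices of world-mm points, each with
#'   at least 2 points, finite coordinates, consistently ordered
#'   beginning-to-end.
#' @param name optional bundle name.
#' @return object of class `streamline_bundle`.
#' @export
streamline_bundle <- function(streamlines, name = "bundle") {
  stopifnot(is.list(streamlines), length(streamlines) >= 1)
  for (s in streamlines) {
    if (!is.matrix(s) || ncol(s) != 3 || nrow(s) < 2 || any(!is.finite(s))) {
      stop("each streamline must be a finite n x 3 matrix with n >= 2",
           call. = FALSE)
    }
  }
  structure(list(streamlines = streamlines, name = name),
            class = "streamline_bundle")
}

#' @export
print.streamline_bundle <- function(x, ...) {
  cat("<streamline_bundle>", x$name, ":", length(x$streamlines),
      "streamlines,", sum(vapply(x$streamlines, nrow, 1L)), "points\n")
  invisible(x)
}

#' @export
length.streamline_bundle <- function(x) length(x$streamlines)

#' Unit tangents of a streamline (central differences)
#'
#' One-sided differences at the endpoints.
#' @param points n x 3 matrix.
#' @return n x 3 matrix of unit tangents.
#' @keywords internal
streamline_tangents <- function(points) {
  n <- nrow(points)
  d <- rbind(points[2, ] - points[1, ],
             points[seq(3, length.out = max(0, n - 2)), , drop = FALSE] -
               points[seq(1, length.out = max(0, n - 2)), , drop = FALSE],
             points[n, ] - points[n - 1, ])
  nrm <- sqrt(rowSums(d^2))
  nrm[nrm == 0] <- 1
  d / nrm
}

#' Resample a streamline to equidistant points
#'
#' @param points n x 3 matrix of ordered points.
#' @param n number of output points at equal arc-length spacing, endpoints
#'   included (default 100).
#' @return n x 3 matrix; NULL (with a warning) for zero-length streamlines.
#' @export
resample_streamline <- function(points, n = 100L) {
  seglen <- sqrt(rowSums((points[-1, , drop = FALSE] -
                            points[-nrow(points), , drop = FALSE])^2))
  s <- c(0, cumsum(seglen))
  total <- s[length(s)]
  if (total <= 0) {
    warning("zero-length streamline skipped")
    return(NULL)
  }
  tgt <- seq(0, total, length.out = n)
  out <- cbind(stats::approx(s, points[, 1], xout = tgt, ties = "ordered")$y,
               stats::approx(s, points[, 2], xout = tgt, ties = "ordered")$y,
               stats::approx(s, points[, 3], xout = tgt, ties = "ordered")$y)
  out
}

#' Enforce consistent streamline ordering within a bundle
#'
#' Flips streamlines whose start point is nearer the centroid of all end
#' points than the centroid of all start points, so segment indices
#' correspond across streamlines.
#' @param bundle a `streamline_bundle`.
#' @return reordered bundle.
#' @export
orient_bundle <- function(bundle) {
  starts <- t(vapply(bundle$streamlines, function(s) s[1, ], numeric(3)))
  ends <- t(vapply(bundle$streamlines, function(s) s[nrow(s), ], numeric(3)))
  c_start <- colMeans(starts)
  c_end <- colMeans(ends)
  flipped <- lapply(seq_along(bundle$streamlines), function(i) {
    s <- bundle$streamlines[[i]]
    d_keep <- sum((s[1, ] - c_start)^2) + sum((s[nrow(s), ] - c_end)^2)
    d_flip <- sum((s[1, ] - c_end)^2) + sum((s[nrow(s), ] - c_start)^2)
    if (d_flip < d_keep) s[rev(seq_len(nrow(s))), , drop = FALSE] else s
  })
  streamline_bundle(flipped, bundle$name)
}

#' Voxel indices containing world points
#'
#' Half-open voxel intervals: a point belongs to the voxel whose centre is
#' nearest under the world-to-voxel affine.
#' @keywords internal
points_to_voxels <- function(points, affine, dm) {
  ijk <- round(world_to_voxel(points, affine))
  inside <- ijk[, 1] >= 1 & ijk[, 1] <= dm[1] &
    ijk[, 2] >= 1 & ijk[, 2] <= dm[2] &
    ijk[, 3] >= 1 & ijk[, 3] <= dm[3]
  list(ijk = ijk, inside = inside)
}

#' Dominant streamline orientation per voxel
#'
#' For each voxel of the target grid, the dyadic mean of the unit tangents
#' of all streamline points falling in that voxel; invalid where no point
#' falls.
#'
#' @param bundle a `streamline_bundle` (world-mm coordinates).
#' @param dim length-3 grid dimensions.
#' @param voxel_mm voxel size in mm.
#' @param affine voxel-to-world affine of the grid.
#' @return `axial_field` on the grid.
#' @export
voxel_streamline_orientation <- function(bundle, dim, voxel_mm,
                                         affine = default_affine(voxel_mm)) {
  pts <- do.call(rbind, bundle$streamlines)
  tans <- do.call(rbind, lapply(bundle$streamlines, streamline_tangents))
  pv <- points_to_voxels(pts, affine, dim)
  keep <- pv$inside
  ijk <- pv$ijk[keep, , drop = FALSE]
  tans <- tans[keep, , drop = FALSE]
  lin <- (ijk[, 3] - 1L) * dim[1] * dim[2] + (ijk[, 2] - 1L) * dim[1] + ijk[, 1]
  groups <- split(seq_along(lin), lin)
  idx <- as.integer(names(groups))
  ax <- matrix(NA_real_, length(groups), 3)
  for (g in seq_along(groups)) {
    ax[g, ] <- as.numeric(dyadic_mean(tans[groups[[g]], , drop = FALSE]))
  }
  field_from_matrix(ax, idx, as.integer(dim), voxel_mm, affine)
}

#' Along-tract vessel-fiber angle profile
#'
#' Resamples every streamline to `n_segments` equal-arc-length points; at
#' point k of each streamline the angle between the streamline tangent axis
#' and the vessel axis of the containing voxel is computed (skipped where
#' the vessel voxel is invalid or outside the grid), and segment-k values
#' are pooled across streamlines.
#'
#' @param bundle a `streamline_bundle`, consistently oriented (see
#'   [orient_bundle()]).
#' @param vessels `axial_field` of vessel axes covering the bundle.
#' @param n_segments number of segments (default 100).
#' @param reorient apply [orient_bundle()] first (default TRUE).
#' @return object of class `tract_profile`: tibble with one row per
#'   segment (`segment`, `mean_angle`, `min_angle`, `max_angle`, `n`),
#'   exactly `n_segments` rows; segments with no valid sample have NA
#'   statistics. Attribute `bundle` carries the bundle name.
#' @export
along_tract_profile <- function(bundle, vessels, n_segments = 100L,
                                reorient = TRUE) {
  if (reorient) bundle <- orient_bundle(bundle)
  n <- prod(vessels$dim)
  seg_vals <- vector("list", n_segments)
  any_valid <- FALSE
  for (s in bundle$streamlines) {
    rs <- resample_streamline(s, n_segments)
    if (is.null(rs)) next
    tans <- streamline_tangents(rs)
    pv <- points_to_voxels(rs, vessels$affine, vessels$dim)
    lin <- (pv$ijk[, 3] - 1L) * vessels$dim[1] * vessels$dim[2] +
      (pv$ijk[, 2] - 1L) * vessels$dim[1] + pv$ijk[, 1]
    ok <- pv$inside
    ok[ok] <- vessels$mask[lin[ok]]
    if (!any(ok)) next
    any_valid <- TRUE
    va <- cbind(vessels$axes[lin[ok]], vessels$axes[lin[ok] + n],
                vessels$axes[lin[ok] + 2L * n])
    ang <- angular_deviation(tans[ok, , drop = FALSE], va)
    segs <- which(ok)
    for (w in seq_along(segs)) {
      k <- segs[w]
      seg_vals[[k]] <- c(seg_vals[[k]], ang[w])
    }
  }
  if (!any_valid) {
    warning("bundle entirely outside valid vessel voxels: all-missing profile")
  }
  out <- tibble::tibble(
    segment = seq_len(n_segments),
    mean_angle = vapply(seg_vals, function(v)
      if (length(v)) mean(v) else NA_real_, numeric(1)),
    min_angle = vapply(seg_vals, function(v)
      if (length(v)) min(v) else NA_real_, numeric(1)),
    max_angle = vapply(seg_vals, function(v)
      if (length(v)) max(v) else NA_real_, numeric(1)),
    n = vapply(seg_vals, length, integer(1)))
  attr(out, "bundle") <- bundle$name
  class(out) <- c("tract_profile", class(out))
  out
}

#' Mean angle over a tract profile
#'
#' @param profile a `tract_profile`.
#' @return mean of the non-missing segment means (degrees); NA when every
#'   segment is missing.
#' @export
bundle_mean_angle <- function(profile) {
  v <- profile$mean_angle[!is.na(profile$mean_angle)]
  if (!length(v)) return(NA_real_)
  mean(v)
}

#' Write / read a tract profile as TSV
#'
#' @param profile a `tract_profile`.
#' @param path file path.
#' @export
write_tract_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tract_profile
#' @export
read_tract_profile <- function(path) {
  out <- tibble::as_tibble(utils::read.delim(path))
  class(out) <- c("tract_profile", class(out))
  out
}
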