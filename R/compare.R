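#' Vessel-fiber angle maps and summaries
#'
#' Voxel-wise angular deviation between the vessel axis and either the
#' dominant FOD peak (largest apparent fiber density) or the nearest peak
#' (minimum angle over all peaks): the nearest angle asks not whether
#' vasculature follows the dominant fiber direction but whether it is
#' parallel to *any* fiber population in the voxel.
#'
#' @name angle-compare
NULL

angle_map_new <- function(angle, affine, voxel_mm, kind) {
  structure(list(angle = angle, affine = affine,
                 voxel_mm = rep(voxel_mm, length.out = 3),
                 kind = kind, dim = dim(angle)),
            class = "angle_map")
}

#' @export
print.angle_map <- function(x, ...) {
  ok <- !is.na(x$angle)
  cat("<angle_map>", x$kind, "; grid", paste(x$dim, collapse = " x "), ";",
      sum(ok), "defined voxels; median",
      if (any(ok)) signif(stats::median(x$angle[ok]), 3) else NA, "deg\n")
  invisible(x)
}

#' Dominant-angle map
#'
#' Angle between the vessel axis and the largest-amplitude FOD peak, per
#' voxel; missing wherever either the vessel axis or all peaks are missing
#' (missing voxels are excluded from statistics, never zero-filled).
#'
#' @param vessels `axial_field` of vessel axes (coarse grid).
#' @param peaks `peak_field` on the same grid.
#' @return object of class `angle_map` with per-voxel degrees in \[0, 90\]
#'   or NA.
#' @export
dominant_angle_map <- function(vessels, peaks) {
  stopifnot(identical(vessels$dim, peaks$dim))
  dom <- dominant_peak(peaks)
  both <- vessels$mask & dom$mask
  ang <- array(NA_real_, vessels$dim)
  idx <- which(both)
  if (length(idx)) {
    n <- prod(vessels$dim)
    va <- cbind(vessels$axes[idx], vessels$axes[idx + n],
                vessels$axes[idx + 2L * n])
    fa <- cbind(dom$axes[idx], dom$axes[idx + n], dom$axes[idx + 2L * n])
    ang[idx] <- angular_deviation(va, fa)
  }
  angle_map_new(ang, vessels$affine, vessels$voxel_mm, "dominant")
}

#' Nearest-angle map
#'
#' Angle between the vessel axis and all FOD peaks of the voxel, retaining
#' the minimum.
#'
#' @inheritParams dominant_angle_map
#' @return `angle_map` (kind `"nearest"`).
#' @export
nearest_angle_map <- function(vessels, peaks) {
  stopifnot(identical(vessels$dim, peaks$dim))
  dm <- vessels$dim
  n <- prod(dm)
  mp <- peaks$max_peaks
  ang <- array(NA_real_, dm)
  idx <- which(vessels$mask & peaks$n_peaks > 0)
  if (length(idx)) {
    va <- cbind(vessels$axes[idx], vessels$axes[idx + n],
                vessels$axes[idx + 2L * n])
    best <- rep(Inf, length(idx))
    for (p in seq_len(mp)) {
      has <- which(peaks$n_peaks[idx] >= p)
      if (!length(has)) break
      off <- (p - 1L) * n
      ih <- idx[has]
      fa <- cbind(peaks$axes[ih + off],
                  peaks$axes[ih + off + mp * n],
                  peaks$axes[ih + off + 2L * mp * n])
      a <- angular_deviation(va[has, , drop = FALSE], fa)
      best[has] <- pmin(best[has], a)
    }
    ang[idx] <- best
  }
  angle_map_new(ang, vessels$affine, vessels$voxel_mm, "nearest")
}

#' Histogram and summary of an angle map
#'
#' @param map an `angle_map`.
#' @param bin_width_deg bin width over the \[0, 90\] partition (default 2).
#' @return object of class `angle_histogram`: tibble of `bin_lo`, `bin_hi`,
#'   `bin_mid`, `count` with attributes `mean`, `median`, `mode` (midpoint
#'   of the fullest bin) and `n`; empty map gives zero counts and NA stats.
#' @export
angle_histogram <- function(map, bin_width_deg = 2) {
  vals <- map$angle[!is.na(map$angle)]
  breaks <- seq(0, 90 + bin_width_deg - 1e-9, by = bin_width_deg)
  if (breaks[length(breaks)] < 90) breaks <- c(breaks, 90)
  breaks[length(breaks)] <- max(breaks[length(breaks)], 90)
  cnt <- if (length(vals)) {
    tabulate(findInterval(vals, breaks, rightmost.closed = TRUE),
             nbins = length(breaks) - 1)
  } else rep(0L, length(breaks) - 1)
  out <- tibble::tibble(bin_lo = breaks[-length(breaks)],
                        bin_hi = breaks[-1],
                        bin_mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
                        count = cnt)
  attr(out, "n") <- length(vals)
  attr(out, "mean") <- if (length(vals)) mean(vals) else NA_real_
  attr(out, "median") <- if (length(vals)) stats::median(vals) else NA_real_
  attr(out, "mode") <- if (length(vals)) out$bin_mid[which.max(cnt)] else NA_real_
  class(out) <- c("angle_histogram", class(out))
  out
}

#' Summary statistics of an angle map
#'
#' @param x an `angle_map`.
#' @param ... unused.
#' @return one-row tibble: n, mean, median, q25, q75.
#' @export
glance.angle_map <- function(x, ...) {
  v <- x$angle[!is.na(x$angle)]
  tibble::tibble(kind = x$kind, n = length(v),
                 mean = if (length(v)) mean(v) else NA_real_,
                 median = if (length(v)) stats::median(v) else NA_real_,
                 q25 = if (length(v)) unname(stats::quantile(v, 0.25)) else NA_real_,
                 q75 = if (length(v)) unname(stats::quantile(v, 0.75)) else NA_real_)
}

#' Tidy an angle map into a tibble
#' @param x an `angle_map`.
#' @param ... unused.
#' @return tibble with voxel indices and angle for defined voxels.
#' @export
tidy.angle_map <- function(x, ...) {
  idx <- which(!is.na(x$angle))
  ijk <- arrayInd(idx, x$dim)
  tibble::tibble(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
                 angle = x$angle[idx], kind = x$kind)
}

#' Region-wise angle summary over an atlas
#'
#' Per-label statistics of the dominant and nearest angle maps over the
#' defined voxels of each atlas label, in the style of region-of-interest
#' summaries over a white-matter atlas.
#'
#' @param dominant,nearest `angle_map`s (either may be NULL to summarise
#'   one map only).
#' @param atlas integer label volume on the same grid (0 = background).
#' @param label_names optional named character vector (names = label ids).
#' @return tibble with columns label_id, label_name, n_voxels,
#'   mean_dominant, median_dominant, mean_nearest, median_nearest, q25, q75
#'   (quartiles of the dominant map); labels with no defined voxels get
#'   NA statistics.
#' @export
region_summary <- function(dominant, nearest = NULL, atlas,
                           label_names = NULL) {
  ref <- dominant %||% nearest
  stopifnot(identical(dim(atlas), ref$dim))
  labs <- sort(setdiff(unique(as.integer(atlas)), 0L))
  stat1 <- function(map, lab) {
    if (is.null(map)) return(c(NA_real_, NA_real_, NA_real_, NA_real_, 0L))
    v <- map$angle[atlas == lab]
    v <- v[!is.na(v)]
    if (!length(v)) return(c(NA_real_, NA_real_, NA_real_, NA_real_, 0L))
    c(mean(v), stats::median(v), unname(stats::quantile(v, c(0.25, 0.75))),
      length(v))
  }
  rows <- lapply(labs, function(lab) {
    d <- stat1(dominant, lab)
    nn <- stat1(nearest, lab)
    tibble::tibble(label_id = lab,
                   label_name = label_names[as.character(lab)] %|na|% paste0("label_", lab),
                   n_voxels = as.integer(max(d[5], nn[5])),
                   mean_dominant = d[1], median_dominant = d[2],
                   mean_nearest = nn[1], median_nearest = nn[2],
                   q25 = d[3], q75 = d[4])
  })
  dplyr::bind_rows(rows)
}

`%|na|%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Reorient an axial field with local Jacobians (PPD)
#'
#' Preservation of principal direction for a single axis per voxel: each
#' axis a becomes normalize(J a) under the local Jacobian J of the spatial
#' transform, so orientations follow the warp.
#'
#' @param field an `axial_field`.
#' @param jacobian either a single 3 x 3 matrix applied everywhere or an
#'   array of dim `c(dim, 3, 3)` of per-voxel Jacobians.
#' @return reoriented `axial_field`; voxels where `J a` vanishes or J is
#'   singular are marked invalid (a warning reports the count).
#' @export
ppd_reorient <- function(field, jacobian) {
  idx <- which(field$mask)
  n <- prod(field$dim)
  ax <- cbind(field$axes[idx], field$axes[idx + n], field$axes[idx + 2L * n])
  if (is.matrix(jacobian) && all(dim(jacobian) == c(3, 3))) {
    new_ax <- ax %*% t(jacobian)
  } else {
    stopifnot(identical(dim(jacobian), c(field$dim, 3L, 3L)))
    new_ax <- matrix(0, length(idx), 3)
    for (r in 1:3) for (c3 in 1:3) {
      jj <- jacobian[idx + ((c3 - 1L) * 3L + (r - 1L)) * n]
      new_ax[, r] <- new_ax[, r] + jj * ax[, c3]
    }
  }
  nrm <- sqrt(rowSums(new_ax^2))
  bad <- nrm < 1e-12
  if (any(bad)) {
    warning(sum(bad), " voxel(s) invalidated by singular Jacobian")
  }
  good <- !bad
  field_from_matrix(new_ax[good, , drop = FALSE] / nrm[good],
                    idx[good], field$dim, field$voxel_mm, field$affine)
}

#' Population mean orientation and across-subject deviation
#'
#' Per voxel with valid axes from at least two subjects: the dyadic mean
#' across subjects and the mean angular deviation of subject axes about
#' that mean (the across-subject orientation-variability map).
#'
#' @param fields list of >= 2 `axial_field`s on one common grid.
#' @param dispersion `"about-mean"` (default) or `"pairwise"` (mean
#'   pairwise angular deviation).
#' @return list with `mean` (`axial_field`), `deviation` (array, degrees,
#'   NA where < 2 subjects valid) and `n_subjects` (integer array).
#' @export
population_mean <- function(fields, dispersion = c("about-mean", "pairwise")) {
  dispersion <- match.arg(dispersion)
  if (length(fields) < 2) stop("need at least two subjects", call. = FALSE)
  dm <- fields[[1]]$dim
  for (f in fields) stopifnot(identical(f$dim, dm))
  n <- prod(dm)
  nsub <- length(fields)
  valid <- sapply(fields, function(f) as.logical(f$mask))
  count <- rowSums(valid)
  use <- which(count >= 2)
  mean_ax <- matrix(NA_real_, length(use), 3)
  dev <- array(NA_real_, dm)
  for (w in seq_along(use)) {
    v <- use[w]
    subs <- which(valid[v, ])
    ax <- t(sapply(subs, function(s) {
      c(fields[[s]]$axes[v], fields[[s]]$axes[v + n],
        fields[[s]]$axes[v + 2L * n])
    }))
    m <- dyadic_mean(ax)
    mean_ax[w, ] <- as.numeric(m)
    dev[v] <- if (dispersion == "about-mean") {
      mean_angular_deviation(ax, m)
    } else {
      pairwise_angular_deviation(ax)
    }
  }
  mf <- field_from_matrix(mean_ax, use, dm, fields[[1]]$voxel_mm,
                          fields[[1]]$affine)
  list(mean = mf, deviation = dev, n_subjects = array(as.integer(count), dm))
}
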