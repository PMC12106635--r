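#' FOD peak extraction by Newton search on the sphere
#'
#' Local maxima of the per-voxel SH series are found by ascending the
#' spherical function from a set of pre-specified seed directions with a
#' damped Newton iteration in the local tangent plane. Converged directions
#' are merged, sorted by amplitude, thresholded at 10% of the largest peak,
#' and truncated to three peaks per voxel.
#'
#' @name fod-peaks
NULL

#' Orthonormal tangent basis at each direction
#' @keywords internal
tangent_basis <- function(dirs) {
  # pick the world axis least aligned with each direction
  ref <- matrix(0, nrow(dirs), 3)
  pick <- max.col(-abs(dirs), ties.method = "first")
  ref[cbind(seq_len(nrow(dirs)), pick)] <- 1
  e1 <- ref - dirs * rowSums(ref * dirs)
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(dirs[, 2] * e1[, 3] - dirs[, 3] * e1[, 2],
              dirs[, 3] * e1[, 1] - dirs[, 1] * e1[, 3],
              dirs[, 1] * e1[, 2] - dirs[, 2] * e1[, 1])
  list(e1 = e1, e2 = e2)
}

#' Find SH peaks for a single voxel
#'
#' @param coeffs SH coefficient vector (even orders, package basis).
#' @param seeds matrix of seed directions; default 100-direction spherical
#'   Fibonacci hemisphere set. At least 60 hemisphere directions required.
#' @param max_peaks maximum number of peaks retained (default 3).
#' @param rel_threshold peaks below this fraction of the largest amplitude
#'   are discarded (default 0.1).
#' @param min_separation_deg merge radius: converged maxima closer than
#'   this are collapsed, keeping the larger (default 15).
#' @param max_iter,tol_deg Newton iteration controls: stop when the angular
#'   step drops below `tol_deg` (default 0.01 degrees) or after `max_iter`
#'   (default 50) iterations.
#' @return tibble with columns `ax`, `ay`, `az` (canonical-sign unit axis)
#'   and `amplitude`, sorted by descending amplitude (ties broken by
#'   lexicographic axis order); zero rows when no positive peak exists.
#' @export
find_sh_peaks <- function(coeffs, seeds = sphere_fibonacci(100),
                          max_peaks = 3L, rel_threshold = 0.1,
                          min_separation_deg = 15, max_iter = 50L,
                          tol_deg = 0.01) {
  if (nrow(seeds) < 60) {
    stop("need at least 60 hemisphere seed directions", call. = FALSE)
  }
  if (all(coeffs == 0)) {
    return(tibble::tibble(ax = numeric(), ay = numeric(), az = numeric(),
                          amplitude = numeric()))
  }
  lmax <- sh_lmax_for(length(coeffs))
  fval <- function(d) as.numeric(sh_basis(d, lmax) %*% coeffs)
  dirs <- axis_normalize(seeds)
  active <- rep(TRUE, nrow(dirs))
  h <- 1e-3  # radians, finite-difference step on the sphere
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    da <- dirs[active, , drop = FALSE]
    tb <- tangent_basis(da)
    na <- nrow(da)
    # 9-point stencil in the tangent plane (central differences)
    offs <- rbind(c(0, 0), c(h, 0), c(-h, 0), c(0, h), c(0, -h),
                  c(h, h), c(h, -h), c(-h, h), c(-h, -h))
    pts <- matrix(0, na * 9L, 3)
    for (s in 1:9) {
      p <- da + offs[s, 1] * tb$e1 + offs[s, 2] * tb$e2
      pts[(s - 1L) * na + seq_len(na), ] <- p / sqrt(rowSums(p^2))
    }
    fv <- matrix(fval(pts), na, 9L)
    g1 <- (fv[, 2] - fv[, 3]) / (2 * h)
    g2 <- (fv[, 4] - fv[, 5]) / (2 * h)
    h11 <- (fv[, 2] - 2 * fv[, 1] + fv[, 3]) / h^2
    h22 <- (fv[, 4] - 2 * fv[, 1] + fv[, 5]) / h^2
    h12 <- (fv[, 6] - fv[, 7] - fv[, 8] + fv[, 9]) / (4 * h^2)
    # damped Newton: fall back to gradient ascent unless H negative definite
    det_h <- h11 * h22 - h12^2
    neg_def <- (h11 < 0) & (det_h > 0)
    s1 <- ifelse(neg_def, -( h22 * g1 - h12 * g2) / det_h, 0.1 * g1)
    s2 <- ifelse(neg_def, -(-h12 * g1 + h11 * g2) / det_h, 0.1 * g2)
    sn <- sqrt(s1^2 + s2^2)
    cap <- 0.2  # radians: keep steps within the tangent-plane approximation
    scl <- ifelse(sn > cap, cap / sn, 1)
    s1 <- s1 * scl; s2 <- s2 * scl; sn <- sn * scl
    newd <- da + s1 * tb$e1 + s2 * tb$e2
    newd <- newd / sqrt(rowSums(newd^2))
    dirs[active, ] <- newd
    conv <- sn < tol_deg * pi / 180
    active[active] <- !conv
  }
  amp <- fval(dirs)
  # verify each converged direction is a local maximum: compare against a
  # small ring of neighbours (rejects walkers stalled at minima/saddles)
  tb <- tangent_basis(dirs)
  rr <- 1 * pi / 180
  ring_ok <- rep(TRUE, nrow(dirs))
  for (aang in seq(0, 2 * pi - 1e-9, by = pi / 4)) {
    p <- dirs + rr * (cos(aang) * tb$e1 + sin(aang) * tb$e2)
    p <- p / sqrt(rowSums(p^2))
    ring_ok <- ring_ok & (fval(p) <= amp + 1e-12)
  }
  keep <- amp > 0 & ring_ok
  if (!any(keep)) {
    return(tibble::tibble(ax = numeric(), ay = numeric(), az = numeric(),
                          amplitude = numeric()))
  }
  dirs <- axis_canonical(dirs[keep, , drop = FALSE])
  amp <- amp[keep]
  ord <- order(-amp, -dirs[, 1], -dirs[, 2], -dirs[, 3])
  dirs <- dirs[ord, , drop = FALSE]; amp <- amp[ord]
  sel <- integer()
  for (i in seq_along(amp)) {
    if (length(sel) == 0 ||
        all(angular_deviation(dirs[sel, , drop = FALSE], dirs[i, ]) >=
              min_separation_deg)) {
      sel <- c(sel, i)
    }
    if (length(sel) >= max_peaks) break
  }
  dirs <- dirs[sel, , drop = FALSE]; amp <- amp[sel]
  keep2 <- amp >= rel_threshold * amp[1]
  dirs <- dirs[keep2, , drop = FALSE]; amp <- amp[keep2]
  tibble::tibble(ax = dirs[, 1], ay = dirs[, 2], az = dirs[, 3],
                 amplitude = amp)
}

#' Extract FOD peaks over an SH field
#'
#' @param field an [sh_field()].
#' @param mask optional logical array restricting extraction.
#' @inheritParams find_sh_peaks
#' @return object of class `peak_field`: list with `axes`
#'   (dim `c(dim, max_peaks, 3)`), `amplitudes` (`c(dim, max_peaks)`,
#'   zero-padded, descending), `n_peaks` (integer array), `voxel_mm`,
#'   `affine`.
#' @export
extract_peaks <- function(field, mask = NULL, seeds = sphere_fibonacci(100),
                          max_peaks = 3L, rel_threshold = 0.1,
                          min_separation_deg = 15) {
  stopifnot(inherits(field, "sh_field"))
  cf <- if (identical(field$basis, "cos-first")) {
    convert_sh_basis(sh_coef_matrix(field))
  } else sh_coef_matrix(field)
  dm <- field$dim
  if (is.null(mask)) mask <- array(TRUE, dm)
  stopifnot(identical(dim(mask), dm))
  idx <- which(mask & rowSums(abs(matrix(cf, prod(dm), ncol(cf))) > 0) > 0)
  axes <- array(0, c(dm, max_peaks, 3L))
  amps <- array(0, c(dm, max_peaks))
  npk <- array(0L, dm)
  nv <- prod(dm)
  cache <- new.env(parent = emptyenv())  # phantoms repeat coefficient rows
  for (v in idx) {
    key <- paste(format(cf[v, ], digits = 12), collapse = ",")
    pk <- if (!is.null(cache[[key]])) cache[[key]] else {
      cache[[key]] <- find_sh_peaks(cf[v, ], seeds = seeds,
                                    max_peaks = max_peaks,
                                    rel_threshold = rel_threshold,
                                    min_separation_deg = min_separation_deg)
      cache[[key]]
    }
    np <- nrow(pk)
    npk[v] <- np
    if (np > 0) {
      for (p in seq_len(np)) {
        amps[v + (p - 1L) * nv] <- pk$amplitude[p]
        axes[v + (p - 1L) * nv] <- pk$ax[p]
        axes[v + (p - 1L) * nv + max_peaks * nv] <- pk$ay[p]
        axes[v + (p - 1L) * nv + 2L * max_peaks * nv] <- pk$az[p]
      }
    }
  }
  structure(list(axes = axes, amplitudes = amps, n_peaks = npk,
                 max_peaks = as.integer(max_peaks),
                 voxel_mm = field$voxel_mm, affine = field$affine,
                 dim = dm),
            class = "peak_field")
}

#' @export
print.peak_field <- function(x, ...) {
  cat("<peak_field> grid", paste(x$dim, collapse = " x "), ";",
      sum(x$n_peaks > 0), "voxels with peaks (max",
      max(x$n_peaks), "per voxel)\n")
  invisible(x)
}

#' Peak axes of one voxel
#'
#' @param peaks a `peak_field`.
#' @param i,j,k voxel indices (1-based).
#' @return matrix with one row per peak (descending amplitude) and
#'   attribute `amplitudes`; zero rows when the voxel has no peak.
#' @export
voxel_peaks <- function(peaks, i, j, k) {
  np <- peaks$n_peaks[i, j, k]
  if (np == 0) {
    out <- matrix(numeric(), 0, 3)
    attr(out, "amplitudes") <- numeric()
    return(out)
  }
  ax <- matrix(peaks$axes[i, j, k, seq_len(np), ], np, 3)
  attr(ax, "amplitudes") <- peaks$amplitudes[i, j, k, seq_len(np)]
  ax
}

#' Dominant (largest-amplitude) peak axis per voxel
#'
#' @param peaks a `peak_field`.
#' @return `axial_field` holding the first peak axis where at least one
#'   peak exists; voxels without peaks are invalid and excluded downstream.
#' @export
dominant_peak <- function(peaks) {
  dm <- peaks$dim
  idx <- which(peaks$n_peaks > 0)
  nv <- prod(dm)
  mp <- peaks$max_peaks
  ax_mat <- cbind(peaks$axes[idx],
                  peaks$axes[idx + mp * nv],
                  peaks$axes[idx + 2L * mp * nv])
  field_from_matrix(ax_mat, idx, dm, peaks$voxel_mm, peaks$affine)
}
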