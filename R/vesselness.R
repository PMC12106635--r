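#' Multiscale Frangi vesselness and Hessian tube-axis extraction
#'
#' Tube-like structures (vessels) are enhanced by eigen-analysis of the
#' scale-space Hessian: along a vessel the second derivative is near zero
#' while the two orthogonal derivatives are large. The eigenvector of the
#' smallest-magnitude eigenvalue is the local tube axis.
#'
#' @name vesselness
NULL

# -- separable Gaussian-derivative convolution (reflect padding) -----------

#' Sampled Gaussian-derivative kernel
#' @param sigma scale in voxels; order derivative order 0..2.
#' @keywords internal
gauss_kernel <- function(sigma, order = 0L) {
  r <- max(2L, ceiling(4 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  k <- switch(as.character(order),
              "0" = g,
              "1" = -x / sigma^2 * g,
              "2" = (x^2 - sigma^2) / sigma^4 * g,
              stop("order must be 0, 1 or 2"))
  # discrete derivative kernels must annihilate constants exactly
  if (order > 0) k <- k - mean(k)
  k
}

#' Convolution matrix with mirror boundary for one axis
#' @keywords internal
conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  m <- matrix(0, n, n)
  # mirror (reflect about edge samples): index p reflects to 2 - p or 2n - p
  reflect <- function(p) {
    while (any(p < 1L | p > n)) {
      p <- ifelse(p < 1L, 2L - p, p)
      p <- ifelse(p > n, 2L * n - p, p)
    }
    p
  }
  for (t in seq_along(kernel)) {
    off <- t - r - 1L
    src <- reflect(seq_len(n) + off)
    for (i in seq_len(n)) m[i, src[i]] <- m[i, src[i]] + kernel[t]
  }
  m
}

#' Separable convolution of a 3D array along one axis
#' @keywords internal
conv_axis <- function(vol, kernel, axis) {
  dm <- dim(vol)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 2, 1))
  v <- if (axis == 1L) vol else aperm(vol, perm)
  dmp <- dim(v)
  m <- conv_matrix(dmp[1], kernel)
  out <- m %*% matrix(v, dmp[1], prod(dmp[-1]))
  out <- array(out, dmp)
  if (axis == 1L) out else aperm(out, perm)
}

#' Gaussian-derivative filtering of a volume
#'
#' @param vol 3D array.
#' @param sigma_mm scale in mm.
#' @param voxel_mm length-3 voxel size in mm.
#' @param orders length-3 integer derivative orders per axis.
#' @return filtered array; derivatives are with respect to mm.
#' @keywords internal
gauss_deriv <- function(vol, sigma_mm, voxel_mm, orders) {
  voxel_mm <- rep(voxel_mm, length.out = 3)
  out <- vol
  for (ax in 1:3) {
    s_vox <- sigma_mm / voxel_mm[ax]
    k <- gauss_kernel(s_vox, orders[ax])
    out <- conv_axis(out, k, ax)
    # convert voxel-unit derivative to mm-unit derivative
    if (orders[ax] > 0) out <- out / voxel_mm[ax]^orders[ax]
  }
  out
}

#' Scale-space Hessian eigen-analysis
#'
#' Computes the Hessian by Gaussian-derivative filtering at scale
#' `sigma_mm` with gamma-normalization (multiplication by sigma^2), then
#' the per-voxel eigenvalues sorted by absolute value (|l1| <= |l2| <= |l3|)
#' and the eigenvector of l1 — the tube-axis candidate.
#'
#' @param vol 3D array, at least 5 voxels per axis, all finite.
#' @param sigma_mm positive scale in mm.
#' @param voxel_mm voxel size in mm (scalar or length 3).
#' @return list with arrays `l1`, `l2`, `l3` and axis-component arrays
#'   `v1` (dim `c(dim(vol), 3)`).
#' @export
hessian_eigen <- function(vol, sigma_mm, voxel_mm = 1) {
  if (sigma_mm <= 0) stop("sigma must be positive", call. = FALSE)
  if (any(dim(vol) < 5)) stop("volume too small (need >= 5 voxels per axis)",
                              call. = FALSE)
  if (any(!is.finite(vol))) stop("volume contains non-finite voxels",
                                 call. = FALSE)
  g2 <- sigma_mm^2
  hxx <- gauss_deriv(vol, sigma_mm, voxel_mm, c(2, 0, 0)) * g2
  hyy <- gauss_deriv(vol, sigma_mm, voxel_mm, c(0, 2, 0)) * g2
  hzz <- gauss_deriv(vol, sigma_mm, voxel_mm, c(0, 0, 2)) * g2
  hxy <- gauss_deriv(vol, sigma_mm, voxel_mm, c(1, 1, 0)) * g2
  hxz <- gauss_deriv(vol, sigma_mm, voxel_mm, c(1, 0, 1)) * g2
  hyz <- gauss_deriv(vol, sigma_mm, voxel_mm, c(0, 1, 1)) * g2
  e <- .eig3_sym(as.numeric(hxx), as.numeric(hyy), as.numeric(hzz),
                 as.numeric(hxy), as.numeric(hxz), as.numeric(hyz))
  dm <- dim(vol)
  list(l1 = array(e$l1, dm), l2 = array(e$l2, dm), l3 = array(e$l3, dm),
       v1 = array(c(e$v1x, e$v1y, e$v1z), c(dm, 3L)))
}

#' Frangi filter parameters
#'
#' @param scales Gaussian scales in mm (default suits ~0.2 mm input).
#' @param alpha plate-vs-line sensitivity (default 0.5).
#' @param beta blob sensitivity (default 0.5).
#' @param c noise sensitivity; NULL (default) uses half the maximum Hessian
#'   norm at each scale, the filter's original heuristic.
#' @param threshold vesselness cutoff in (0,1) applied after per-volume
#'   rescaling (default 0.5).
#' @return list of class `frangi_params`.
#' @export
frangi_params <- function(scales = c(0.2, 0.4, 0.8, 1.2), alpha = 0.5,
                          beta = 0.5, c = NULL, threshold = 0.5) {
  stopifnot(length(scales) >= 1, all(scales > 0), alpha > 0, beta > 0,
            threshold > 0, threshold < 1)
  structure(list(scales = scales, alpha = alpha, beta = beta, c = c,
                 threshold = threshold), class = "frangi_params")
}

#' Multiscale Frangi vesselness
#'
#' For each scale, eigenvalues (|l1| <= |l2| <= |l3|) give the ratios
#' RA = |l2|/|l3| (plate vs line), RB = |l1|/sqrt(|l2 l3|) (blob), and the
#' second-order structure norm S = sqrt(l1^2+l2^2+l3^2); the response is
#' (1-exp(-RA^2/2a^2)) * exp(-RB^2/2b^2) * (1-exp(-S^2/2c^2)), zeroed where
#' the polarity sign condition fails (dark tubes: l2, l3 > 0; bright:
#' l2, l3 < 0). `"both"` takes the voxel-wise maximum of the two polarity
#' responses. The output is the maximum over scales, recording the best
#' scale and the tube axis (l1 eigenvector) at that scale.
#'
#' @param vol 3D array (e.g. SWI contrast).
#' @param params a [frangi_params()] object.
#' @param voxel_mm voxel size in mm.
#' @param polarity `"dark"`, `"bright"`, or `"both"` (default).
#' @return object of class `vesselness_result`: list with `vesselness`
#'   (raw Frangi response in \[0,1\]), `best_scale` (mm), `axes`
#'   (dim `c(dim, 3)` tube axes), `polarity` (character array where
#'   response > 0), `voxel_mm`, `affine`.
#' @export
frangi_vesselness <- function(vol, params = frangi_params(), voxel_mm = 1,
                              polarity = c("both", "dark", "bright")) {
  polarity <- match.arg(polarity)
  dm <- dim(vol)
  best_v <- array(0, dm)
  best_scale <- array(NA_real_, dm)
  best_axes <- array(NA_real_, c(dm, 3L))
  best_pol <- array(NA_character_, dm)
  if (all(vol == vol[1])) {
    # constant (incl. all-zero) image: zero response, no error
    out <- structure(list(vesselness = best_v, best_scale = best_scale,
                          axes = best_axes, polarity = best_pol,
                          voxel_mm = rep(voxel_mm, length.out = 3),
                          affine = attr(vol, "affine") %||%
                            default_affine(voxel_mm)),
                     class = "vesselness_result")
    return(out)
  }
  a2 <- 2 * params$alpha^2
  b2 <- 2 * params$beta^2
  n <- prod(dm)
  for (s in params$scales) {
    e <- hessian_eigen(vol, s, voxel_mm)
    al1 <- abs(e$l1); al2 <- abs(e$l2); al3 <- abs(e$l3)
    S2 <- al1^2 + al2^2 + al3^2
    cc <- params$c %||% (sqrt(max(S2)) / 2)
    RA2 <- (al2 / pmax(al3, .Machine$double.xmin))^2
    RB2 <- al1^2 / pmax(al2 * al3, .Machine$double.xmin)
    base <- (1 - exp(-RA2 / a2)) * exp(-RB2 / b2) *
      (1 - exp(-S2 / (2 * cc^2)))
    base[al3 == 0] <- 0
    resp_dark <- ifelse(e$l2 > 0 & e$l3 > 0, base, 0)
    resp_bright <- ifelse(e$l2 < 0 & e$l3 < 0, base, 0)
    resp <- switch(polarity,
                   dark = resp_dark, bright = resp_bright,
                   both = pmax(resp_dark, resp_bright))
    pol <- switch(polarity,
                  dark = array("dark", dm), bright = array("bright", dm),
                  both = ifelse(resp_dark >= resp_bright, "dark", "bright"))
    upd <- which(resp > best_v)
    if (length(upd)) {
      best_v[upd] <- resp[upd]
      best_scale[upd] <- s
      best_pol[upd] <- pol[upd]
      best_axes[upd] <- e$v1[upd]
      best_axes[upd + n] <- e$v1[upd + n]
      best_axes[upd + 2L * n] <- e$v1[upd + 2L * n]
    }
  }
  structure(list(vesselness = best_v, best_scale = best_scale,
                 axes = best_axes, polarity = best_pol,
                 voxel_mm = rep(voxel_mm, length.out = 3),
                 affine = attr(vol, "affine") %||% default_affine(voxel_mm)),
            class = "vesselness_result")
}

#' @export
print.vesselness_result <- function(x, ...) {
  cat("<vesselness_result> grid", paste(dim(x$vesselness), collapse = " x "),
      "; response range", paste(signif(range(x$vesselness), 3), collapse = "–"),
      "\n")
  invisible(x)
}

#' 6-connected binary dilation
#'
#' @param mask logical 3D array.
#' @param iterations number of one-voxel dilation steps.
#' @return dilated logical array.
#' @export
dilate_mask <- function(mask, iterations = 1L) {
  dm <- dim(mask)
  shift1 <- function(m, ax, by) {
    out <- array(FALSE, dm)
    idx_src <- lapply(dm, seq_len)
    idx_dst <- idx_src
    if (by > 0) {
      idx_dst[[ax]] <- seq(1 + by, dm[ax]); idx_src[[ax]] <- seq(1, dm[ax] - by)
    } else {
      idx_dst[[ax]] <- seq(1, dm[ax] + by); idx_src[[ax]] <- seq(1 - by, dm[ax])
    }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (it in seq_len(iterations)) {
    grown <- mask
    for (ax in 1:3) for (by in c(-1L, 1L)) {
      grown <- grown | shift1(mask, ax, by)
    }
    mask <- grown
  }
  mask
}

#' Segment a vessel mask inside white matter
#'
#' Thresholds the (rescaled) vesselness response and restricts it to white
#' matter, removing voxels near gray-matter and CSF boundaries by excluding
#' the dilated GM and CSF masks (partial-volume suppression).
#'
#' @param result a `vesselness_result`.
#' @param params a [frangi_params()] (threshold is taken from here).
#' @param wm_mask logical white-matter mask on the same grid.
#' @param gm_mask,csf_mask optional logical masks; each is dilated
#'   `dilation_voxels` steps (6-connected) and excluded.
#' @param dilation_voxels dilation iterations (default 3, i.e. 600 um at
#'   0.2 mm voxels).
#' @param rescale rescale vesselness to \[0,1\] over the volume before
#'   thresholding (default TRUE).
#' @return logical vessel mask.
#' @export
segment_vessels <- function(result, params = frangi_params(), wm_mask,
                            gm_mask = NULL, csf_mask = NULL,
                            dilation_voxels = 3L, rescale = TRUE) {
  v <- result$vesselness
  stopifnot(identical(dim(wm_mask), dim(v)))
  if (!any(wm_mask)) {
    warning("empty white-matter mask: no vessels segmented")
    return(array(FALSE, dim(v)))
  }
  if (rescale && max(v) > 0) v <- v / max(v)
  mask <- (v >= params$threshold) & wm_mask
  if (!is.null(gm_mask) && any(gm_mask)) {
    mask <- mask & !dilate_mask(gm_mask, dilation_voxels)
  }
  if (!is.null(csf_mask) && any(csf_mask)) {
    mask <- mask & !dilate_mask(csf_mask, dilation_voxels)
  }
  mask
}

#' Pool vessel axes onto a coarse grid
#'
#' Downsamples the fine-grid tube axes to a coarse isotropic grid (2 mm by
#' default) by taking, within each coarse patch, the dyadic mean of the
#' axes of all vessel voxels — weighted by vesselness by default. Coarse
#' voxels whose patch holds no vessel voxel are invalid.
#'
#' @param result a `vesselness_result` (supplies axes and weights) or an
#'   `axial_field` (uniform weights).
#' @param vessel_mask logical fine-grid mask of vessel voxels.
#' @param target_voxel_mm coarse voxel size in mm (default 2).
#' @param weighting `"vesselness"` (default) or `"uniform"`.
#' @return `axial_field` on the coarse grid with extra elements `count`
#'   (vessel voxels per patch) and `degenerate` (logical array flagging
#'   patches whose dyadic tensor had tied leading eigenvalues).
#' @export
downsample_orientations <- function(result, vessel_mask, target_voxel_mm = 2,
                                    weighting = c("vesselness", "uniform")) {
  weighting <- match.arg(weighting)
  if (inherits(result, "axial_field")) {
    axes <- result$axes; voxel_mm <- result$voxel_mm
    weights_vol <- NULL; affine <- result$affine
  } else {
    axes <- result$axes; voxel_mm <- result$voxel_mm
    weights_vol <- if (weighting == "vesselness") result$vesselness else NULL
    affine <- result$affine
  }
  dm <- dim(vessel_mask)
  fac <- round(target_voxel_mm / voxel_mm)
  if (any(abs(fac * voxel_mm - target_voxel_mm) > 0.01 * target_voxel_mm)) {
    # not an integer multiple: nearest-patch binning still uses round(fac)
    fac <- pmax(1, fac)
  }
  cdim <- as.integer(ceiling(dm / fac))
  idx <- which(vessel_mask)
  ijk <- arrayInd(idx, dm)
  cijk <- 1L + (ijk - 1L) %/% matrix(fac, nrow(ijk), 3, byrow = TRUE)
  cidx <- (cijk[, 3] - 1L) * cdim[1] * cdim[2] +
    (cijk[, 2] - 1L) * cdim[1] + cijk[, 1]
  n <- prod(dm)
  ax_mat <- cbind(axes[idx], axes[idx + n], axes[idx + 2L * n])
  w <- if (is.null(weights_vol)) rep(1, length(idx)) else weights_vol[idx]
  groups <- split(seq_along(idx), cidx)
  out_idx <- as.integer(names(groups))
  out_ax <- matrix(NA_real_, length(groups), 3)
  out_deg <- logical(length(groups))
  for (g in seq_along(groups)) {
    rows <- groups[[g]]
    m <- dyadic_mean(ax_mat[rows, , drop = FALSE], w[rows])
    out_ax[g, ] <- as.numeric(m)
    out_deg[g] <- attr(m, "degenerate")
  }
  count <- array(0L, cdim)
  count[out_idx] <- lengths(groups)
  # coarse affine: coarse voxel j (0-based) centres at fine coord f*j+(f-1)/2
  shift <- rbind(cbind(diag(fac), (fac - 1) / 2), c(0, 0, 0, 1))
  caffine <- affine %*% shift
  field <- field_from_matrix(out_ax, out_idx, cdim,
                             voxel_mm * fac, caffine)
  deg <- array(FALSE, cdim)
  deg[out_idx] <- out_deg
  field$count <- count
  field$degenerate <- deg
  field
}
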