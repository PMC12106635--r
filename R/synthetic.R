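#' Synthetic ground-truth phantoms
#'
#' Generators for the three kinds of input the pipeline consumes — images
#' with dark/bright tubular structures of known orientation, SH coefficient
#' fields with 1-3 fiber populations of known axes and weights, and
#' streamline bundles with known tangents — co-registered on one voxel
#' grid, so every stage is testable against exact truth without scanner
#' data. All generators are deterministic under a fixed seed.
#'
#' @name synthetic-phantoms
NULL

#' Specify a tube (synthetic vessel)
#'
#' @param type centerline type: `"line"`, `"arc"` or `"helix"`.
#' @param point,direction for lines: a point on the axis and its direction.
#' @param center,normal,arc_radius,arc_deg for arcs: circle centre, plane
#'   normal, radius (mm) and swept angle; helices additionally use `pitch`
#'   (mm rise per turn).
#' @param radius tube radius in mm (> 0).
#' @param contrast signed intensity delta; negative = dark vessel.
#' @param profile `"gaussian"` (delta * exp(-d^2/(2 r^2))) or `"hard"`
#'   (delta inside radius).
#' @param pitch helix pitch in mm per turn.
#' @param half_length for lines: half-extent along the axis in mm
#'   (default Inf = clip to the rendered volume).
#' @return list of class `tube_spec`.
#' @export
tube_spec <- function(type = c("line", "arc", "helix"), point = c(0, 0, 0),
                      direction = c(0, 0, 1), center = c(0, 0, 0),
                      normal = c(0, 0, 1), arc_radius = 10, arc_deg = 180,
                      pitch = 5, radius = 0.4, contrast = -50,
                      profile = c("gaussian", "hard"), half_length = Inf) {
  type <- match.arg(type)
  profile <- match.arg(profile)
  stopifnot(radius > 0)
  structure(list(type = type, point = point,
                 direction = axis_normalize(direction), center = center,
                 normal = axis_normalize(normal), arc_radius = arc_radius,
                 arc_deg = arc_deg, pitch = pitch, radius = radius,
                 contrast = contrast, profile = profile,
                 half_length = half_length),
            class = "tube_spec")
}

#' Sample a tube centerline and its tangents
#' @param spec a `tube_spec`.
#' @param extent_mm curve length to cover (lines are clipped to this).
#' @param step_mm sample spacing.
#' @return list of `points` and unit `tangents` matrices.
#' @keywords internal
tube_curve <- function(spec, extent_mm, step_mm) {
  if (spec$type == "line") {
    half <- min(extent_mm, spec$half_length %||% Inf)
    t_par <- seq(-half, half, by = step_mm)
    pts <- outer(t_par, spec$direction) +
      matrix(spec$point, length(t_par), 3, byrow = TRUE)
    tans <- matrix(spec$direction, length(t_par), 3, byrow = TRUE)
  } else {
    # orthonormal frame in the circle plane
    n <- spec$normal
    a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- axis_normalize(a - n * sum(a * n))
    v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
           n[1] * u[2] - n[2] * u[1])
    ang_max <- spec$arc_deg * pi / 180
    dphi <- step_mm / spec$arc_radius
    phi <- seq(0, ang_max, by = dphi)
    pts <- matrix(spec$center, length(phi), 3, byrow = TRUE) +
      spec$arc_radius * (outer(cos(phi), u) + outer(sin(phi), v))
    tans <- -outer(sin(phi), u) + outer(cos(phi), v)
    if (spec$type == "helix") {
      rise <- spec$pitch / (2 * pi)
      pts <- pts + outer(phi * rise, n)
      tans <- spec$arc_radius * tans + matrix(rise * n, length(phi), 3,
                                              byrow = TRUE)
    }
    tans <- tans / sqrt(rowSums(tans^2))
  }
  list(points = pts, tangents = tans)
}

#' Render a tube phantom image with ground truth
#'
#' Background plus rendered tube profiles plus noise. The truth records,
#' for every voxel within a tube radius, the tangent of the nearest
#' centerline sample of the locally strongest tube.
#'
#' @param shape length-3 grid dimensions (each >= 32).
#' @param voxel_mm voxel size in mm.
#' @param tubes list of [tube_spec()]s.
#' @param background constant background intensity (default 100).
#' @param noise_sigma additive noise standard deviation (default 0).
#' @param noise `"gaussian"` (default; analytically tractable) or
#'   `"rician"` (magnitude-image noise model).
#' @param seed RNG seed (fixed for reproducibility).
#' @return list with `volume` (array with `affine`/`voxel_mm` attributes),
#'   `truth_axes` (`axial_field` of tube tangents on the tube support) and
#'   `tube_mask` (logical array, voxels within one radius of a centerline).
#' @export
make_tube_phantom <- function(shape, voxel_mm, tubes, background = 100,
                              noise_sigma = 0,
                              noise = c("gaussian", "rician"), seed = 1L) {
  noise <- match.arg(noise)
  shape <- as.integer(rep(shape, length.out = 3))
  stopifnot(all(shape >= 32))
  voxel_mm <- rep(voxel_mm, length.out = 3)
  set.seed(seed)
  vol <- array(background, shape)
  affine <- default_affine(voxel_mm)
  truth_ax <- array(NA_real_, c(shape, 3L))
  strength <- array(0, shape)   # |contribution| of the locally strongest tube
  tube_mask <- array(FALSE, shape)
  n <- prod(shape)
  extent <- max(shape * voxel_mm)
  for (spec in tubes) {
    crv <- tube_curve(spec, extent, min(voxel_mm) / 2)
    # voxels within reach of the curve bounding box
    lo <- apply(crv$points, 2, min) - 4 * spec$radius
    hi <- apply(crv$points, 2, max) + 4 * spec$radius
    rng <- lapply(1:3, function(ax) {
      seq(max(1L, floor(lo[ax] / voxel_mm[ax]) + 1L),
          min(shape[ax], ceiling(hi[ax] / voxel_mm[ax]) + 1L))
    })
    if (any(lengths(rng) == 0)) next
    ijk <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
    xyz <- voxel_to_world(ijk, affine)
    lin <- (ijk[, 3] - 1L) * shape[1] * shape[2] +
      (ijk[, 2] - 1L) * shape[1] + ijk[, 1]
    if (spec$type == "line") {
      # analytic point-line distance, clipped to the sampled extent
      rel <- xyz - matrix(spec$point, nrow(xyz), 3, byrow = TRUE)
      t_par <- rel %*% spec$direction
      half <- min(extent, spec$half_length %||% Inf)
      t_par <- pmin(pmax(t_par, -half), half)
      foot <- matrix(spec$point, nrow(xyz), 3, byrow = TRUE) +
        outer(as.numeric(t_par), spec$direction)
      d <- sqrt(rowSums((xyz - foot)^2))
      best_s <- rep(1L, nrow(xyz))   # line tangent is constant
    } else {
      # nearest curve sample per voxel, double-chunked to bound memory
      best_d2 <- rep(Inf, nrow(xyz))
      best_s <- rep(1L, nrow(xyz))
      vchunk <- 20000L
      schunk <- 512L
      for (v0 in seq(1L, nrow(xyz), by = vchunk)) {
        vs <- v0:min(v0 + vchunk - 1L, nrow(xyz))
        xv <- xyz[vs, , drop = FALSE]
        for (c0 in seq(1L, nrow(crv$points), by = schunk)) {
          cs <- c0:min(c0 + schunk - 1L, nrow(crv$points))
          cp <- crv$points[cs, , drop = FALSE]
          d2 <- matrix(rowSums(xv^2), length(vs), length(cs)) -
            2 * xv %*% t(cp) +
            matrix(rowSums(cp^2), length(vs), length(cs), byrow = TRUE)
          wmin <- max.col(-d2, ties.method = "first")
          dmin <- d2[cbind(seq_len(nrow(d2)), wmin)]
          upd <- dmin < best_d2[vs]
          best_d2[vs[upd]] <- dmin[upd]
          best_s[vs[upd]] <- cs[wmin[upd]]
        }
      }
      d <- sqrt(pmax(best_d2, 0))
    }
    contrib <- if (spec$profile == "gaussian") {
      spec$contrast * exp(-d^2 / (2 * spec$radius^2))
    } else {
      spec$contrast * (d <= spec$radius)
    }
    vol[lin] <- vol[lin] + contrib
    inside <- d <= spec$radius
    stronger <- abs(contrib) > strength[lin]
    take <- inside & stronger
    if (any(take)) {
      strength[lin[take]] <- abs(contrib[take])
      tans <- crv$tangents[best_s[take], , drop = FALSE]
      truth_ax[lin[take]] <- tans[, 1]
      truth_ax[lin[take] + n] <- tans[, 2]
      truth_ax[lin[take] + 2L * n] <- tans[, 3]
      tube_mask[lin[take]] <- TRUE
    }
  }
  if (noise_sigma > 0) {
    if (noise == "gaussian") {
      vol <- vol + array(stats::rnorm(n, 0, noise_sigma), shape)
    } else {
      vol <- sqrt((vol + array(stats::rnorm(n, 0, noise_sigma), shape))^2 +
                    array(stats::rnorm(n, 0, noise_sigma), shape)^2)
    }
  }
  attr(vol, "affine") <- affine
  attr(vol, "voxel_mm") <- voxel_mm
  truth <- axial_field(truth_ax, tube_mask, voxel_mm, affine)
  list(volume = vol, truth_axes = truth, tube_mask = tube_mask)
}

# Zonal lobe kernel: K(t) = sum_l f_l (2l+1)/(4 pi) P_l(t), f_l =
# exp(-sharpness * l (l+1)). Rotated to axis mu its SH coefficients are
# c_lm = f_l Y_lm(mu) (addition theorem), so lobes have analytic
# coefficients and their maxima sit exactly on the configured axes.

#' SH coefficients of one axially symmetric lobe
#' @keywords internal
lobe_sh_coeffs <- function(axis, lmax, sharpness) {
  lm <- sh_lm(lmax)
  fl <- exp(-sharpness * lm[, 1] * (lm[, 1] + 1))
  fl * as.numeric(sh_basis(matrix(axis, 1), lmax))
}

#' Peak amplitude of the unit lobe kernel
#' @keywords internal
lobe_peak_amplitude <- function(lmax, sharpness) {
  l <- seq(0, lmax, by = 2)
  sum(exp(-sharpness * l * (l + 1)) * (2 * l + 1) / (4 * pi))
}

#' Fiber configuration for a region
#'
#' @param axes matrix of fiber axes (one row per population, 1-3 rows) or
#'   a single 3-vector.
#' @param fractions positive volume fractions, summing to <= 1.
#' @return list of class `fiber_config`.
#' @export
fiber_config <- function(axes, fractions) {
  if (!is.matrix(axes)) axes <- matrix(axes, ncol = 3)
  axes <- axis_normalize(axes)
  stopifnot(nrow(axes) == length(fractions), all(fractions > 0),
            sum(fractions) <= 1 + 1e-9, nrow(axes) <= 3)
  if (nrow(axes) >= 2) {
    pairs <- utils::combn(nrow(axes), 2)
    seps <- angular_deviation(axes[pairs[1, ], , drop = FALSE],
                              axes[pairs[2, ], , drop = FALSE])
    if (any(seps < 30)) {
      stop("fiber populations closer than 30 degrees: truth would be ",
           "ambiguous", call. = FALSE)
    }
  }
  structure(list(axes = axes, fractions = fractions), class = "fiber_config")
}

#' Synthesize an SH field with known fiber populations
#'
#' Each region is filled with the sum of axially symmetric lobes (analytic
#' even-order SH coefficients) at the configured axes, scaled by the
#' volume fractions; the default sharpness gives a lobe FWHM of about 25
#' degrees at lmax 8. Truth peaks are the configured axes with amplitudes
#' proportional to the fractions, filtered by the 10% relative-amplitude
#' rule (populations below 10% of the largest are recorded as discarded).
#'
#' @param shape length-3 grid dimensions.
#' @param voxel_mm voxel size in mm.
#' @param regions list of entries, each a list with `mask` (logical array)
#'   and `config` (a [fiber_config()]).
#' @param lmax even degree >= 4 (default 8).
#' @param sharpness lobe concentration parameter (default 0.02; smaller =
#'   sharper lobes).
#' @param rel_threshold relative amplitude cut used for the truth peak
#'   list (default 0.1).
#' @param seed unused placeholder for interface symmetry (the generator is
#'   deterministic); kept so callers can thread one seed everywhere.
#' @return list with `field` (an [sh_field()]) and `truth` — tibble of
#'   region index, peak axes, relative amplitudes and `retained` flag.
#' @export
make_fod_field <- function(shape, voxel_mm, regions, lmax = 8,
                           sharpness = 0.02, rel_threshold = 0.1,
                           seed = 1L) {
  stopifnot(lmax %% 2 == 0, lmax >= 4)
  shape <- as.integer(rep(shape, length.out = 3))
  nc <- sh_ncoef(lmax)
  coeffs <- array(0, c(shape, nc))
  n <- prod(shape)
  truth <- list()
  for (r in seq_along(regions)) {
    reg <- regions[[r]]
    stopifnot(identical(dim(reg$mask), shape),
              inherits(reg$config, "fiber_config"))
    cf <- numeric(nc)
    for (p in seq_len(nrow(reg$config$axes))) {
      cf <- cf + reg$config$fractions[p] *
        lobe_sh_coeffs(reg$config$axes[p, ], lmax, sharpness)
    }
    idx <- which(reg$mask)
    for (j in seq_len(nc)) coeffs[idx + (j - 1L) * n] <- cf[j]
    fr <- reg$config$fractions
    truth[[r]] <- tibble::tibble(
      region = r,
      peak = seq_along(fr),
      ax = reg$config$axes[, 1], ay = reg$config$axes[, 2],
      az = reg$config$axes[, 3],
      rel_amplitude = fr / max(fr),
      retained = fr / max(fr) >= rel_threshold)
  }
  list(field = sh_field(coeffs, lmax, voxel_mm),
       truth = dplyr::bind_rows(truth))
}

#' Generate a streamline bundle with known tangents
#'
#' Streamlines are rigid offsets of a centerline with Gaussian
#' cross-section jitter (offsets orthogonal to the start tangent), all
#' ordered beginning-to-end.
#'
#' @param spec a [tube_spec()] describing the centerline (radius/contrast
#'   ignored).
#' @param n_streamlines number of streamlines (>= 1).
#' @param cross_section_sigma_mm jitter standard deviation (0 = exact
#'   copies of the centerline).
#' @param step_mm point spacing along the centerline.
#' @param extent_mm half-length for line centerlines.
#' @param seed RNG seed.
#' @return list with `bundle` (a `streamline_bundle`) and `tangents`
#'   (matrix of analytic unit tangents at the centerline points).
#' @export
make_bundle <- function(spec, n_streamlines = 20L,
                        cross_section_sigma_mm = 0.5, step_mm = 1,
                        extent_mm = 40, seed = 1L) {
  stopifnot(n_streamlines >= 1)
  set.seed(seed)
  crv <- tube_curve(spec, extent_mm, step_mm)
  t0 <- crv$tangents[1, ]
  streamlines <- lapply(seq_len(n_streamlines), function(i) {
    off <- stats::rnorm(3, 0, cross_section_sigma_mm)
    off <- off - t0 * sum(off * t0)   # keep offsets in the cross-section
    crv$points + matrix(off, nrow(crv$points), 3, byrow = TRUE)
  })
  list(bundle = streamline_bundle(streamlines, "synthetic"),
       tangents = crv$tangents)
}

#' End-to-end crossing scenario with ground truth
#'
#' Builds one co-registered phantom realizing the pipeline's headline
#' contrast: vessels need not align with the dominant fiber direction yet
#' may align with a secondary population in the same voxel. Three blocks
#' along x share one grid:
#' \itemize{
#'   \item parallel region — single fiber population along z, tubes along
#'     z (dominant = nearest = 0);
#'   \item crossing region — dominant population along x (fraction 0.65)
#'     plus a secondary population at `crossing_deg` from x in the x-y
#'     plane (fraction 0.35), tubes laid along the secondary axis
#'     (nearest = 0, dominant = `crossing_deg`);
#'   \item orthogonal region — single population along x, tubes along z
#'     (dominant = nearest = 90).
#' }
#'
#' @param seed RNG seed for tube noise.
#' @param fine_voxel_mm SWI-grid voxel size (default 0.5 mm).
#' @param coarse_voxel_mm pooled orientation grid (default 2 mm).
#' @param shape fine-grid dimensions (default c(96, 48, 48)).
#' @param crossing_deg designed crossing angle (default 60).
#' @param snr tube contrast-to-noise ratio (default 10).
#' @param lmax SH degree of the FOD field (default 8).
#' @return list with the co-registered inputs (`swi`, `sh`, `wm_mask`,
#'   `gm_mask`, `csf_mask`, `atlas`, `bundle`) and `truth` (region table
#'   of designed dominant/nearest angles, fine-grid tube axes, bundle
#'   tangents, region label meanings).
#' @export
make_crossing_scenario <- function(seed = 1L, fine_voxel_mm = 0.5,
                                   coarse_voxel_mm = 2,
                                   shape = c(96L, 48L, 48L),
                                   crossing_deg = 60, snr = 10, lmax = 8) {
  shape <- as.integer(rep(shape, length.out = 3))
  voxel_mm <- rep(fine_voxel_mm, 3)
  fov <- shape * voxel_mm
  third <- fov[1] / 3
  contrast <- -50
  # secondary fiber axis: crossing_deg from x in the x-y plane
  sec <- c(cos(crossing_deg * pi / 180), sin(crossing_deg * pi / 180), 0)
  # tubes: a planar grid of parallel lines per region, clear of region edges
  line_at <- function(p, d) tube_spec("line", point = p, direction = d,
                                      radius = 1.6 * fine_voxel_mm,
                                      contrast = contrast)
  margin <- 6 * fine_voxel_mm
  offsets <- seq(margin, fov[2] - margin, by = 6 * fine_voxel_mm)
  z_offsets <- seq(margin, fov[3] - margin, by = 6 * fine_voxel_mm)
  tubes <- list()
  for (oy in offsets) {
    # region 1 (parallel): tubes along z
    tubes <- c(tubes, list(line_at(c(third * 0.5, oy, fov[3] / 2),
                                   c(0, 0, 1))))
    # region 3 (orthogonal): tubes along z
    tubes <- c(tubes, list(line_at(c(third * 2.5, oy, fov[3] / 2),
                                   c(0, 0, 1))))
  }
  for (oz in z_offsets) {
    # region 2 (crossing): tubes along the secondary axis, clipped so they
    # stay inside the crossing slab
    tb <- line_at(c(third * 1.5, fov[2] / 2, oz), sec)
    tb$half_length <- min((third / 2 - 2) / abs(sec[1]),
                          (fov[2] / 2 - 2) / abs(sec[2]))
    tubes <- c(tubes, list(tb))
  }
  phantom <- make_tube_phantom(shape, voxel_mm, tubes,
                               background = 100,
                               noise_sigma = abs(contrast) / snr,
                               seed = seed)
  # clip tube truth/support to each region's slab so axes stay in-region
  xs <- (seq_len(shape[1]) - 1) * voxel_mm[1]
  region_of_x <- findInterval(xs, c(0, third, 2 * third)) # 1, 2, 3
  # array() recycling repeats the x-profile over y and z (column-major)
  region_vol <- array(as.integer(region_of_x), shape)
  # masks: WM = interior box; GM/CSF shells at the y faces
  wm <- array(FALSE, shape)
  wm[, 3:(shape[2] - 2), 3:(shape[3] - 2)] <- TRUE
  gm <- array(FALSE, shape); gm[, 1:2, ] <- TRUE
  csf <- array(FALSE, shape); csf[, (shape[2] - 1):shape[2], ] <- TRUE
  # coarse-grid atlas of the three regions
  fac <- round(coarse_voxel_mm / fine_voxel_mm)
  cdim <- as.integer(ceiling(shape / fac))
  # coarse voxel centres in fine-grid world coordinates
  cx <- ((seq_len(cdim[1]) - 1) * fac + (fac - 1) / 2) * voxel_mm[1]
  atlas <- array(as.integer(findInterval(cx, c(0, third, 2 * third))), cdim)
  # bundle: straight line along x through the crossing region centre —
  # parallel to vessels in regions 1/3 (tubes along z? no: tangent is x)
  bund <- make_bundle(tube_spec("line",
                                point = c(fov[1] / 2, fov[2] / 2, fov[3] / 2),
                                direction = c(1, 0, 0)),
                      n_streamlines = 20L, cross_section_sigma_mm = 1,
                      step_mm = fine_voxel_mm, extent_mm = fov[1] / 2 - 1,
                      seed = seed + 1L)
  regions_sh <- list(
    list(mask = region_vol == 1,
         config = fiber_config(c(0, 0, 1), 1)),
    list(mask = region_vol == 2,
         config = fiber_config(rbind(c(1, 0, 0), sec), c(0.65, 0.35))),
    list(mask = region_vol == 3,
         config = fiber_config(c(1, 0, 0), 1)))
  # FOD field lives on the coarse grid (diffusion resolution)
  cregions_sh <- lapply(1:3, function(r) {
    list(mask = atlas == r, config = regions_sh[[r]]$config)
  })
  shift <- rbind(cbind(diag(rep(fac, 3)), rep((fac - 1) / 2, 3)),
                 c(0, 0, 0, 1))
  caffine <- default_affine(voxel_mm) %*% shift
  fod <- make_fod_field(cdim, voxel_mm * fac, cregions_sh, lmax = lmax,
                        seed = seed)
  fod$field$affine <- caffine
  truth_regions <- tibble::tibble(
    label = 1:3,
    name = c("parallel", "crossing", "orthogonal"),
    dominant_deg = c(0, crossing_deg, 90),
    nearest_deg = c(0, 0, 90))
  list(swi = phantom$volume,
       sh = fod$field,
       wm_mask = wm, gm_mask = gm, csf_mask = csf,
       atlas = atlas,
       bundle = bund$bundle,
       fine_voxel_mm = voxel_mm,
       coarse_voxel_mm = voxel_mm * fac,
       coarse_affine = caffine,
       truth = list(regions = truth_regions,
                    tube_axes = phantom$truth_axes,
                    tube_mask = phantom$tube_mask,
                    region_vol = region_vol,
                    fod_peaks = fod$truth,
                    bundle_tangents = bund$tangents))
}
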