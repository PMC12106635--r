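# hand-built fields on a tiny grid for direct checks
mini_vessels <- function(axes_list, dm = c(2L, 2L, 1L)) {
  axes <- array(NA_real_, c(dm, 3)); mask <- array(FALSE, dm)
  for (nm in names(axes_list)) {
    idx <- as.integer(strsplit(nm, ",")[[1]])
    mask[idx[1], idx[2], idx[3]] <- TRUE
    axes[idx[1], idx[2], idx[3], ] <- axes_list[[nm]]
  }
  axial_field(axes, mask, 2)
}

mini_peaks <- function(peaks_list, dm = c(2L, 2L, 1L), mp = 3L) {
  axes <- array(0, c(dm, mp, 3)); amps <- array(0, c(dm, mp))
  npk <- array(0L, dm)
  for (nm in names(peaks_list)) {
    idx <- as.integer(strsplit(nm, ",")[[1]])
    pl <- peaks_list[[nm]]
    npk[idx[1], idx[2], idx[3]] <- length(pl)
    for (p in seq_along(pl)) {
      axes[idx[1], idx[2], idx[3], p, ] <- pl[[p]]$axis
      amps[idx[1], idx[2], idx[3], p] <- pl[[p]]$amp
    }
  }
  structure(list(axes = axes, amplitudes = amps, n_peaks = npk,
                 max_peaks = mp, voxel_mm = rep(2, 3),
                 affine = diag(c(2, 2, 2, 1)), dim = dm),
            class = "peak_field")
}

test_that("dominant and nearest maps use the right peak per voxel", {
  v <- mini_vessels(list("1,1,1" = c(0, 0, 1), "2,1,1" = c(0, 0, 1)))
  p <- mini_peaks(list(
    "1,1,1" = list(list(axis = c(0, 0, 1), amp = 1)),
    "2,1,1" = list(list(axis = c(1, 0, 0), amp = 1),
                   list(axis = c(0, 0, 1), amp = 0.6)),
    "1,2,1" = list(list(axis = c(1, 0, 0), amp = 1))))
  dom <- dominant_angle_map(v, p)
  near <- nearest_angle_map(v, p)
  expect_equal(dom$angle[1, 1, 1], 0)
  expect_equal(dom$angle[2, 1, 1], 90)   # dominant is x, vessel z
  expect_equal(near$angle[2, 1, 1], 0)   # nearest is the secondary z peak
  expect_true(is.na(dom$angle[1, 2, 1])) # no vessel axis there
  expect_true(is.na(dom$angle[2, 2, 1])) # neither side defined
  # single-peak voxel: nearest equals dominant
  expect_equal(near$angle[1, 1, 1], dom$angle[1, 1, 1])
})

test_that("nearest angle never exceeds dominant angle", {
  set.seed(41)
  dm <- c(4L, 4L, 3L)
  axes <- array(NA_real_, c(dm, 3)); mask <- array(TRUE, dm)
  pax <- array(0, c(dm, 3, 3)); pam <- array(0, c(dm, 3))
  npk <- array(0L, dm)
  for (v in seq_len(prod(dm))) {
    ijk <- arrayInd(v, dm)
    a <- runif_axis()
    axes[ijk[1], ijk[2], ijk[3], ] <- a
    np <- sample(1:3, 1)
    npk[v] <- np
    amps <- sort(stats::runif(np, 0.2, 1), decreasing = TRUE)
    for (pp in seq_len(np)) {
      pax[ijk[1], ijk[2], ijk[3], pp, ] <- runif_axis()
      pam[ijk[1], ijk[2], ijk[3], pp] <- amps[pp]
    }
  }
  vf <- axial_field(axes, mask, 2)
  pf <- structure(list(axes = pax, amplitudes = pam, n_peaks = npk,
                       max_peaks = 3L, voxel_mm = rep(2, 3),
                       affine = diag(c(2, 2, 2, 1)), dim = dm),
                  class = "peak_field")
  dom <- dominant_angle_map(vf, pf)
  near <- nearest_angle_map(vf, pf)
  expect_true(all(near$angle <= dom$angle + 1e-12))
  expect_true(all(dom$angle >= 0 & dom$angle <= 90))
  expect_true(all(near$angle >= 0 & near$angle <= 90))
})

test_that("angle histogram bins and summarizes correctly", {
  dm <- c(3L, 3L, 1L)
  ang <- array(45, dm)
  map <- vasofiber:::angle_map_new(ang, diag(4), rep(2, 3), "dominant")
  h <- angle_histogram(map, bin_width_deg = 2)
  expect_equal(sum(h$count), 9)
  expect_equal(sum(h$count > 0), 1)
  expect_equal(attr(h, "mean"), 45)
  expect_equal(attr(h, "median"), 45)
  expect_equal(attr(h, "mode"), 45)
  # uniform angles: mean near 45
  set.seed(43)
  u <- array(stats::runif(8000, 0, 90), c(20, 20, 20))
  map_u <- vasofiber:::angle_map_new(u, diag(4), rep(2, 3), "dominant")
  h_u <- angle_histogram(map_u)
  expect_equal(attr(h_u, "mean"), 45, tolerance = 0.05)
  # bimodal mixture: both designed modes recovered
  bim <- array(c(stats::rnorm(4000, 20, 2), stats::rnorm(4000, 70, 2)),
               c(20, 20, 20))
  bim <- pmin(pmax(bim, 0), 90)
  map_b <- vasofiber:::angle_map_new(bim, diag(4), rep(2, 3), "dominant")
  h_b <- angle_histogram(map_b, bin_width_deg = 2)
  top_two <- h_b$bin_mid[order(-h_b$count)][1:4]
  expect_true(any(abs(top_two - 20) <= 3))
  expect_true(any(abs(top_two - 70) <= 3))
  # empty map
  empty <- vasofiber:::angle_map_new(array(NA_real_, dm), diag(4),
                                     rep(2, 3), "dominant")
  h_e <- angle_histogram(empty)
  expect_equal(sum(h_e$count), 0)
  expect_true(is.na(attr(h_e, "mean")))
})

test_that("region summary aggregates per label with missing handling", {
  dm <- c(4L, 4L, 2L)
  ang <- array(NA_real_, dm)
  atlas <- array(0L, dm)
  atlas[1:2, , ] <- 1L; atlas[3:4, , ] <- 2L
  ang[1:2, , ] <- 10; ang[3:4, , ] <- 80
  dmap <- vasofiber:::angle_map_new(ang, diag(4), rep(2, 3), "dominant")
  rs <- region_summary(dmap, NULL, atlas)
  expect_equal(rs$mean_dominant, c(10, 80), tolerance = 1e-9)
  # one label covering everything equals the global stats
  rs_all <- region_summary(dmap, NULL, array(1L, dm))
  expect_equal(rs_all$mean_dominant, mean(ang, na.rm = TRUE))
  expect_equal(rs_all$median_dominant, stats::median(ang, na.rm = TRUE))
  # label fully outside the valid mask: zero count, NA stats
  ang2 <- ang; ang2[3:4, , ] <- NA
  dmap2 <- vasofiber:::angle_map_new(ang2, diag(4), rep(2, 3), "dominant")
  rs2 <- region_summary(dmap2, NULL, atlas)
  expect_equal(rs2$n_voxels[rs2$label_id == 2], 0L)
  expect_true(is.na(rs2$mean_dominant[rs2$label_id == 2]))
})

test_that("PPD reorientation follows the Jacobian", {
  set.seed(47)
  dm <- c(4L, 4L, 2L)
  axes <- array(NA_real_, c(dm, 3)); mask <- array(TRUE, dm)
  for (v in seq_len(prod(dm))) {
    ijk <- arrayInd(v, dm)
    axes[ijk[1], ijk[2], ijk[3], ] <- runif_axis()
  }
  f <- axial_field(axes, mask, 2)
  # identity leaves the field unchanged
  f_id <- ppd_reorient(f, diag(3))
  expect_equal(f_id$axes[f_id$mask], f$axes[f$mask], tolerance = 1e-12)
  # a global rotation rotates every axis exactly and preserves angles
  R <- rot_axis_angle(c(1, 2, 0.5), 33)
  f_rot <- ppd_reorient(f, R)
  a0 <- field_axes_matrix(f)
  a1 <- field_axes_matrix(f_rot)
  expect_equal(a1, a0 %*% t(R), tolerance = 1e-12)
  pair_dev0 <- angular_deviation(a0[1:10, ], a0[11:20, ])
  pair_dev1 <- angular_deviation(a1[1:10, ], a1[11:20, ])
  expect_equal(pair_dev1, pair_dev0, tolerance = 1e-6)
  # anisotropic scaling: hand-computable case
  g <- mini_vessels(list("1,1,1" = c(1, 1, 0) / sqrt(2)))
  g_s <- ppd_reorient(g, diag(c(2, 1, 1)))
  expect_equal(g_s$axes[1, 1, 1, ], c(2, 1, 0) / sqrt(5), tolerance = 1e-12)
})

test_that("singular Jacobians invalidate voxels with a warning", {
  g <- mini_vessels(list("1,1,1" = c(0, 0, 1), "2,1,1" = c(1, 0, 0)))
  J <- diag(c(1, 1, 0))  # kills the z axis
  expect_warning(out <- ppd_reorient(g, J), "singular")
  expect_false(out$mask[1, 1, 1])
  expect_true(out$mask[2, 1, 1])
})

test_that("population mean recovers shared orientation and dispersion", {
  v1 <- mini_vessels(list("1,1,1" = c(0, 0, 1)))
  v2 <- mini_vessels(list("1,1,1" = c(0, 0, -1)))  # same axis, flipped sign
  pop <- population_mean(list(v1, v2))
  expect_equal(abs(pop$mean$axes[1, 1, 1, ]), c(0, 0, 1), tolerance = 1e-9)
  expect_equal(pop$deviation[1, 1, 1], 0, tolerance = 1e-6)
  # two subjects at x and y: symmetric 45-degree case
  px <- mini_vessels(list("1,1,1" = c(1, 0, 0)))
  py <- mini_vessels(list("1,1,1" = c(0, 1, 0)))
  pop2 <- population_mean(list(px, py))
  expect_equal(pop2$deviation[1, 1, 1], 45, tolerance = 1e-6)
  expect_error(population_mean(list(v1)), "two subjects")
  # voxels valid in < 2 subjects stay invalid
  v3 <- mini_vessels(list("2,1,1" = c(1, 0, 0)))
  pop3 <- population_mean(list(v1, v3))
  expect_false(pop3$mean$mask[1, 1, 1])
  expect_false(pop3$mean$mask[2, 1, 1])
})

test_that("population mean recovers a cone-dispersed axis within 5 degrees", {
  truth <- axis_normalize(c(0.3, -0.2, 0.93))
  cone <- cone_axes(truth, 15, 6)  # 6 subjects at exactly 15 deg
  subs <- lapply(seq_len(6), function(s) {
    mini_vessels(list("1,1,1" = cone[s, ]))
  })
  pop <- population_mean(subs)
  expect_lt(angular_deviation(pop$mean$axes[1, 1, 1, ], truth), 5)
  # symmetric cone at alpha: deviation about the mean equals alpha
  expect_equal(pop$deviation[1, 1, 1], 15, tolerance = 0.5)
  # subject order and per-subject sign flips leave the result unchanged
  subs_flip <- lapply(rev(seq_len(6)), function(s) {
    mini_vessels(list("1,1,1" = -cone[s, ]))
  })
  pop2 <- population_mean(subs_flip)
  expect_equal(abs(pop2$mean$axes[1, 1, 1, ]),
               abs(pop$mean$axes[1, 1, 1, ]), tolerance = 1e-9)
  expect_equal(pop2$deviation[1, 1, 1], pop$deviation[1, 1, 1],
               tolerance = 1e-9)
})

test_that("pairwise dispersion option is exposed", {
  px <- mini_vessels(list("1,1,1" = c(1, 0, 0)))
  py <- mini_vessels(list("1,1,1" = c(0, 1, 0)))
  pop <- population_mean(list(px, py), dispersion = "pairwise")
  expect_equal(pop$deviation[1, 1, 1], 90)
})
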