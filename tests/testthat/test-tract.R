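test_that("streamline resampling is equidistant and endpoint-preserving", {
  seg <- rbind(c(0, 0, 0), c(99, 0, 0))
  rs <- resample_streamline(seg, 100)
  expect_equal(nrow(rs), 100)
  expect_equal(diff(rs[, 1]), rep(1, 99), tolerance = 1e-12)
  rs2 <- resample_streamline(seg, 2)
  expect_equal(rs2, seg)
  # semicircle: chord-sum arc length within 0.1% of pi r
  r <- 10
  th <- seq(0, pi, length.out = 400)
  semi <- cbind(r * cos(th), r * sin(th), 0)
  rs3 <- resample_streamline(semi, 100)
  chord <- sum(sqrt(rowSums(diff(rs3)^2)))
  expect_lt(abs(chord - pi * r) / (pi * r), 0.001)
  expect_warning(out <- resample_streamline(rbind(c(1, 1, 1), c(1, 1, 1))),
                 "zero-length")
  expect_null(out)
})

test_that("voxel orientation from streamlines follows tangents", {
  # one straight streamline along x
  pts <- cbind(seq(0.5, 15.5, by = 0.25), 4, 4)
  b <- streamline_bundle(list(pts))
  f <- voxel_streamline_orientation(b, c(16, 8, 8), 1)
  idx <- which(f$mask)
  expect_gt(length(idx), 10)
  ax <- field_axes_matrix(f)
  expect_true(all(angular_deviation(ax, c(1, 0, 0)) < 1e-6))
  # antiparallel pair gives the same axis
  b2 <- streamline_bundle(list(pts, pts[rev(seq_len(nrow(pts))), ]))
  f2 <- voxel_streamline_orientation(b2, c(16, 8, 8), 1)
  ax2 <- field_axes_matrix(f2)
  expect_true(all(angular_deviation(ax2, c(1, 0, 0)) < 1e-6))
})

test_that("bent-bundle voxel axes follow the local analytic tangent", {
  # quarter arc of radius 12 in the xy plane
  th <- seq(0, pi / 2, length.out = 200)
  r <- 12
  pts <- cbind(16 + r * cos(th), 4 + r * sin(th), 4)
  b <- streamline_bundle(list(pts))
  f <- voxel_streamline_orientation(b, c(32, 20, 8), 1)
  idx <- which(f$mask)
  ijk <- arrayInd(idx, f$dim)
  xyz <- vasofiber:::voxel_to_world(ijk, f$affine)
  n <- prod(f$dim)
  ax <- cbind(f$axes[idx], f$axes[idx + n], f$axes[idx + 2 * n])
  for (w in seq_along(idx)) {
    # analytic tangent at the arc angle nearest this voxel
    ang <- atan2(xyz[w, 2] - 4, xyz[w, 1] - 16)
    tan_true <- c(-sin(ang), cos(ang), 0)
    expect_lt(angular_deviation(ax[w, ], tan_true), 10)
  }
})

test_that("orientation is stable under streamline supersampling", {
  th <- seq(0, pi / 2, length.out = 100)
  pts <- cbind(16 + 12 * cos(th), 4 + 12 * sin(th), 4)
  pts2 <- resample_streamline(pts, 200)  # 2x supersampled
  f1 <- voxel_streamline_orientation(streamline_bundle(list(pts)),
                                     c(32, 20, 8), 1)
  f2 <- voxel_streamline_orientation(streamline_bundle(list(pts2)),
                                     c(32, 20, 8), 1)
  common <- which(f1$mask & f2$mask)
  n <- prod(f1$dim)
  a1 <- cbind(f1$axes[common], f1$axes[common + n], f1$axes[common + 2 * n])
  a2 <- cbind(f2$axes[common], f2$axes[common + n], f2$axes[common + 2 * n])
  expect_true(all(angular_deviation(a1, a2) < 2))
})

# vessel field constant along x, with an orthogonal middle third
three_zone_vessels <- function(dm = c(60L, 10L, 10L), voxel = 1) {
  axes <- array(NA_real_, c(dm, 3)); mask <- array(TRUE, dm)
  third <- dm[1] / 3
  for (i in seq_len(dm[1])) {
    a <- if (i > third && i <= 2 * third) c(0, 0, 1) else c(1, 0, 0)
    axes[i, , , 1] <- a[1]; axes[i, , , 2] <- a[2]; axes[i, , , 3] <- a[3]
  }
  axial_field(axes, mask, voxel)
}

test_that("along-tract profiles have exactly n segments with the designed shape", {
  vessels <- three_zone_vessels()
  mk <- make_bundle(tube_spec("line", point = c(30, 5, 5),
                              direction = c(1, 0, 0)),
                    n_streamlines = 10, cross_section_sigma_mm = 0.8,
                    step_mm = 0.5, extent_mm = 28, seed = 8)
  pr <- along_tract_profile(mk$bundle, vessels, n_segments = 100)
  expect_equal(nrow(pr), 100)
  expect_equal(pr$segment, 1:100)
  ok <- !is.na(pr$mean_angle)
  expect_true(all(pr$mean_angle[ok] >= 0 & pr$mean_angle[ok] <= 90))
  # bundle parallel to vessels in outer thirds, orthogonal in the middle
  expect_lt(mean(pr$mean_angle[1:30], na.rm = TRUE), 10)
  expect_gt(mean(pr$mean_angle[40:60], na.rm = TRUE), 80)
  expect_lt(mean(pr$mean_angle[71:100], na.rm = TRUE), 10)
  # zone-weighted bundle mean
  expect_equal(bundle_mean_angle(pr),
               mean(pr$mean_angle, na.rm = TRUE))
  # parallel-everywhere bundle: profile ~ 0 throughout
  uni <- three_zone_vessels()
  uni$axes[, , , 1] <- 1; uni$axes[, , , 2] <- 0; uni$axes[, , , 3] <- 0
  pr0 <- along_tract_profile(mk$bundle, uni, n_segments = 100)
  expect_lt(max(pr0$mean_angle, na.rm = TRUE), 5)
})

test_that("reversing every streamline reverses the segment index only", {
  vessels <- three_zone_vessels()
  # asymmetric vessel field so reversal is detectable
  vessels$axes[1:10, , , ] <- 0
  vessels$axes[1:10, , , 3] <- 1
  mk <- make_bundle(tube_spec("line", point = c(30, 5, 5),
                              direction = c(1, 0, 0)),
                    n_streamlines = 5, cross_section_sigma_mm = 0.5,
                    step_mm = 0.5, extent_mm = 28, seed = 9)
  pr_fwd <- along_tract_profile(mk$bundle, vessels, reorient = FALSE)
  rev_bundle <- streamline_bundle(lapply(mk$bundle$streamlines, function(s) {
    s[rev(seq_len(nrow(s))), , drop = FALSE]
  }))
  pr_rev <- along_tract_profile(rev_bundle, vessels, reorient = FALSE)
  expect_equal(pr_rev$mean_angle, rev(pr_fwd$mean_angle), tolerance = 1e-9)
  expect_equal(pr_rev$n, rev(pr_fwd$n))
})

test_that("bundles outside the vessel field warn and return missing", {
  vessels <- three_zone_vessels(c(10L, 10L, 10L))
  vessels$mask[] <- FALSE
  pts <- cbind(seq(1, 9, by = 0.5), 5, 5)
  b <- streamline_bundle(list(pts))
  expect_warning(pr <- along_tract_profile(b, vessels), "outside")
  expect_true(all(is.na(pr$mean_angle)))
  expect_true(is.na(bundle_mean_angle(pr)))
})

test_that("bundle orientation enforcement flips stragglers", {
  fwd <- cbind(seq(0, 10), 0, 0)
  bwd <- fwd[rev(seq_len(nrow(fwd))), ]
  b <- streamline_bundle(list(fwd, fwd, bwd))
  ob <- orient_bundle(b)
  starts <- t(sapply(ob$streamlines, function(s) s[1, ]))
  expect_lt(max(stats::dist(starts)), 1e-9)  # all share the same start end
})

test_that("profile TSV round trip preserves values", {
  vessels <- three_zone_vessels()
  mk <- make_bundle(tube_spec("line", point = c(30, 5, 5),
                              direction = c(1, 0, 0)),
                    n_streamlines = 3, cross_section_sigma_mm = 0.5,
                    step_mm = 1, extent_mm = 25, seed = 10)
  pr <- along_tract_profile(mk$bundle, vessels)
  path <- tempfile(fileext = ".tsv")
  write_tract_profile(pr, path)
  pr2 <- read_tract_profile(path)
  expect_equal(pr2$mean_angle, pr$mean_angle, tolerance = 1e-9)
  expect_equal(pr2$n, pr$n)
})
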