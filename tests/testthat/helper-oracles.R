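# Independent oracles used across the test files. Each oracle is a separate
# implementation path from the package code it checks.

# --- direct-sum real SH evaluation (independent of the package recursion) --
# Unnormalized associated Legendre P_l^m WITHOUT Condon-Shortley phase, via
# the explicit derivative-free recurrence on unnormalized functions with
# exact factorial normalization applied afterwards.
oracle_assoc_legendre <- function(l, m, x) {
  # P_m^m = (2m-1)!! (1-x^2)^{m/2}
  pmm <- rep(1, length(x))
  if (m > 0) {
    somx2 <- sqrt(pmax(0, 1 - x^2))
    fact <- 1
    for (i in seq_len(m)) {
      pmm <- pmm * fact * somx2
      fact <- fact + 2
    }
  }
  if (l == m) return(pmm)
  pmmp1 <- x * (2 * m + 1) * pmm
  if (l == m + 1) return(pmmp1)
  for (ll in (m + 2):l) {
    pll <- ((2 * ll - 1) * x * pmmp1 - (ll + m - 1) * pmm) / (ll - m)
    pmm <- pmmp1
    pmmp1 <- pll
  }
  pmmp1
}

# real SH in the package's declared convention, evaluated by direct sums
oracle_sh_value <- function(coeffs, dir) {
  lmax <- (sqrt(8 * length(coeffs) + 1) - 3) / 2
  dir <- dir / sqrt(sum(dir^2))
  ct <- dir[3]
  phi <- atan2(dir[2], dir[1])
  val <- 0
  j <- 0
  for (l in seq(0, lmax, by = 2)) {
    for (m in -l:l) {
      j <- j + 1
      am <- abs(m)
      nfac <- sqrt((2 * l + 1) / (4 * pi) *
                     exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      plm_cs <- (-1)^am * oracle_assoc_legendre(l, am, ct)  # with CS phase
      y <- if (m < 0) {
        sqrt(2) * (-1)^am * nfac * plm_cs * sin(am * phi)
      } else if (m == 0) {
        nfac * plm_cs
      } else {
        sqrt(2) * (-1)^am * nfac * plm_cs * cos(am * phi)
      }
      val <- val + coeffs[j] * y
    }
  }
  val
}

# --- dense-grid argmax oracle for SH peak locations ------------------------
oracle_grid_peaks <- function(coeffs, n_grid = 10242, n_peaks = Inf,
                              sep_deg = 15, nbr_deg = 8) {
  grid <- sphere_fibonacci(n_grid, hemisphere = TRUE)
  amp <- sh_amplitude(coeffs, grid)
  # candidates: every grid point that could be a retained peak
  cand <- which(amp >= max(0.08 * max(amp), 0))
  cand <- cand[order(-amp[cand])]
  if (length(cand) > 3000) cand <- cand[1:3000]
  thr <- cos(nbr_deg * pi / 180)
  is_max <- logical(length(cand))
  for (i in seq_along(cand)) {
    # antipodally symmetric neighbourhood on the hemisphere grid
    dots <- abs(grid %*% grid[cand[i], ])
    nb <- which(dots >= thr)
    is_max[i] <- all(amp[cand[i]] >= amp[nb])
  }
  maxima <- cand[is_max]
  # merge grid-resolution duplicates, keeping the larger amplitude
  sel <- integer()
  for (i in maxima) {
    if (length(sel) == 0 ||
        all(angular_deviation(grid[sel, , drop = FALSE], grid[i, ]) >=
              sep_deg)) {
      sel <- c(sel, i)
    }
    if (length(sel) >= n_peaks) break
  }
  list(axes = grid[sel, , drop = FALSE], amplitudes = amp[sel])
}

# --- grid search over the sphere minimizing mean squared angular deviation -
oracle_axial_mean_gridsearch <- function(axes, n_grid = 20000) {
  grid <- sphere_fibonacci(n_grid, hemisphere = TRUE)
  cost <- vapply(seq_len(nrow(grid)), function(i) {
    mean(angular_deviation(axes, grid[i, ])^2)
  }, numeric(1))
  grid[which.min(cost), ]
}

# --- analytic cone sampler: n axes at exactly alpha degrees around ref -----
cone_axes <- function(ref, alpha_deg, n) {
  ref <- ref / sqrt(sum(ref^2))
  a <- if (abs(ref[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - ref * sum(a * ref)
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(ref[2] * e1[3] - ref[3] * e1[2],
          ref[3] * e1[1] - ref[1] * e1[3],
          ref[1] * e1[2] - ref[2] * e1[1])
  phi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  al <- alpha_deg * pi / 180
  cos(al) * matrix(ref, n, 3, byrow = TRUE) +
    sin(al) * (outer(cos(phi), e1) + outer(sin(phi), e2))
}

# --- rotation matrices -----------------------------------------------------
rot_z <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), sin(r), 0, -sin(r), cos(r), 0, 0, 0, 1), 3, 3)
}
rot_axis_angle <- function(axis, deg) {
  axis <- axis / sqrt(sum(axis^2))
  r <- deg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(r) * K + (1 - cos(r)) * K %*% K
}

# lobe coefficients for test FODs (same kernel the generator uses)
test_lobe <- function(axis, lmax = 8, sharpness = 0.02) {
  vasofiber:::lobe_sh_coeffs(axis, lmax, sharpness)
}

# random unit axis
runif_axis <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}
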