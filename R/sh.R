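#' Real even-order spherical harmonics
#'
#' Fiber orientation distributions (FODs) are antipodally symmetric
#' functions on the sphere, represented by real, even-order spherical
#' harmonic (SH) coefficients. The basis used here is orthonormal:
#' for each even degree l and order m = -l..l,
#'   m < 0:  sqrt(2) * (-1)^m * Im(Y_l^|m|)
#'   m = 0:  Y_l^0
#'   m > 0:  sqrt(2) * (-1)^m * Re(Y_l^m)
#' stored in (l, m) order with m ascending within l ("sin-first"). A
#' converter to/from the "cos-first" ordering (m descending sign
#' convention used by some toolchains) is provided.
#'
#' @name spherical-harmonics
NULL

#' Number of even-order SH coefficients up to lmax
#' @param lmax even nonnegative integer.
#' @export
sh_ncoef <- function(lmax) {
  stopifnot(lmax %% 2 == 0, lmax >= 0)
  as.integer((lmax + 1) * (lmax + 2) / 2)
}

#' Degree/order table for the even SH basis
#' @keywords internal
sh_lm <- function(lmax) {
  l <- unlist(lapply(seq(0, lmax, by = 2), function(li) rep(li, 2 * li + 1)))
  m <- unlist(lapply(seq(0, lmax, by = 2), function(li) seq(-li, li)))
  cbind(l = l, m = m)
}

#' Normalized associated Legendre functions
#'
#' Computes N_l^m P_l^m(x) for all l = 0..lmax, m = 0..l, where
#' N_l^m = sqrt((2l+1)/(4pi) * (l-m)!/(l+m)!), by the standard stable
#' recursion (no Condon-Shortley phase folded in; it is applied in the
#' basis assembly).
#'
#' @param x numeric vector in \[-1, 1\].
#' @param lmax maximum degree.
#' @return list indexed `[[l+1]][[m+1]]` of numeric vectors.
#' @keywords internal
legendre_norm <- function(x, lmax) {
  out <- vector("list", lmax + 1)
  for (l in 0:lmax) out[[l + 1]] <- vector("list", l + 1)
  s <- sqrt(pmax(0, 1 - x^2))
  # P~_0^0
  out[[1]][[1]] <- rep(sqrt(1 / (4 * pi)), length(x))
  if (lmax == 0) return(out)
  # diagonal: P~_m^m = -? sqrt((2m+1)/(2m)) s P~_{m-1}^{m-1} (phase excluded)
  for (m in 1:lmax) {
    out[[m + 1]][[m + 1]] <- sqrt((2 * m + 1) / (2 * m)) * s *
      out[[m]][[m]]
  }
  # first off-diagonal: P~_{m+1}^m = sqrt(2m+3) x P~_m^m
  for (m in 0:(lmax - 1)) {
    out[[m + 2]][[m + 1]] <- sqrt(2 * m + 3) * x * out[[m + 1]][[m + 1]]
  }
  # upward recursion in l
  if (lmax >= 2) {
    for (m in 0:(lmax - 2)) {
      for (l in (m + 2):lmax) {
        a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
        b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
        out[[l + 1]][[m + 1]] <- a * (x * out[[l]][[m + 1]] -
                                        b * out[[l - 1]][[m + 1]])
      }
    }
  }
  out
}

#' Real even SH basis matrix
#'
#' @param dirs n x 3 matrix of unit directions (or a 3-vector).
#' @param lmax even maximum degree.
#' @return n x `sh_ncoef(lmax)` matrix B such that `B %*% coeffs` evaluates
#'   the SH series at each direction.
#' @export
sh_basis <- function(dirs, lmax) {
  if (!is.matrix(dirs)) dirs <- matrix(dirs, ncol = 3)
  dirs <- axis_normalize(dirs)
  ct <- dirs[, 3]
  phi <- atan2(dirs[, 2], dirs[, 1])
  P <- legendre_norm(ct, lmax)
  lm <- sh_lm(lmax)
  B <- matrix(0, nrow(dirs), nrow(lm))
  for (j in seq_len(nrow(lm))) {
    l <- lm[j, 1]; m <- lm[j, 2]
    am <- abs(m)
    # Condon-Shortley phase (-1)^m on the complex Y_l^m
    plm <- (-1)^am * P[[l + 1]][[am + 1]]
    B[, j] <- if (m < 0) {
      sqrt(2) * (-1)^am * plm * sin(am * phi)
    } else if (m == 0) {
      plm
    } else {
      sqrt(2) * (-1)^am * plm * cos(am * phi)
    }
  }
  B
}

#' Evaluate an SH series at directions
#'
#' @param coeffs coefficient vector of length `sh_ncoef(lmax)`.
#' @param dirs n x 3 matrix of unit directions (or a 3-vector).
#' @return amplitude(s); antipodally symmetric by construction (even orders
#'   only).
#' @export
sh_amplitude <- function(coeffs, dirs) {
  lmax <- sh_lmax_for(length(coeffs))
  as.numeric(sh_basis(dirs, lmax) %*% coeffs)
}

#' lmax implied by a coefficient count
#' @keywords internal
sh_lmax_for <- function(ncoef) {
  lmax <- (sqrt(8 * ncoef + 1) - 3) / 2
  if (abs(lmax - round(lmax)) > 1e-9 || round(lmax) %% 2 != 0) {
    stop("coefficient length does not match an even lmax", call. = FALSE)
  }
  as.integer(round(lmax))
}

#' Convert between the two common real-SH orderings
#'
#' Swaps the sin/cos assignment of the +/-m basis functions within each
#' degree ("sin-first" <-> "cos-first"); applying it twice is the identity.
#'
#' @param coeffs coefficient vector or matrix (coefficients in columns...
#'   rows are voxels, columns coefficients).
#' @return converted coefficients, same shape.
#' @export
convert_sh_basis <- function(coeffs) {
  vec <- !is.matrix(coeffs)
  if (vec) coeffs <- matrix(coeffs, nrow = 1)
  lm <- sh_lm(sh_lmax_for(ncol(coeffs)))
  perm <- integer(nrow(lm))
  for (j in seq_len(nrow(lm))) {
    tgt <- which(lm[, 1] == lm[j, 1] & lm[, 2] == -lm[j, 2])
    perm[j] <- tgt
  }
  out <- coeffs[, perm, drop = FALSE]
  if (vec) as.numeric(out) else out
}

#' Deterministic quasi-uniform sphere directions (spherical Fibonacci)
#'
#' @param n number of directions.
#' @param hemisphere keep one representative per antipodal pair by mapping
#'   all points to the z >= 0 hemisphere (default TRUE).
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_fibonacci <- function(n, hemisphere = TRUE) {
  i <- seq_len(n) - 0.5
  ga <- pi * (3 - sqrt(5))
  z <- if (hemisphere) 1 - i / n else 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- ga * (seq_len(n) - 1)
  cbind(r * cos(th), r * sin(th), z)
}

#' SH coefficient field
#'
#' @param coeffs 4D array `c(dim, ncoef)` of per-voxel even-order SH
#'   coefficients.
#' @param lmax even maximum degree matching the last dimension.
#' @param voxel_mm voxel size in mm.
#' @param affine 4 x 4 voxel-to-world matrix.
#' @param basis ordering tag, `"sin-first"` (package canonical) or
#'   `"cos-first"`.
#' @return object of class `sh_field`.
#' @export
sh_field <- function(coeffs, lmax, voxel_mm,
                     affine = default_affine(voxel_mm),
                     basis = "sin-first") {
  dm <- dim(coeffs)
  stopifnot(length(dm) == 4, dm[4] == sh_ncoef(lmax))
  structure(list(coeffs = coeffs, lmax = as.integer(lmax),
                 voxel_mm = rep(voxel_mm, length.out = 3),
                 affine = affine, basis = basis, dim = dm[1:3]),
            class = "sh_field")
}

#' @export
print.sh_field <- function(x, ...) {
  cat("<sh_field> grid", paste(x$dim, collapse = " x "),
      "; lmax", x$lmax, paste0("(", sh_ncoef(x$lmax), " coefficients, "),
      x$basis, "ordering)\n")
  invisible(x)
}

#' Coefficient matrix (voxels x ncoef) of an sh_field
#' @keywords internal
sh_coef_matrix <- function(field) {
  matrix(field$coeffs, prod(field$dim), sh_ncoef(field$lmax))
}
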