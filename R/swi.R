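#' Susceptibility-weighted contrast construction
#'
#' Builds SWI contrast from magnitude and phase volumes: high-pass filter
#' the phase (homodyne: complex division by a Hanning-windowed low-pass
#' version of the complex image), convert the filtered phase to a
#' multiplicative mask with a 4th-degree power function, multiply the
#' magnitude by the mask, and average co-registered repetitions.
#'
#' @name swi-contrast
NULL

#' 1D Hanning low-pass window over FFT frequencies
#'
#' @param n axis length.
#' @param fraction fraction of the axis kept (full width of the window as a
#'   fraction of the k-space extent).
#' @return length-n weights in FFT (unshifted) frequency order.
#' @keywords internal
hanning_lowpass_1d <- function(n, fraction) {
  f <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n]
  half <- fraction * n / 2
  w <- ifelse(abs(f) <= half, 0.5 * (1 + cos(pi * f / half)), 0)
  w
}

#' High-pass filter a phase volume (homodyne)
#'
#' Divides the complex image (magnitude * exp(i*phase)) by its low-pass
#' version, where the low-pass keeps a central k-space region under a
#' separable Hanning window of the given per-axis fraction. The phase of
#' the quotient is the high-passed phase, wrapped to (-pi, pi]. Removes
#' slowly varying background field while preserving the local phase of
#' small paramagnetic structures such as veins.
#'
#' @param magnitude,phase 3D arrays on the same grid; phase in radians.
#' @param window_fraction per-axis fraction in (0,1) of k-space kept by the
#'   Hanning low-pass (default 0.25).
#' @param slicewise filter each axial (third-dimension) slice in 2D
#'   (default TRUE, matching 2D acquisitions); FALSE filters in 3D.
#' @return 3D array of high-passed phase in (-pi, pi].
#' @export
highpass_phase <- function(magnitude, phase, window_fraction = 0.25,
                           slicewise = TRUE) {
  if (any(window_fraction <= 0) || any(window_fraction >= 1)) {
    stop("window_fraction must be in (0, 1)", call. = FALSE)
  }
  stopifnot(identical(dim(magnitude), dim(phase)))
  if (any(magnitude < 0)) stop("magnitude must be nonnegative", call. = FALSE)
  cimg <- magnitude * exp(1i * phase)
  dm <- dim(cimg)
  wf <- rep(window_fraction, length.out = 3)
  lp_2d <- function(slice) {
    w <- outer(hanning_lowpass_1d(nrow(slice), wf[1]),
               hanning_lowpass_1d(ncol(slice), wf[2]))
    stats::fft(stats::fft(slice) * w, inverse = TRUE) / length(slice)
  }
  if (slicewise) {
    lp <- cimg
    for (k in seq_len(dm[3])) lp[, , k] <- lp_2d(cimg[, , k])
  } else {
    w3 <- outer(outer(hanning_lowpass_1d(dm[1], wf[1]),
                      hanning_lowpass_1d(dm[2], wf[2])),
                hanning_lowpass_1d(dm[3], wf[3]))
    lp <- stats::fft(stats::fft(cimg) * w3, inverse = TRUE) / length(cimg)
  }
  # regularized complex division: phase of c * Conj(lp)
  quot <- cimg * Conj(lp)
  hp <- Arg(quot)
  hp[hp <= -pi] <- pi  # wrap convention (-pi, pi]
  array(hp, dm)
}

#' Phase mask from high-passed phase
#'
#' Maps phase to a multiplicative weight in \[0, 1\] that suppresses voxels
#' carrying vein-like phase. With the default negative polarity,
#' `m = (pi + phi) / pi` for `phi < 0` and 1 otherwise, raised to the given
#' power (the 4th-degree power function by default).
#'
#' @param hp_phase phase array in (-pi, pi].
#' @param power positive integer exponent (default 4).
#' @param polarity `"negative"` (default; suppress negative phase) or
#'   `"positive"`.
#' @return array of weights in \[0, 1\].
#' @export
phase_mask <- function(hp_phase, power = 4, polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  if (power < 1) stop("power must be >= 1", call. = FALSE)
  m <- if (polarity == "negative") {
    ifelse(hp_phase < 0, (pi + hp_phase) / pi, 1)
  } else {
    ifelse(hp_phase > 0, (pi - hp_phase) / pi, 1)
  }
  pmin(pmax(m, 0), 1)^power
}

#' Combine magnitude and phase mask into SWI contrast
#'
#' @param magnitude,mask arrays on the same grid.
#' @return voxel-wise product.
#' @export
swi_combine <- function(magnitude, mask) {
  if (!identical(dim(magnitude), dim(mask))) {
    stop("magnitude and mask grids differ", call. = FALSE)
  }
  magnitude * mask
}

#' Average co-registered repetitions
#'
#' Voxel-wise arithmetic mean of repeated acquisitions to increase SNR;
#' inputs are assumed already aligned.
#'
#' @param volumes list of arrays with identical dimensions.
#' @return array of the same dimensions.
#' @export
average_repetitions <- function(volumes) {
  if (!is.list(volumes) || length(volumes) == 0) {
    stop("need at least one volume", call. = FALSE)
  }
  dm <- dim(volumes[[1]])
  for (v in volumes) {
    if (!identical(dim(v), dm)) stop("volume grids differ", call. = FALSE)
  }
  Reduce(`+`, volumes) / length(volumes)
}

#' Full SWI contrast for one repetition
#'
#' Convenience composition: high-pass the phase, build the phase mask, and
#' multiply into the magnitude.
#'
#' @inheritParams highpass_phase
#' @inheritParams phase_mask
#' @return SWI contrast array.
#' @export
swi_contrast <- function(magnitude, phase, window_fraction = 0.25, power = 4,
                         polarity = "negative", slicewise = TRUE) {
  hp <- highpass_phase(magnitude, phase, window_fraction, slicewise)
  swi_combine(magnitude, phase_mask(hp, power, polarity))
}
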