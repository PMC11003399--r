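#' Optical system configuration
#'
#' Defines the sampled Fourier-optics geometry shared by all retrieval and
#' reconstruction routines. The holographic (back focal) plane is sampled on
#' `n_grid` points at `pitch_holo_mm` per sample; the target (front focal)
#' plane pitch follows from the Fourier conjugacy
#' \deqn{\Delta u = \lambda f / (N \Delta s).}
#'
#' Defaults describe a 940 nm system with a 15 mm modulator aperture spanning
#' the grid and an 8 mm effective focal length, giving a target-plane pitch of
#' about 0.5 um/sample over a 513 um field of view.
#'
#' @param wavelength_nm laser wavelength in nanometres.
#' @param n_grid samples per axis; even, at least 16.
#' @param pitch_holo_mm holographic-plane pitch in mm per sample.
#' @param focal_mm effective focal length in mm.
#' @return An object of class `optical_config` with the derived target-plane
#'   pitch `pitch_target_um`.
#' @export
optical_config <- function(wavelength_nm = 940,
                           n_grid = 1024,
                           pitch_holo_mm = 15 / 1024,
                           focal_mm = 8) {
  if (!is.numeric(n_grid) || length(n_grid) != 1 || n_grid < 16 || n_grid %% 2 != 0)
    stop("n_grid must be a single even integer >= 16")
  if (wavelength_nm <= 0 || pitch_holo_mm <= 0 || focal_mm <= 0)
    stop("all lengths must be strictly positive")
  n_grid <- as.integer(n_grid)
  # lambda f / (N ds), expressed in um per sample
  pitch_target_um <- (wavelength_nm * 1e-9) * (focal_mm * 1e-3) /
    (n_grid * pitch_holo_mm * 1e-3) * 1e6
  structure(
    list(
      wavelength_nm = wavelength_nm,
      n_grid = n_grid,
      pitch_holo_mm = pitch_holo_mm,
      focal_mm = focal_mm,
      pitch_target_um = pitch_target_um
    ),
    class = "optical_config"
  )
}

#' @export
print.optical_config <- function(x, ...) {
  cat("<optical_config>\n")
  cat(sprintf("  wavelength   : %g nm\n", x$wavelength_nm))
  cat(sprintf("  grid         : %d samples/axis\n", x$n_grid))
  cat(sprintf("  holo pitch   : %.6g mm/sample (extent %.3g mm)\n",
              x$pitch_holo_mm, x$pitch_holo_mm * x$n_grid))
  cat(sprintf("  focal length : %g mm\n", x$focal_mm))
  cat(sprintf("  target pitch : %.6g um/sample (FOV %.4g um)\n",
              x$pitch_target_um, x$pitch_target_um * x$n_grid))
  invisible(x)
}

#' System aperture specification
#'
#' Hard-edged aperture applied in the holographic plane. A circular aperture
#' models the round pupil of instrumental optics; a square aperture of
#' diameter `n_grid` is the identity (the grid boundary itself acts as the
#' slit/square stop of plain 1D retrieval).
#'
#' @param shape `"circular"` or `"square"`.
#' @param diameter_samples aperture diameter in samples.
#' @return object of class `aperture_spec`.
#' @export
aperture_spec <- function(shape = c("circular", "square"), diameter_samples) {
  shape <- match.arg(shape)
  if (!is.numeric(diameter_samples) || length(diameter_samples) != 1 ||
      diameter_samples < 0)
    stop("diameter_samples must be a single nonnegative number")
  structure(list(shape = shape, diameter_samples = diameter_samples),
            class = "aperture_spec")
}

#' Input beam profile
#'
#' Amplitude profile of the beam illuminating the modulator. The Gaussian
#' profile uses the 1/e^2 *intensity* diameter convention: amplitude
#' `exp(-4 r^2 / d^2)`, so intensity falls to 1/e^2 at `r = d/2`.
#'
#' @param kind `"uniform"` or `"gaussian"`.
#' @param diameter_samples 1/e^2 intensity diameter in samples (gaussian only).
#' @return object of class `beam_profile`.
#' @export
beam_profile <- function(kind = c("uniform", "gaussian"), diameter_samples = NULL) {
  kind <- match.arg(kind)
  if (kind == "gaussian") {
    if (is.null(diameter_samples) || diameter_samples <= 0)
      stop("gaussian beam requires a positive diameter_samples")
  }
  structure(list(kind = kind, diameter_samples = diameter_samples),
            class = "beam_profile")
}

# centered coordinate along one axis, in samples (center at index N/2, 0-based)
axis_coord <- function(n) seq_len(n) - (n %/% 2 + 1)

# 1D beam amplitude sampled on the grid
beam_amplitude_1d <- function(beam, n) {
  if (beam$kind == "uniform") return(rep(1, n))
  exp(-4 * (axis_coord(n) / beam$diameter_samples)^2)
}

# 2D (radial) beam amplitude
beam_amplitude_2d <- function(beam, n) {
  if (beam$kind == "uniform") return(matrix(1, n, n))
  x <- axis_coord(n)
  r2 <- outer(x, x, function(a, b) a^2 + b^2)
  exp(-4 * r2 / beam$diameter_samples^2)
}

# 2D binary aperture mask
aperture_mask_2d <- function(aperture, n) {
  d <- aperture$diameter_samples
  if (d > n) stop("aperture diameter exceeds grid size")
  if (d == 0) return(matrix(0, n, n))
  x <- axis_coord(n)
  if (aperture$shape == "circular") {
    r2 <- outer(x, x, function(a, b) a^2 + b^2)
    (r2 <= (d / 2)^2) * 1
  } else {
    inside <- abs(x) <= d / 2
    outer(inside, inside) * 1
  }
}
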