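#' Sampled complex light field
#'
#' A uniformly sampled complex field tagged with the plane it lives in.
#' 1D fields are complex vectors, 2D fields square complex matrices.
#'
#' @param samples complex vector (1D) or square matrix (2D).
#' @param plane `"holographic"` or `"target"`.
#' @param optics an [optical_config()] supplying the pitch in either plane.
#' @return object of class `light_field`.
#' @export
light_field <- function(samples, plane = c("holographic", "target"), optics) {
  plane <- match.arg(plane)
  if (is.matrix(samples)) {
    if (nrow(samples) != ncol(samples)) stop("2D fields must be square")
    ndim <- 2L
  } else {
    ndim <- 1L
  }
  if (!all(is.finite(Re(samples))) || !all(is.finite(Im(samples))))
    stop("invalid field: non-finite samples")
  structure(
    list(samples = as.complex(samples) * (if (ndim == 2) 1 else 1),
         samples_dim = if (ndim == 2) dim(samples) else length(samples),
         ndim = ndim, plane = plane,
         pitch = if (plane == "holographic") optics$pitch_holo_mm else optics$pitch_target_um,
         optics = optics),
    class = "light_field"
  )
}

#' Raw complex samples of a field
#'
#' Returns the complex samples of a [light_field()] in their natural shape
#' (vector for 1D, matrix for 2D).
#'
#' @param f a `light_field`.
#' @return complex vector or matrix.
#' @export
field_samples <- function(f) {
  if (f$ndim == 2) matrix(f$samples, f$samples_dim[1], f$samples_dim[2]) else f$samples
}

#' @export
print.light_field <- function(x, ...) {
  cat(sprintf("<light_field> %dD, %s plane, %s samples, power %.4g\n",
              x$ndim, x$plane,
              paste(x$samples_dim, collapse = "x"),
              sum(Mod(x$samples)^2)))
  invisible(x)
}

## --- centered unitary Fourier transforms -------------------------------
## DC sits at index N/2 (0-based), i.e. N/2 + 1 in R's 1-based indexing,
## in both planes; transforms are unitary so total power is preserved.

fft_shift <- function(x) {
  if (is.matrix(x)) {
    n <- nrow(x); k <- n %/% 2
    idx <- c((k + 1):n, 1:k)
    x[idx, idx, drop = FALSE]
  } else {
    n <- length(x); k <- n %/% 2
    c(x[(k + 1):n], x[1:k])
  }
}

ft_centered <- function(x, inverse = FALSE) {
  scale <- sqrt(prod(if (is.matrix(x)) dim(x) else length(x)))
  fft_shift(fft(fft_shift(x), inverse = inverse)) / scale
}

#' Propagate a field between holographic and target planes
#'
#' Applies the DC-centered unitary discrete Fourier transform (forward for
#' `to_target`, inverse for `to_hologram`), flipping the plane tag. Total
#' power is preserved and a roundtrip reproduces the input to numerical
#' precision.
#'
#' @param field a [light_field()].
#' @param direction `"to_target"` or `"to_hologram"`.
#' @return the propagated `light_field`.
#' @export
propagate <- function(field, direction = c("to_target", "to_hologram")) {
  direction <- match.arg(direction)
  stopifnot(inherits(field, "light_field"))
  if (direction == "to_target" && field$plane != "holographic")
    stop("to_target requires a holographic-plane field")
  if (direction == "to_hologram" && field$plane != "target")
    stop("to_hologram requires a target-plane field")
  s <- ft_centered(field_samples(field), inverse = (direction == "to_hologram"))
  light_field(s,
              plane = if (direction == "to_target") "target" else "holographic",
              optics = field$optics)
}

#' Apply a hard-edged aperture to a 2D holographic field
#'
#' Samples whose centers fall outside the aperture are set to exactly zero;
#' samples inside are unchanged (no rim anti-aliasing).
#'
#' @param field 2D holographic-plane [light_field()].
#' @param aperture an [aperture_spec()].
#' @return the masked `light_field`.
#' @export
apply_aperture <- function(field, aperture) {
  stopifnot(inherits(field, "light_field"), inherits(aperture, "aperture_spec"))
  if (field$ndim != 2 || field$plane != "holographic")
    stop("apply_aperture expects a 2D holographic-plane field")
  n <- field$samples_dim[1]
  if (aperture$diameter_samples > n) stop("aperture diameter exceeds grid size")
  m <- aperture_mask_2d(aperture, n)
  light_field(field_samples(field) * m, plane = "holographic", optics = field$optics)
}

#' Apply an input beam profile to a holographic field
#'
#' Pointwise multiplication with the beam amplitude. A uniform beam is the
#' identity; the Gaussian beam uses the `exp(-4 r^2/d^2)` amplitude
#' convention (1/e^2 intensity diameter `d`).
#'
#' @param field holographic-plane [light_field()] (1D or 2D).
#' @param beam a [beam_profile()].
#' @return the illuminated `light_field`.
#' @export
apply_beam <- function(field, beam) {
  stopifnot(inherits(field, "light_field"), inherits(beam, "beam_profile"))
  if (field$plane != "holographic") stop("apply_beam expects a holographic-plane field")
  n <- field$samples_dim[1]
  b <- if (field$ndim == 2) beam_amplitude_2d(beam, n) else beam_amplitude_1d(beam, n)
  light_field(field_samples(field) * b, plane = "holographic", optics = field$optics)
}

#' Embed two 1D axis profiles as a separable 2D holographic field
#'
#' Crossed-modulator superposition: the 2D wavefront is the sum of the axis
#' wavefronts, `phi(x, y) = phi_x(x) + phi_y(y)`, and the amplitude the outer
#' product of the axis masks, so
#' `samples[x, y] = amp_x(x) amp_y(y) exp(i (phase_x(x) + phase_y(y)))`.
#' The first index (rows) is x, the second (columns) y.
#'
#' @param phase_x,phase_y phase profiles (radians, length N each).
#' @param amp_x,amp_y amplitude profiles in `[0, 1]` (length N each).
#' @param optics an [optical_config()] with `n_grid == N`.
#' @return 2D holographic-plane [light_field()].
#' @export
embed_ps2d <- function(phase_x, phase_y, amp_x, amp_y, optics) {
  n <- length(phase_x)
  if (length(phase_y) != n || length(amp_x) != n || length(amp_y) != n)
    stop("axis profiles must all have the same length")
  hx <- amp_x * exp(1i * phase_x)
  hy <- amp_y * exp(1i * phase_y)
  light_field(outer(hx, hy), plane = "holographic", optics = optics)
}

#' Extract the midline of a 2D target-plane field
#'
#' Returns the central line through the DC sample (row index N/2, 0-based,
#' for `axis = "x"`: the profile along x at the central y; `axis = "y"` the
#' converse). For separable fields the midline is proportional to the 1D
#' reconstruction of the corresponding axis hologram.
#'
#' @param field 2D target-plane [light_field()].
#' @param axis `"x"` (default) or `"y"`.
#' @return 1D target-plane `light_field`.
#' @export
extract_midline <- function(field, axis = c("x", "y")) {
  axis <- match.arg(axis)
  stopifnot(inherits(field, "light_field"))
  if (field$ndim != 2 || field$plane != "target")
    stop("extract_midline expects a 2D target-plane field")
  s <- field_samples(field)
  c0 <- nrow(s) %/% 2 + 1
  v <- if (axis == "x") s[, c0] else s[c0, ]
  light_field(v, plane = "target", optics = field$optics)
}
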