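#' Compose two axis holograms into a pseudo-2D hologram
#'
#' Pairs an x-axis and a y-axis `hologram_1d` for a crossed-modulator system.
#' An FM axis contributes unit amplitude; an FM/AM axis its amplitude mask.
#'
#' @param hx,hy `hologram_1d` objects of equal length.
#' @param label optional label.
#' @return object of class `ps2d_hologram`.
#' @export
compose <- function(hx, hy, label = NULL) {
  stopifnot(inherits(hx, "hologram_1d"), inherits(hy, "hologram_1d"))
  if (hx$n != hy$n) stop("axis holograms must have equal length")
  structure(list(hologram_x = hx, hologram_y = hy,
                 mode_x = hx$mode, mode_y = hy$mode, label = label),
            class = "ps2d_hologram")
}

#' @export
print.ps2d_hologram <- function(x, ...) {
  cat(sprintf("<ps2d_hologram>%s x: %s (%s), y: %s (%s), N = %d\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              x$hologram_x$engine, x$mode_x,
              x$hologram_y$engine, x$mode_y, x$hologram_x$n))
  invisible(x)
}

axis_mask <- function(h) if (h$mode == "FM/AM") h$mask else rep(1, h$n)

#' Reconstruct the 2D target-plane pattern of a ps2D hologram
#'
#' Pipeline: embed the axis profiles as a separable 2D holographic field,
#' apply the input beam, apply the system aperture, Fourier-propagate.
#' The input power is the beam power passing the aperture (before amplitude
#' masks); the first-order power is the total reconstructed power, the
#' amplitude-mask-rejected remainder going to the zero-order power sink.
#'
#' @param h a [compose()]d `ps2d_hologram`.
#' @param aperture an [aperture_spec()]; default circular, diameter `n_grid`.
#' @param beam a [beam_profile()]; default uniform.
#' @param optics an [optical_config()].
#' @return object of class `recon_result` with elements `amplitude`,
#'   `intensity`, `phase` (2D matrices), `input_power`, `first_order_power`
#'   and `metrics` (list; efficiency pre-filled).
#' @export
reconstruct_2d <- function(h, aperture = NULL, beam = beam_profile("uniform"),
                           optics = optical_config()) {
  stopifnot(inherits(h, "ps2d_hologram"))
  n <- h$hologram_x$n
  if (n != optics$n_grid) stop("hologram length does not match optics$n_grid")
  if (is.null(aperture)) aperture <- aperture_spec("circular", n)
  emb <- embed_ps2d(h$hologram_x$phase, h$hologram_y$phase,
                    axis_mask(h$hologram_x), axis_mask(h$hologram_y), optics)
  ap <- aperture_mask_2d(aperture, n)
  b <- beam_amplitude_2d(beam, n)
  input_power <- sum((b * ap)^2)
  final <- light_field(field_samples(emb) * b * ap, "holographic", optics)
  rec <- propagate(final, "to_target")
  s <- field_samples(rec)
  amp <- Mod(s)
  first_order <- sum(amp^2)
  structure(list(amplitude = amp, intensity = amp^2, phase = Arg(s),
                 input_power = input_power, first_order_power = first_order,
                 field = rec,
                 metrics = list(power_efficiency = first_order / input_power)),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf("<recon_result> %dx%d, input power %.4g, first-order power %.4g (eff %.3f)\n",
              nrow(x$amplitude), ncol(x$amplitude),
              x$input_power, x$first_order_power,
              x$metrics$power_efficiency))
  invisible(x)
}

#' Test a 2D pattern for pseudo-2D separability
#'
#' A pattern is ps2D-separable when it is (numerically) an outer product of
#' two 1D profiles, i.e. its best rank-1 approximation leaves a relative
#' Frobenius residual below `tol`. The all-zero pattern is trivially
#' separable with zero profiles.
#'
#' @param pattern nonnegative 2D matrix.
#' @param tol relative residual tolerance (default 1e-3).
#' @return list with `separable` (logical), `profile_x`, `profile_y`
#'   (nonnegative factors such that `outer(profile_x, profile_y)` is the
#'   rank-1 approximation) and `residual`.
#' @export
is_ps2d_separable <- function(pattern, tol = 1e-3) {
  if (any(pattern < 0)) stop("pattern must be nonnegative")
  n <- nrow(pattern)
  if (all(pattern == 0))
    return(list(separable = TRUE, profile_x = numeric(n),
                profile_y = numeric(ncol(pattern)), residual = 0))
  # restrict the SVD to the nonzero rows/columns (zero lines carry no power)
  rows <- which(rowSums(pattern) > 0)
  cols <- which(colSums(pattern) > 0)
  sv <- svd(pattern[rows, cols, drop = FALSE])
  total <- sum(sv$d^2)
  residual <- sqrt(max(0, 1 - sv$d[1]^2 / total))
  u <- numeric(n); v <- numeric(ncol(pattern))
  u[rows] <- sv$u[, 1]; v[cols] <- sv$v[, 1]
  # Perron-Frobenius: leading factors of a nonnegative matrix can be taken
  # nonnegative; fix the sign
  if (sum(u) < 0) { u <- -u; v <- -v }
  s1 <- sqrt(sv$d[1])
  list(separable = residual < tol,
       profile_x = pmax(u, 0) * s1,
       profile_y = pmax(v, 0) * s1,
       residual = residual)
}

#' Two-photon rendering of a reconstruction
#'
#' Models the second-order nonlinearity of two-photon excitation: pointwise
#' intensity squared, normalized to unit maximum.
#'
#' @param r a `recon_result`, or an intensity matrix.
#' @return 2D image matrix with maximum 1.
#' @export
two_photon_render <- function(r) {
  intensity <- if (inherits(r, "recon_result")) r$intensity else r
  img <- intensity^2
  m <- max(img)
  if (m > 0) img / m else img
}
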