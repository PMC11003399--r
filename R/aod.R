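#' Acousto-optic deflector device specification
#'
#' In the synchronous mode the AOD transfer function reduces to a static
#' linear relation between the local wavefront slope and the local acoustic
#' frequency offset from the carrier,
#' \deqn{d\phi/ds = (2\pi / v_{ac}) \, \Delta f(s),}
#' with \eqn{v_{ac}} the acoustic phase velocity. The intrinsic cycle time is
#' the acoustic transit time across the aperture, `T_AOD = aperture /
#' velocity`, which caps the usable laser rate at `1/T_AOD`.
#'
#' @param v_ac_m_s acoustic phase velocity in m/s (650 for TeO2 shear waves).
#' @param aperture_mm device aperture diameter in mm.
#' @param carrier_MHz acoustic carrier frequency in MHz.
#' @param bandwidth_MHz allocated modulation bandwidth in MHz (full width).
#' @param laser_rate_kHz pulsed-laser repetition rate in kHz.
#' @return object of class `aod_spec` with derived `t_aod_us`.
#' @export
aod_spec <- function(v_ac_m_s = 650, aperture_mm = 15, carrier_MHz = 82,
                     bandwidth_MHz = 50, laser_rate_kHz = 40) {
  vals <- c(v_ac_m_s, aperture_mm, carrier_MHz, bandwidth_MHz, laser_rate_kHz)
  if (any(vals <= 0)) stop("all AOD parameters must be positive")
  t_aod_us <- (aperture_mm * 1e-3) / v_ac_m_s * 1e6
  structure(list(v_ac_m_s = v_ac_m_s, aperture_mm = aperture_mm,
                 carrier_MHz = carrier_MHz, bandwidth_MHz = bandwidth_MHz,
                 laser_rate_kHz = laser_rate_kHz, t_aod_us = t_aod_us),
            class = "aod_spec")
}

#' @export
print.aod_spec <- function(x, ...) {
  cat(sprintf("<aod_spec> v_ac %g m/s, aperture %g mm, T_AOD %.3f us (max rate %.1f kHz)\n",
              x$v_ac_m_s, x$aperture_mm, x$t_aod_us, 1e3 / x$t_aod_us))
  cat(sprintf("  carrier %g MHz, bandwidth %g MHz, laser rate %g kHz\n",
              x$carrier_MHz, x$bandwidth_MHz, x$laser_rate_kHz))
  invisible(x)
}

# physical AOD coordinate (mm) for each sample: the grid spans the aperture
aod_coordinate_mm <- function(n, spec) axis_coord(n) * (spec$aperture_mm / n)

#' Convert an optical phase profile to an AOD frequency envelope
#'
#' Differentiates the unwrapped phase along the physical device coordinate
#' (central differences, one-sided at the edges) and scales by
#' `v_ac / (2 pi)`. One-dimensional phase profiles are free of vortices and
#' can always be unwrapped.
#'
#' @param h a `hologram_1d` (its unwrapped `phase` is used) or a numeric
#'   unwrapped phase profile.
#' @param spec an [aod_spec()].
#' @return data.frame with columns `s_mm` (device coordinate) and
#'   `delta_f_MHz` (frequency offset from the carrier).
#' @export
phase_to_frequency <- function(h, spec = aod_spec()) {
  phi <- if (inherits(h, "hologram_1d")) h$phase else as.numeric(h)
  n <- length(phi)
  s_m <- aod_coordinate_mm(n, spec) * 1e-3
  dphi <- numeric(n)
  dphi[2:(n - 1)] <- (phi[3:n] - phi[1:(n - 2)]) / (s_m[3:n] - s_m[1:(n - 2)])
  dphi[1] <- (phi[2] - phi[1]) / (s_m[2] - s_m[1])
  dphi[n] <- (phi[n] - phi[n - 1]) / (s_m[n] - s_m[n - 1])
  delta_f_hz <- spec$v_ac_m_s / (2 * pi) * dphi
  data.frame(s_mm = s_m * 1e3, delta_f_MHz = delta_f_hz * 1e-6)
}

#' Convert an AOD frequency envelope back to an optical phase
#'
#' Cumulative integral of `2 pi / v_ac * delta_f` along the device
#' coordinate, with zero phase at the left edge. The integration rule is the
#' exact inverse of the central-difference stencil used by
#' [phase_to_frequency()] (midpoint/leapfrog accumulation), so a conversion
#' roundtrip reproduces the phase up to an additive constant to machine
#' precision.
#'
#' @param envelope data.frame with `s_mm` and `delta_f_MHz` (as produced by
#'   [phase_to_frequency()]), uniformly sampled.
#' @param spec an [aod_spec()].
#' @return unwrapped phase profile (radians).
#' @export
frequency_to_phase <- function(envelope, spec = aod_spec()) {
  if (!all(is.finite(envelope$delta_f_MHz))) stop("non-finite envelope")
  s_m <- envelope$s_mm * 1e-3
  n <- length(s_m)
  h <- diff(s_m)
  if (n > 2 && diff(range(h)) > 1e-9 * mean(h))
    stop("envelope must be uniformly sampled")
  g <- 2 * pi / spec$v_ac_m_s * envelope$delta_f_MHz * 1e6
  phi <- numeric(n)
  phi[2] <- h[1] * g[1]                       # one-sided edge stencil
  if (n > 2) for (k in 2:(n - 1)) phi[k + 1] <- phi[k - 1] + 2 * h[1] * g[k]
  phi
}

#' Validate a hologram or envelope against AOD device constraints
#'
#' Checks (i) the synchronous-mode rate constraint `laser_rate <= 1/T_AOD`
#' (boundary inclusive) and (ii) that the frequency envelope stays within
#' half the allocated bandwidth around the carrier.
#'
#' @param x a `hologram_1d` or a frequency-envelope data.frame.
#' @param spec an [aod_spec()].
#' @return object of class `aod_report`: `pass`, per-check flags and margins.
#' @export
aod_validate <- function(x, spec = aod_spec()) {
  env <- if (inherits(x, "hologram_1d")) phase_to_frequency(x, spec) else x
  max_rate_khz <- 1e3 / spec$t_aod_us
  rate_ok <- spec$laser_rate_kHz <= max_rate_khz
  excursion <- max(abs(env$delta_f_MHz))
  half_bw <- spec$bandwidth_MHz / 2
  bw_ok <- excursion <= half_bw
  structure(list(pass = rate_ok && bw_ok,
                 rate_ok = rate_ok,
                 rate_margin_kHz = max_rate_khz - spec$laser_rate_kHz,
                 bandwidth_ok = bw_ok,
                 excursion_MHz = excursion,
                 bandwidth_margin_MHz = half_bw - excursion),
            class = "aod_report")
}

#' @export
print.aod_report <- function(x, ...) {
  cat(sprintf("<aod_report> %s\n", if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  laser rate : %s (margin %.2f kHz)\n",
              if (x$rate_ok) "ok" else "violated", x$rate_margin_kHz))
  cat(sprintf("  bandwidth  : %s (excursion %.3f MHz, margin %.3f MHz)\n",
              if (x$bandwidth_ok) "ok" else "violated",
              x$excursion_MHz, x$bandwidth_margin_MHz))
  invisible(x)
}
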