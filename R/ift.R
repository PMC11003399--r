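#' Configuration for iterative Fourier transform hologram retrieval
#'
#' @param iterations number of IFT cycles (>= 1). The static and dynamic
#'   phase-only engines default to 200 cycles (well past stagnation); the
#'   complex engine defaults to a short 10-cycle budget (see the methods
#'   vignette for the calibration of this choice).
#' @param seed integer seed for the random initial target-plane phase.
#' @param regularization `"static"`, `"dynamic"` or `"complex"`.
#' @param gain_max maximum amplitude-feedback gain g_AM in `[0, 0.99]`
#'   (complex engine only).
#' @param ramp_iterations length of the linear gain ramp; defaults to half the
#'   iteration count (at least 2). Must not exceed `iterations`.
#' @param apod_gain post hoc apodization gain in `[0, 1]` applied by
#'   [apodize()] convenience paths.
#' @param guard_samples guard band (samples) between target and freedom
#'   domains when a default freedom domain is constructed.
#' @return object of class `ift_config`.
#' @export
ift_config <- function(iterations = 200, seed = 1,
                       regularization = c("static", "dynamic", "complex"),
                       gain_max = 0.99, ramp_iterations = NULL,
                       apod_gain = 0, guard_samples = 2) {
  regularization <- match.arg(regularization)
  if (iterations < 1) stop("iterations must be >= 1")
  if (gain_max < 0 || gain_max >= 1) stop("gain_max must lie in [0, 0.99] (< 1)")
  if (is.null(ramp_iterations)) ramp_iterations <- max(2, ceiling(iterations / 2))
  if (ramp_iterations > iterations) stop("ramp_iterations must not exceed iterations")
  if (apod_gain < 0 || apod_gain > 1) stop("apod_gain must lie in [0, 1]")
  structure(list(iterations = as.integer(iterations), seed = as.integer(seed),
                 regularization = regularization, gain_max = gain_max,
                 ramp_iterations = as.integer(ramp_iterations),
                 apod_gain = apod_gain, guard_samples = as.integer(guard_samples)),
            class = "ift_config")
}

# unwrap a phase profile: cumulative sum of wrapped first differences
unwrap_phase <- function(phi) {
  if (length(phi) < 2) return(phi)
  d <- diff(phi)
  d <- Arg(exp(1i * d))
  cumsum(c(phi[1], d))
}

wrap_phase <- function(phi) Arg(exp(1i * phi))

new_hologram_1d <- function(phase, mask, holo_amplitude, mode, engine, cfg,
                            error, n) {
  structure(list(
    phase = unwrap_phase(phase),
    phase_wrapped = wrap_phase(phase),
    mask = mask,
    holo_amplitude = holo_amplitude,
    mode = mode,
    engine = engine,
    seed = cfg$seed,
    iterations = cfg$iterations,
    gain_max = if (identical(engine, "complex") || identical(engine, "extended-complex")) cfg$gain_max else 0,
    error = error,
    n = n
  ), class = "hologram_1d")
}

#' @export
print.hologram_1d <- function(x, ...) {
  cat(sprintf("<hologram_1d> %s engine, %d samples, mode %s, seed %d, final error %.4g\n",
              x$engine, x$n, x$mode, x$seed, x$error))
  invisible(x)
}

# linear gain ramp: 0 at cycle 1 up to gain_max at the end of the ramp
feedback_gain <- function(k, cfg) {
  if (cfg$gain_max == 0) return(0)
  r <- cfg$ramp_iterations
  if (k >= r) cfg$gain_max else cfg$gain_max * (k - 1) / (r - 1)
}

## Core Gerchberg-Saxton loop shared by all 1D engines.
##
## Per cycle: inverse-propagate the target-plane field, apply the
## holographic-plane amplitude rule (input beam for phase-only retrieval, a
## gain-weighted blend of beam and normalized current amplitude for complex
## retrieval), forward-propagate (optionally through the separable-2D
## circular-aperture route of the extended engine), and re-impose the target
## amplitude (everywhere for static regularization; only on the target domain
## for dynamic regularization, carrying the freedom-domain amplitude over).
gs_core <- function(target, cfg, optics, dynamic = FALSE,
                    aperture = NULL, partner = NULL, engine_label = "static") {
  n <- optics$n_grid
  if (length(target$amplitude) != n)
    stop("target length does not match optics$n_grid")
  t_amp <- target$amplitude
  td <- target$target_domain
  fd <- target$freedom_domain
  if (dynamic) {
    if (is.null(fd) || !any(fd))
      stop("dynamic regularization requires a non-empty freedom domain")
  }
  beam_amp <- rep(1, n)
  circ2d <- NULL
  if (!is.null(aperture)) {
    if (aperture$shape != "circular") {
      warning("square aperture is equivalent to the plain 1D slit model; using plain engine")
      aperture <- NULL
    } else {
      circ2d <- aperture_mask_2d(aperture, n)
    }
  }
  set.seed(cfg$seed)
  tf <- t_amp * exp(1i * stats::runif(n, 0, 2 * pi))
  mask <- beam_amp
  holo <- NULL
  complexeng <- cfg$regularization == "complex"
  for (k in seq_len(cfg$iterations)) {
    holo <- ft_centered(tf, inverse = TRUE)
    amp_h <- Mod(holo)
    amp_h_n <- amp_h / max(amp_h)
    g <- if (complexeng) feedback_gain(k, cfg) else 0
    mask <- (1 - g) * beam_amp + g * amp_h_n
    h_field <- mask * exp(1i * Arg(holo))
    if (is.null(circ2d)) {
      tp <- ft_centered(h_field)
    } else {
      px <- h_field
      py <- if (is.null(partner)) h_field else partner
      tp <- ft_centered(circ2d * outer(px, py))[, n %/% 2 + 1]
    }
    amp_new <- t_amp
    if (dynamic) amp_new[fd] <- Mod(tp)[fd]
    tf <- amp_new * exp(1i * Arg(tp))
  }
  phase <- Arg(holo)
  amp_h_n <- Mod(holo) / max(Mod(holo))
  out_mask <- if (complexeng) mask else rep(1, n)
  mode <- if (complexeng) "FM/AM" else "FM"
  # record the engine's own final reconstruction error
  recon <- if (is.null(circ2d)) {
    Mod(ft_centered(out_mask * exp(1i * phase)))
  } else {
    h1 <- out_mask * exp(1i * phase)
    py <- if (is.null(partner)) h1 else partner
    Mod(ft_centered(circ2d * outer(h1, py))[, n %/% 2 + 1])
  }
  err <- target_error(recon, target)
  new_hologram_1d(phase, out_mask, amp_h_n, mode, engine_label, cfg, err, n)
}

#' Static-target phase-only hologram retrieval
#'
#' Gerchberg-Saxton iteration with the full target amplitude re-imposed over
#' the whole target plane each cycle and the holographic amplitude clamped to
#' the (uniform) input beam. Returns a phase-only (FM) hologram; the final
#' holographic amplitude is retained in `holo_amplitude` for optional post hoc
#' apodization via [apodize()].
#'
#' @param target a [target_1d()] without freedom domain.
#' @param cfg an [ift_config()] with `regularization = "static"`.
#' @param optics an [optical_config()].
#' @return a `hologram_1d`.
#' @export
gs_static <- function(target, cfg = ift_config(), optics = optical_config()) {
  if (!is.null(target$freedom_domain) && any(target$freedom_domain))
    stop("gs_static requires an empty freedom domain (use gs_dynamic)")
  if (cfg$regularization != "static") stop("cfg$regularization must be 'static'")
  gs_core(target, cfg, optics, dynamic = FALSE, engine_label = "static")
}

#' Dynamic-target (freedom-domain) phase-only retrieval
#'
#' As [gs_static()], but the amplitude constraint is applied only on the
#' target domain; on the freedom domain the current amplitude is carried over
#' each cycle (the target is dynamically updated), letting higher diffraction
#' orders self-organize outside the pattern of interest. If the target's
#' freedom domain is unset (`NULL`), the default one (everything beyond a
#' guard band of `cfg$guard_samples`) is attached; an explicitly all-`FALSE`
#' freedom domain degenerates to the static behavior.
#'
#' @inheritParams gs_static
#' @export
gs_dynamic <- function(target, cfg = ift_config(regularization = "dynamic"),
                       optics = optical_config()) {
  if (cfg$regularization != "dynamic") stop("cfg$regularization must be 'dynamic'")
  if (is.null(target$freedom_domain))
    target <- with_freedom_domain(target, cfg$guard_samples)
  gs_core(target, cfg, optics, dynamic = any(target$freedom_domain),
          engine_label = "dynamic")
}

#' Complex (FM/AM) hologram retrieval with amplitude feedback
#'
#' Joint optimization of the holographic phase and amplitude: each cycle the
#' holographic amplitude is a gain-weighted blend of the input-beam amplitude
#' and the current holographic amplitude rescaled to unit maximum, with the
#' gain ramped linearly from 0 at the first cycle to `gain_max` at the end of
#' the ramp and held constant thereafter. Returns an FM/AM hologram whose
#' amplitude mask is the final blended amplitude.
#'
#' @param target a [target_1d()].
#' @param cfg an [ift_config()] with `regularization = "complex"`. Defaults to
#'   the short 10-cycle budget with a 5-cycle ramp.
#' @param optics an [optical_config()].
#' @return a `hologram_1d` with `mode = "FM/AM"`.
#' @export
gs_complex <- function(target,
                       cfg = ift_config(iterations = 10, regularization = "complex"),
                       optics = optical_config()) {
  if (cfg$regularization != "complex") stop("cfg$regularization must be 'complex'")
  gs_core(target, cfg, optics, dynamic = FALSE, engine_label = "complex")
}

#' Extended 1D retrieval with circular system aperture
#'
#' As the plain engines, but each cycle the current 1D holographic field is
#' expanded into a separable 2D field (same profile on both axes, or a fixed
#' `partner` profile on the second axis), the circular aperture is imposed,
#' the 2D field is Fourier-propagated and the 1D field recovered from its
#' midline before the target constraint is applied. A square aperture request
#' falls back to the plain engine with a warning (a square stop factorizes
#' into slits, which the plain 1D model already represents).
#'
#' @param target a [target_1d()].
#' @param aperture a circular [aperture_spec()].
#' @param cfg an [ift_config()]; any regularization.
#' @param optics an [optical_config()].
#' @param partner optional fixed complex profile (length N) used for the
#'   second axis during expansion; default uses the current profile on both.
#' @return a `hologram_1d`.
#' @export
gs_extended <- function(target, aperture,
                        cfg = ift_config(iterations = 10, regularization = "complex"),
                        optics = optical_config(), partner = NULL) {
  if (cfg$regularization == "dynamic" &&
      (is.null(target$freedom_domain) || !any(target$freedom_domain)))
    target <- with_freedom_domain(target, cfg$guard_samples)
  gs_core(target, cfg, optics,
          dynamic = (cfg$regularization == "dynamic"),
          aperture = aperture, partner = partner,
          engine_label = paste0("extended-", cfg$regularization))
}

#' Post hoc apodization of a phase hologram
#'
#' Blends a uniform transmission with the hologram's retained final
#' holographic amplitude: `mask = (1 - gain) + gain * holo_amplitude`. At
#' gain 0 the hologram stays phase-only (FM); any positive gain switches the
#' mode to FM/AM. The phase is unchanged.
#'
#' @param h a `hologram_1d` carrying `holo_amplitude`.
#' @param gain apodization gain in `[0, 1]`.
#' @return the apodized `hologram_1d`.
#' @export
apodize <- function(h, gain) {
  stopifnot(inherits(h, "hologram_1d"))
  if (gain < 0 || gain > 1) stop("apodization gain must lie in [0, 1]")
  if (is.null(h$holo_amplitude)) stop("hologram carries no stored holographic amplitude")
  h$mask <- (1 - gain) + gain * h$holo_amplitude
  if (gain > 0) h$mode <- "FM/AM"
  h$engine <- paste0(h$engine, "+apodized")
  h
}

#' Decadic feedback gain
#'
#' Rescales the linear amplitude-feedback gain for display and sweeps:
#' `g' = 0.5 log10(1 / (1 - g))`, mapping `[0, 0.99]` onto `[0, 1]`.
#'
#' @param g_lin linear gain in `[0, 0.99]`.
#' @return decadic gain.
#' @export
decadic_gain <- function(g_lin) {
  if (any(g_lin < 0 | g_lin >= 1)) stop("linear gain must lie in [0, 0.99] (< 1)")
  0.5 * log10(1 / (1 - g_lin))
}

#' @rdname decadic_gain
#' @param g_dec decadic gain in `[0, 1]`.
#' @export
inverse_decadic_gain <- function(g_dec) {
  if (any(g_dec < 0)) stop("decadic gain must be nonnegative")
  1 - 10^(-2 * g_dec)
}

#' Reconstruct the 1D target-plane field of a hologram
#'
#' Forward-propagates `mask * beam * exp(i phase)`; the plain 1D model (slit
#' aperture equal to the grid). With `oversample > 1` the hologram is
#' zero-padded to `oversample * N` samples before propagation, sampling the
#' target plane at `pitch / oversample` (useful to resolve the phase
#' structure within diffraction-limited features).
#'
#' @param h a `hologram_1d`.
#' @param optics an [optical_config()].
#' @param beam a [beam_profile()]; default uniform.
#' @param oversample integer zero-padding factor (default 1).
#' @return 1D target-plane [light_field()]; when oversampled, built on an
#'   enlarged-grid copy of the optics with the finer target pitch.
#' @export
reconstruct_1d <- function(h, optics = optical_config(), beam = beam_profile("uniform"),
                           oversample = 1) {
  stopifnot(inherits(h, "hologram_1d"))
  b <- beam_amplitude_1d(beam, h$n)
  s <- h$mask * b * exp(1i * h$phase)
  if (oversample > 1) {
    m <- as.integer(oversample)
    big <- complex(real = numeric(h$n * m))
    lo <- (h$n * m) %/% 2 + 1 - h$n %/% 2
    big[lo:(lo + h$n - 1)] <- s
    s <- big
    # same geometry on the enlarged grid: target pitch shrinks by 1/m
    optics <- optical_config(optics$wavelength_nm, h$n * m,
                             optics$pitch_holo_mm, optics$focal_mm)
  }
  holo <- light_field(s, "holographic", optics)
  propagate(holo, "to_target")
}
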