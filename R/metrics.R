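#' Relative RMS target error
#'
#' Root-mean-square deviation between the reconstruction amplitude and the
#' target amplitude over the target domain, after rescaling the
#' reconstruction to unit maximum on the target domain (both profiles then
#' share the unit-peak convention), relative to the target's RMS:
#' \deqn{e = \sqrt{\sum_{TD} (\hat A - T)^2 / \sum_{TD} T^2}.}
#' A reconstruction that vanishes on the target domain has error 1 by
#' convention. Invariant under global rescaling of the reconstruction.
#'
#' @param recon_amplitude numeric vector or matrix of reconstruction
#'   amplitudes (same shape as the target pattern).
#' @param target a [target_1d()], or a list with elements `amplitude` and
#'   `target_domain` of matching shape (2D patterns).
#' @return error as a fraction (>= 0).
#' @export
target_error <- function(recon_amplitude, target) {
  td <- target$target_domain
  if (is.null(td)) td <- target$amplitude > 0
  if (!any(td)) stop("undefined metric: empty target domain")
  if (length(recon_amplitude) != length(target$amplitude))
    stop("shape mismatch between reconstruction and target")
  a <- recon_amplitude[td]
  t <- target$amplitude[td]
  if (max(a) == 0) return(1)
  a <- a / max(a)
  sqrt(sum((a - t)^2) / sum(t^2))
}

#' Speckle noise in the target domain
#'
#' Coefficient of variation (sd/mean) of the ratio of reconstructed intensity
#' to target intensity over the target domain; for flat targets this is the
#' CV of the intensity itself. Invariant under global intensity rescaling.
#'
#' @inheritParams target_error
#' @return speckle noise as a fraction.
#' @export
speckle_noise <- function(recon_amplitude, target) {
  td <- target$target_domain
  if (is.null(td)) td <- target$amplitude > 0
  if (!any(td)) stop("undefined metric: empty target domain")
  ratio <- (recon_amplitude[td]^2) / (target$amplitude[td]^2)
  m <- mean(ratio)
  if (m == 0) stop("undefined metric: zero mean intensity on the target domain")
  stats::sd(ratio) / m
}

#' First-order power efficiency
#'
#' Fraction of the input power diffracted into the first Bragg order. For a
#' 2D [reconstruct_2d()] result this is the reconstructed (post-mask,
#' post-aperture) power divided by the input power (beam power through the
#' aperture, before amplitude masks); power rejected by amplitude modulation
#' is transferred to the zero order and lost.
#'
#' @param result a `recon_result` from [reconstruct_2d()], or a
#'   `hologram_1d` (with `beam`) for the 1D bookkeeping.
#' @param beam a [beam_profile()] used for 1D holograms; default uniform.
#' @return efficiency in `[0, 1]`.
#' @export
power_efficiency <- function(result, beam = beam_profile("uniform")) {
  if (inherits(result, "recon_result")) {
    if (result$input_power <= 0) stop("zero input power")
    return(result$first_order_power / result$input_power)
  }
  if (inherits(result, "hologram_1d")) {
    b <- beam_amplitude_1d(beam, result$n)
    inp <- sum(b^2)
    if (inp <= 0) stop("zero input power")
    return(sum((result$mask * b)^2) / inp)
  }
  stop("power_efficiency expects a recon_result or hologram_1d")
}

#' Moving variance of the reconstructed phase
#'
#' Sliding-window variance of the phase, computed wrap-aware: within each
#' window the phase is referenced to the window's circular mean before
#' squaring, so 2 pi wraps do not inflate the variance. Window edges shrink
#' at the field boundary.
#'
#' @param field a 1D target-plane [light_field()] (or numeric phase vector
#'   with `pitch_um` supplied).
#' @param window_um window width in um (default 0.5).
#' @param pitch_um sample pitch in um; taken from the field if omitted.
#' @return numeric vector of per-sample phase variance (rad^2).
#' @export
moving_phase_variance <- function(field, window_um = 0.5, pitch_um = NULL) {
  if (inherits(field, "light_field")) {
    phi <- Arg(field$samples)
    pitch_um <- field$optics$pitch_target_um
  } else {
    phi <- as.numeric(field)
    if (is.null(pitch_um)) stop("pitch_um required for a raw phase vector")
  }
  n <- length(phi)
  w <- max(2L, as.integer(round(window_um / pitch_um)))
  if (w > n) stop("window exceeds the field extent")
  half <- w %/% 2
  z <- exp(1i * phi)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    mu <- Arg(mean(z[lo:hi]))
    d <- Arg(exp(1i * (phi[lo:hi] - mu)))
    out[i] <- mean(d^2)
  }
  out
}

#' Sweep the apodization gain of a static-target hologram
#'
#' Retrieves one static FM hologram per seed, applies a sequence of
#' apodization gains post hoc, and records the target error and power
#' efficiency of each apodized reconstruction (uniform beam).
#'
#' @param target a [target_1d()].
#' @param gains apodization gains to evaluate.
#' @param seeds integer seeds (one retrieval per seed).
#' @param cfg base [ift_config()].
#' @param optics an [optical_config()].
#' @return data.frame with columns `gain`, `mean_error`, `sd_error`,
#'   `mean_efficiency`, `sd_efficiency`, `n`.
#' @export
apodization_sweep <- function(target, gains = seq(0, 1, length.out = 10),
                              seeds = 1:30, cfg = ift_config(),
                              optics = optical_config()) {
  per_seed <- vapply(seeds, function(s) {
    cfg$seed <- s
    h <- gs_static(target, cfg, optics)
    vapply(gains, function(g) {
      ha <- apodize(h, g)
      amp <- Mod(field_samples(reconstruct_1d(ha, optics)))
      c(target_error(amp, target), power_efficiency(ha))
    }, numeric(2))
  }, matrix(0, 2, length(gains)))
  err <- per_seed[1, , , drop = FALSE]
  eff <- per_seed[2, , , drop = FALSE]
  data.frame(
    gain = gains,
    mean_error = apply(err, 2, mean),
    sd_error = apply(err, 2, stats::sd),
    mean_efficiency = apply(eff, 2, mean),
    sd_efficiency = apply(eff, 2, stats::sd),
    n = length(seeds)
  )
}

#' Sweep the amplitude-feedback gain of the complex engine
#'
#' Runs the complex engine at a sequence of maximum feedback gains and
#' records speckle noise (uniform-beam reconstruction) and first-order power
#' efficiency (Gaussian beam by default, per the power-budget convention).
#'
#' @param target a [target_1d()].
#' @param gains linear feedback gains in `[0, 0.99]`.
#' @param seeds integer seeds.
#' @param cfg base [ift_config()] (complex regularization).
#' @param optics an [optical_config()].
#' @param beam beam used for the efficiency bookkeeping.
#' @return data.frame with columns `gain`, `decadic_gain`, `mean_speckle`,
#'   `sd_speckle`, `mean_efficiency`, `sd_efficiency`, `n`.
#' @export
feedback_sweep <- function(target, gains = inverse_decadic_gain(seq(0, 1, length.out = 6)),
                           seeds = 1:30,
                           cfg = ift_config(iterations = 10, regularization = "complex"),
                           optics = optical_config(), beam = NULL) {
  if (is.null(beam))
    beam <- beam_profile("gaussian", diameter_samples = optics$n_grid)
  per_seed <- vapply(seeds, function(s) {
    vapply(gains, function(g) {
      cfg$seed <- s; cfg$gain_max <- g
      h <- gs_complex(target, cfg, optics)
      amp <- Mod(field_samples(reconstruct_1d(h, optics)))
      c(speckle_noise(amp, target), power_efficiency(h, beam))
    }, numeric(2))
  }, matrix(0, 2, length(gains)))
  spk <- per_seed[1, , , drop = FALSE]
  eff <- per_seed[2, , , drop = FALSE]
  data.frame(
    gain = gains,
    decadic_gain = decadic_gain(gains),
    mean_speckle = apply(spk, 2, mean),
    sd_speckle = apply(spk, 2, stats::sd),
    mean_efficiency = apply(eff, 2, mean),
    sd_efficiency = apply(eff, 2, stats::sd),
    n = length(seeds)
  )
}
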