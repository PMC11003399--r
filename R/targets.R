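#' 1D intensity target with target/freedom domain masks
#'
#' Holds a nonnegative amplitude profile (normalized to unit maximum), the
#' target-domain mask on which the amplitude is constrained during retrieval,
#' and an optional freedom-domain mask on which the field may evolve freely.
#' Samples in neither mask are clamped to zero.
#'
#' @param amplitude nonnegative numeric vector, length N.
#' @param target_domain logical mask; defaults to `amplitude > 0`.
#' @param freedom_domain logical mask, disjoint from `target_domain`, or NULL.
#' @param length_um physical extent of the target-domain support in um
#'   (derived from the optics if omitted).
#' @param optics optional [optical_config()] used to derive `length_um`.
#' @return object of class `target_1d`.
#' @export
target_1d <- function(amplitude, target_domain = NULL, freedom_domain = NULL,
                      length_um = NULL, optics = NULL) {
  if (any(amplitude < 0) || !all(is.finite(amplitude)))
    stop("target amplitude must be finite and nonnegative")
  if (max(amplitude) == 0) stop("degenerate target: all-zero amplitude")
  amplitude <- amplitude / max(amplitude)
  n <- length(amplitude)
  if (is.null(target_domain)) target_domain <- amplitude > 0
  if (length(target_domain) != n) stop("target_domain length mismatch")
  if (any(amplitude[!target_domain] != 0))
    stop("amplitude must be zero outside the target domain")
  if (!is.null(freedom_domain)) {
    if (length(freedom_domain) != n) stop("freedom_domain length mismatch")
    if (any(freedom_domain & target_domain))
      stop("target and freedom domains must be disjoint")
  }
  if (is.null(length_um) && !is.null(optics)) {
    sup <- range(which(target_domain))
    length_um <- diff(sup) * optics$pitch_target_um
  }
  structure(list(amplitude = amplitude,
                 target_domain = target_domain,
                 freedom_domain = freedom_domain,
                 length_um = length_um),
            class = "target_1d")
}

#' Add a default freedom domain to a target
#'
#' Marks everything outside the target-domain support, minus a guard band of
#' `guard` samples on each side, as freedom domain.
#'
#' @param target a [target_1d()].
#' @param guard guard-band half width in samples.
#' @return the target with `freedom_domain` set.
#' @export
with_freedom_domain <- function(target, guard = 2) {
  n <- length(target$amplitude)
  guarded <- target$target_domain
  for (i in which(target$target_domain)) {
    lo <- max(1, i - guard); hi <- min(n, i + guard)
    guarded[lo:hi] <- TRUE
  }
  target$freedom_domain <- !guarded
  target
}

#' Built-in target fixtures
#'
#' Deterministic generators for the study's standard 1D targets on the
#' configured grid. Point targets are one sample wide with points centered on
#' the grid; dense targets are sampled from their analytic profile.
#'
#' Available fixtures:
#' \describe{
#'   \item{three_point, five_point, seven_point}{3/5/7 equidistant unit
#'     points spanning `length_um` (defaults 8, 16, 21 um).}
#'   \item{seven_point_inhomogeneous}{as seven_point with amplitudes ramping
#'     linearly from 0.4 to 1.}
#'   \item{line_8um, line_16um, line_21um}{boxcar line segments.}
#'   \item{triangle, parabola, sinusoid}{dense profiles over `length_um`
#'     (default 8 um): symmetric triangle, inverted parabola, one-period
#'     raised cosine.}
#' }
#'
#' @param name fixture name (see Details).
#' @param optics an [optical_config()].
#' @param length_um overall target length L_S in um (fixture-specific default).
#' @return a [target_1d()].
#' @export
make_fixture <- function(name, optics, length_um = NULL) {
  n <- optics$n_grid
  du <- optics$pitch_target_um
  c0 <- n %/% 2 + 1
  points_target <- function(npts, ls, amps = rep(1, npts)) {
    sp <- ls / (npts - 1) / du
    idx <- c0 + round((seq_len(npts) - (npts + 1) / 2) * sp)
    if (any(idx < 1 | idx > n)) stop("target longer than the field of view")
    a <- numeric(n); a[idx] <- amps
    target_1d(a, length_um = ls, optics = optics)
  }
  dense_target <- function(ls, profile) {
    w <- round(ls / du / 2)
    idx <- (c0 - w):(c0 + w)
    if (any(idx < 1 | idx > n)) stop("target longer than the field of view")
    xx <- seq(-1, 1, length.out = length(idx))
    a <- numeric(n); a[idx] <- profile(xx)
    target_1d(a, length_um = ls, optics = optics)
  }
  switch(name,
    three_point = points_target(3, length_um %||% 8),
    five_point = points_target(5, length_um %||% 16),
    seven_point = points_target(7, length_um %||% 21),
    seven_point_inhomogeneous =
      points_target(7, length_um %||% 21, amps = seq(0.4, 1, length.out = 7)),
    line_8um = dense_target(length_um %||% 8, function(x) rep(1, length(x))),
    line_16um = dense_target(length_um %||% 16, function(x) rep(1, length(x))),
    line_21um = dense_target(length_um %||% 21, function(x) rep(1, length(x))),
    triangle = dense_target(length_um %||% 8, function(x) 1 - abs(x)),
    parabola = dense_target(length_um %||% 8, function(x) 1 - x^2),
    sinusoid = dense_target(length_um %||% 8, function(x) 0.5 * (1 + cos(pi * x))),
    stop(sprintf("unknown fixture '%s'", name))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
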