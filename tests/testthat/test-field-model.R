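test_that("optical_config derives the target pitch consistently", {
  opt <- optical_config(940, 1024, 15 / 1024, 8)
  expected <- 940e-9 * 8e-3 / (1024 * 15 / 1024 * 1e-3) * 1e6
  expect_equal(opt$pitch_target_um, expected, tolerance = 1e-12)
  expect_error(optical_config(n_grid = 15), "even")
  expect_error(optical_config(wavelength_nm = -1), "positive")
})

test_that("propagation is a unitary DC-centered transform", {
  opt <- small_optics(64)
  n <- 64
  # constant field -> single central peak carrying all power
  f <- light_field(rep(1 + 0i, n), "holographic", opt)
  g <- propagate(f, "to_target")
  amp <- Mod(field_samples(g))
  expect_equal(which.max(amp), n %/% 2 + 1)
  expect_equal(sum(amp^2), n, tolerance = 1e-10)
  expect_equal(max(amp)^2, n, tolerance = 1e-10)
  expect_identical(g$plane, "target")

  # linear phase ramp displaces the peak by k samples (shift theorem)
  for (k in c(1, 5, -7)) {
    s <- exp(2i * pi * k * (0:(n - 1)) / n)
    amp <- Mod(field_samples(propagate(light_field(s, "holographic", opt), "to_target")))
    expect_equal(which.max(amp), n %/% 2 + 1 + k)
  }

  # unitarity and roundtrip over random fields
  for (seed in 1:100) {
    s <- random_complex(n, seed)
    f <- light_field(s, "target", opt)
    b <- propagate(f, "to_hologram")
    expect_equal(sum(Mod(field_samples(b))^2), sum(Mod(s)^2), tolerance = 1e-10)
    rt <- field_samples(propagate(b, "to_target"))
    expect_lt(max(Mod(rt - s)), 1e-10)
  }

  # plane-tag discipline and invalid fields
  expect_error(propagate(f, "to_target"), "holographic")
  expect_error(light_field(c(1, NaN), "target", opt), "non-finite")
})

test_that("hard apertures zero samples outside and keep samples inside", {
  opt <- small_optics(64)
  n <- 64
  u <- light_field(matrix(1 + 0i, n, n), "holographic", opt)
  circ <- apply_aperture(u, aperture_spec("circular", n))
  ratio <- sum(Mod(field_samples(circ))^2) / sum(Mod(field_samples(u))^2)
  # disk/square area ratio, within one boundary-pixel ring
  ring <- 4 * pi * (n / 2) / n^2
  expect_lt(abs(ratio - pi / 4), ring)
  expect_true(all(field_samples(circ) %in% c(0 + 0i, 1 + 0i)))

  sq <- apply_aperture(u, aperture_spec("square", n))
  expect_equal(field_samples(sq), field_samples(u))

  zero <- apply_aperture(u, aperture_spec("circular", 0))
  expect_true(all(field_samples(zero) == 0))

  expect_error(apply_aperture(u, aperture_spec("circular", n + 2)), "exceeds")
})

test_that("beam profiles follow the 1/e^2 amplitude convention", {
  opt <- small_optics(64)
  n <- 64
  f1 <- light_field(random_complex(n, 1), "holographic", opt)
  expect_equal(field_samples(apply_beam(f1, beam_profile("uniform"))),
               field_samples(f1))
  d <- 32
  g <- beam_profile("gaussian", diameter_samples = d)
  b <- aoholo:::beam_amplitude_1d(g, n)
  c0 <- n %/% 2 + 1
  # 1/e^2 intensity definition: intensity falls to e^-2 at r = d/2
  expect_equal(b[c0 + d / 2]^2, exp(-2), tolerance = 1e-12)
  u <- light_field(rep(1 + 0i, n), "holographic", opt)
  expect_lt(sum(Mod(field_samples(apply_beam(u, g)))^2),
            sum(Mod(field_samples(u))^2))
})

test_that("ps2D embedding is separable and midlines recover axis profiles", {
  opt <- small_optics(64)
  n <- 64
  # zero phases, unit amplitudes -> constant unit field
  e0 <- embed_ps2d(numeric(n), numeric(n), rep(1, n), rep(1, n), opt)
  expect_true(all(field_samples(e0) == 1 + 0i))

  # cylindrical wavefront: quadratic on x only, constant along y
  qx <- 1e-3 * (axis <- seq_len(n) - n / 2)^2
  ec <- field_samples(embed_ps2d(qx, numeric(n), rep(1, n), rep(1, n), opt))
  expect_equal(ec[, 1], ec[, n])

  # reconstruction amplitude of an embedded field factorizes (square aperture)
  set.seed(42)
  px <- stats::runif(n, 0, 2 * pi); py <- stats::runif(n, 0, 2 * pi)
  ax <- stats::runif(n); ay <- stats::runif(n)
  f2 <- propagate(embed_ps2d(px, py, ax, ay, opt), "to_target")
  a2 <- Mod(field_samples(f2))
  a1x <- Mod(field_samples(propagate(light_field(ax * exp(1i * px), "holographic", opt), "to_target")))
  a1y <- Mod(field_samples(propagate(light_field(ay * exp(1i * py), "holographic", opt), "to_target")))
  expect_equal(a2, outer(a1x, a1y), tolerance = 1e-8)

  # midline of the separable field is proportional to the x-axis reconstruction
  mid <- Mod(field_samples(extract_midline(f2, "x")))
  c0 <- n %/% 2 + 1
  expect_equal(mid / max(mid), a1x * a1y[c0] / max(a1x * a1y[c0]), tolerance = 1e-8)

  # centered point target through a circular aperture: midline equals the
  # brute-force central row of the 2D disk transform (Airy-like profile)
  disk <- aoholo:::aperture_mask_2d(aperture_spec("circular", n), n)
  fd <- propagate(light_field(disk * (1 + 0i), "holographic", opt), "to_target")
  mid2 <- field_samples(extract_midline(fd, "x"))
  brute <- aoholo:::fft_shift(stats::fft(aoholo:::fft_shift(disk * (1 + 0i)))) / n
  expect_equal(mid2, brute[, c0], tolerance = 1e-10)

  # zero field stays zero; errors on bad shapes
  z <- propagate(light_field(matrix(0i, n, n), "holographic", opt), "to_target")
  expect_true(all(Mod(field_samples(extract_midline(z))) == 0))
  expect_error(embed_ps2d(numeric(n), numeric(n - 1), rep(1, n), rep(1, n), opt),
               "length")
})
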