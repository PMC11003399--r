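test_that("decadic gain follows the printed formula and inverts exactly", {
  expect_equal(decadic_gain(0), 0)
  expect_equal(decadic_gain(0.9), 0.5)
  expect_equal(decadic_gain(0.99), 1)
  g <- seq(0, 0.99, by = 0.01)
  expect_equal(inverse_decadic_gain(decadic_gain(g)), g, tolerance = 1e-12)
  expect_error(decadic_gain(1), "gain")
  expect_error(ift_config(gain_max = 1), "gain_max")
})

test_that("a centered point target yields a flat phase and a diffraction-limited spot", {
  opt <- small_optics(64)
  tp <- point_target(opt)
  h <- gs_static(tp, ift_config(iterations = 20, seed = 3), opt)
  # constant phase modulo a global offset
  expect_lt(diff(range(h$phase)), 1e-8)
  amp <- recon_amp(h, opt)
  expect_equal(which.max(amp), 33)
  expect_equal(target_error(amp, tp), 0, tolerance = 1e-10)

  # complex engine: feedback has nothing to correct -> flat mask, flat phase
  hc <- gs_complex(tp, ift_config(iterations = 10, seed = 3, regularization = "complex"), opt)
  expect_lt(diff(range(hc$mask)), 1e-8)
  expect_lt(diff(range(hc$phase)), 1e-8)
})

test_that("static retrieval leaves ghost side lobes and a nonzero target error", {
  opt <- small_optics(128)
  t3 <- make_fixture("three_point", opt)
  h <- gs_static(t3, ift_config(iterations = 200, seed = 1), opt)
  amp <- recon_amp(h, opt)
  expect_gt(h$error, 0.02)
  # off-target power (ghost orders) is present
  off <- sum(amp[!t3$target_domain]^2) / sum(amp^2)
  expect_gt(off, 0.001)
  # degenerate target is rejected upstream
  expect_error(target_1d(numeric(128)), "degenerate")
})

test_that("dynamic regularization homogenizes target peaks relative to static", {
  opt <- small_optics(128)
  for (fix in c("three_point", "five_point")) {
    tg <- make_fixture(fix, opt)
    spread <- vapply(1:5, function(s) {
      hs <- gs_static(tg, ift_config(iterations = 150, seed = s), opt)
      hd <- gs_dynamic(tg, ift_config(iterations = 150, seed = s,
                                      regularization = "dynamic"), opt)
      as <- recon_amp(hs, opt)[tg$target_domain]
      ad <- recon_amp(hd, opt)[tg$target_domain]
      c(diff(range(as)) / max(as), diff(range(ad)) / max(ad))
    }, numeric(2))
    expect_lt(mean(spread[2, ]), mean(spread[1, ]))
  }
})

test_that("an explicitly empty freedom domain reproduces the static engine", {
  opt <- small_optics(128)
  t5 <- make_fixture("five_point", opt)
  t5$freedom_domain <- rep(FALSE, 128)
  hs <- gs_static(make_fixture("five_point", opt), ift_config(iterations = 50, seed = 7), opt)
  hd <- gs_dynamic(t5, ift_config(iterations = 50, seed = 7,
                                  regularization = "dynamic"), opt)
  expect_identical(hd$phase, hs$phase)
  expect_identical(hd$mask, hs$mask)
})

test_that("domain mixing trades off on-target speckle against off-target power", {
  opt <- small_optics(128)
  tl <- make_fixture("line_8um", opt)
  res <- vapply(1:5, function(s) {
    hs <- gs_static(tl, ift_config(iterations = 150, seed = s), opt)
    hd <- gs_dynamic(tl, ift_config(iterations = 150, seed = s,
                                    regularization = "dynamic"), opt)
    as <- recon_amp(hs, opt); ad <- recon_amp(hd, opt)
    td <- tl$target_domain
    c(speckle_noise(as, tl), speckle_noise(ad, tl),
      sum(as[!td]^2) / sum(as^2), sum(ad[!td]^2) / sum(ad^2))
  }, numeric(4))
  expect_lt(mean(res[2, ]), mean(res[1, ]))  # on-target speckle reduced
  expect_gt(mean(res[4, ]), mean(res[3, ]))  # off-target power increased
  expect_error(target_1d(tl$amplitude, freedom_domain = tl$target_domain),
               "disjoint")
})

test_that("apodization blends toward the stored holographic amplitude", {
  opt <- small_optics(128)
  t5 <- make_fixture("five_point", opt)
  h <- gs_static(t5, ift_config(iterations = 100, seed = 2), opt)
  h0 <- apodize(h, 0)
  expect_true(all(h0$mask == 1))
  expect_identical(h0$mode, "FM")
  h1 <- apodize(h, 1)
  expect_identical(h1$mode, "FM/AM")
  expect_equal(h1$mask, h$holo_amplitude)
  expect_identical(h1$phase, h$phase)
  expect_error(apodize(h, 1.5), "gain")
  # full apodization removes the target side lobes
  for (fix in c("three_point", "five_point", "seven_point")) {
    tg <- make_fixture(fix, opt)
    ha <- apodize(gs_static(tg, ift_config(iterations = 100, seed = 2), opt), 1)
    amp <- recon_amp(ha, opt)
    off <- sum(amp[!tg$target_domain]^2) / sum(amp^2)
    expect_lt(off, 1e-10)
    expect_lt(target_error(amp, tg), 1e-6)
  }
  # efficiency is lower at full apodization than without it
  expect_lt(power_efficiency(h1), power_efficiency(h0))
})

test_that("amplitude feedback suppresses speckle on dense targets", {
  opt <- small_optics(128)
  t8 <- make_fixture("line_8um", opt)
  cfgc <- function(s, g) ift_config(iterations = 10, seed = s,
                                    regularization = "complex", gain_max = g)
  res <- vapply(1:5, function(s) {
    h99 <- gs_complex(t8, cfgc(s, 0.99), opt)
    h0 <- gs_complex(t8, cfgc(s, 0), opt)
    c(speckle_noise(recon_amp(h99, opt), t8),
      speckle_noise(recon_amp(h0, opt), t8))
  }, numeric(2))
  expect_lt(mean(res[1, ]), 0.05)          # vanishing at full gain
  expect_gt(mean(res[2, ]), 5 * mean(res[1, ]))  # high at zero feedback
  # triangular, parabolic, sinusoidal targets: near noise-free at full gain
  for (fix in c("triangle", "parabola", "sinusoid")) {
    tg <- make_fixture(fix, opt)
    h <- gs_complex(tg, cfgc(1, 0.99), opt)
    expect_lt(target_error(recon_amp(h, opt), tg), 0.1)
  }
})

test_that("holograms are deterministic and self-consistent", {
  opt <- small_optics(128)
  t8 <- make_fixture("line_8um", opt)
  cfg <- ift_config(iterations = 10, seed = 11, regularization = "complex")
  h1 <- gs_complex(t8, cfg, opt)
  h2 <- gs_complex(t8, cfg, opt)
  expect_identical(h1$phase, h2$phase)
  expect_identical(h1$mask, h2$mask)
  # recorded error equals a fresh reconstruction through the forward model
  expect_equal(target_error(recon_amp(h1, opt), t8), h1$error, tolerance = 1e-12)
  hs <- gs_static(t8, ift_config(iterations = 20, seed = 11), opt)
  expect_equal(target_error(recon_amp(hs, opt), t8), hs$error, tolerance = 1e-12)
  # wrapped phase is the unwrapped phase modulo 2 pi
  expect_equal(Arg(exp(1i * h1$phase)), h1$phase_wrapped, tolerance = 1e-12)
})

test_that("the amplitude mask carries harmonics of the phase modulation", {
  opt <- optical_config()
  t3 <- make_fixture("three_point", opt)
  h <- gs_static(t3, ift_config(iterations = 200, seed = 1), opt)
  n <- opt$n_grid
  spec_of <- function(x) Mod(aoholo:::ft_centered(as.complex(x - mean(x))))
  k <- abs(axis_coordinates <- seq_len(n) - (n %/% 2 + 1))
  ph <- spec_of(h$phase_wrapped)
  k0 <- k[which.max(ph)]
  expect_gt(k0, 0)
  am <- spec_of(h$holo_amplitude)
  at_2k0 <- max(am[k == 2 * k0])
  background <- stats::median(am[k > 0])
  expect_gt(at_2k0, 10 * background)
})

test_that("extended retrieval degenerates gracefully", {
  opt <- small_optics(64)
  tp <- point_target(opt)
  cfg <- ift_config(iterations = 10, seed = 5, regularization = "complex")
  # point target: aperture is irrelevant for a flat wavefront
  he <- gs_extended(tp, aperture_spec("circular", 64), cfg, opt)
  hp <- gs_complex(tp, cfg, opt)
  expect_equal(diff(range(he$phase)), 0, tolerance = 1e-8)
  expect_equal(he$mask, hp$mask, tolerance = 1e-8)
  # square aperture falls back to the plain engine with a warning
  expect_warning(hsq <- gs_extended(tp, aperture_spec("square", 64), cfg, opt),
                 "square")
  expect_equal(hsq$phase, hp$phase)
})
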