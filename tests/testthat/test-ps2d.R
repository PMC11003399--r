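test_that("composed point-grid holograms reconstruct the expected grids", {
  opt <- small_optics(128)
  cfg <- function(s) ift_config(iterations = 100, seed = s)
  t5 <- make_fixture("five_point", opt)
  t7 <- make_fixture("seven_point", opt)
  h5 <- gs_static(t5, cfg(1), opt)
  h7 <- gs_static(t7, cfg(2), opt)
  ph <- compose(h5, h7)
  rec <- reconstruct_2d(ph, aperture_spec("square", 128),
                        beam_profile("uniform"), opt)
  # 5 x 7 grid: intensity concentrated on the Cartesian product of supports
  grid_td <- outer(t5$target_domain, t7$target_domain) > 0
  frac <- sum(rec$intensity[grid_td]) / sum(rec$intensity)
  expect_gt(frac, 0.5)
  expect_equal(sum(grid_td), 35)
  peaks <- rec$intensity >= 0.3 * max(rec$intensity)
  expect_true(all(which(peaks) %in% which(grid_td)))

  # identical holograms on both axes: symmetric under x <-> y
  ps <- compose(h5, h5)
  rs <- reconstruct_2d(ps, aperture_spec("square", 128), beam_profile("uniform"), opt)
  expect_equal(rs$intensity, t(rs$intensity), tolerance = 1e-10)

  # hybrid: the amplitude mask varies only along the FM/AM axis
  hc <- gs_complex(make_fixture("line_8um", opt),
                   ift_config(iterations = 10, seed = 1, regularization = "complex"), opt)
  hyb <- compose(hc, h5)
  expect_identical(hyb$mode_x, "FM/AM")
  expect_identical(hyb$mode_y, "FM")
  emb <- embed_ps2d(hyb$hologram_x$phase, hyb$hologram_y$phase,
                    hc$mask, rep(1, 128), opt)
  m <- Mod(field_samples(emb))
  expect_equal(m[, 1], m[, 128])          # constant along y
  expect_gt(diff(range(m[, 1])), 0.01)    # modulated along x
  expect_error(compose(h5, gs_static(point_target(small_optics(64)),
                                     ift_config(iterations = 5), small_optics(64))),
               "length")
})

test_that("square-aperture reconstruction factorizes into 1D reconstructions", {
  opt <- small_optics(128)
  t8 <- make_fixture("line_8um", opt)
  hx <- gs_complex(t8, ift_config(iterations = 10, seed = 1, regularization = "complex"), opt)
  hy <- gs_static(make_fixture("three_point", opt), ift_config(iterations = 50, seed = 2), opt)
  rec <- reconstruct_2d(compose(hx, hy), aperture_spec("square", 128),
                        beam_profile("uniform"), opt)
  ax <- recon_amp(hx, opt); ay <- recon_amp(hy, opt)
  expect_equal(rec$amplitude, outer(ax, ay), tolerance = 1e-8)
})

test_that("reconstruction power bookkeeping matches the AM-sink model", {
  opt <- small_optics(64)
  tp <- point_target(opt)
  hf <- gs_static(tp, ift_config(iterations = 5, seed = 1), opt)
  # pure phase, uniform beam, square aperture: lossless
  r <- reconstruct_2d(compose(hf, hf), aperture_spec("square", 64),
                      beam_profile("uniform"), opt)
  expect_equal(power_efficiency(r), 1, tolerance = 1e-12)
  # a flat mask of 0.5 scales the power by 0.25 per axis pair
  hm <- hf; hm$mask <- rep(0.5, 64); hm$mode <- "FM/AM"
  r2 <- reconstruct_2d(compose(hm, hf), aperture_spec("square", 64),
                       beam_profile("uniform"), opt)
  expect_equal(power_efficiency(r2), 0.25, tolerance = 1e-12)
  # zero-phase unit-amplitude hologram with circular aperture: Airy-type spot
  rc <- reconstruct_2d(compose(hf, hf), aperture_spec("circular", 64),
                       beam_profile("uniform"), opt)
  c0 <- 33
  expect_equal(which(rc$intensity == max(rc$intensity)),
               (c0 - 1) * 64 + c0)
  expect_lt(power_efficiency(rc), 1 + 1e-12)
})

test_that("the separability test agrees with a brute-force singular-value oracle", {
  # oracle: residual from the eigendecomposition of the Gram matrix
  oracle <- function(m) {
    g <- eigen(crossprod(m), symmetric = TRUE, only.values = TRUE)$values
    sqrt(max(0, 1 - g[1] / sum(g)))
  }
  set.seed(99)
  for (rep in 1:60) {
    nr <- sample(2:8, 1); nc <- sample(2:8, 1)
    m <- matrix(stats::rbinom(nr * nc, 1, 0.4), nr, nc)
    if (all(m == 0)) next
    r <- is_ps2d_separable(m, tol = 1e-6)
    expect_equal(r$residual, oracle(m), tolerance = 1e-10)
    expect_identical(r$separable, oracle(m) < 1e-6)
    if (r$separable)
      expect_equal(outer(r$profile_x, r$profile_y), m + 0, tolerance = 1e-8)
  }
  # axis-aligned rectangles are separable
  rect <- matrix(0, 16, 16); rect[4:9, 11:14] <- 1
  expect_true(is_ps2d_separable(rect)$separable)
  # random outer products are separable; 10% noise breaks them at tol 1e-3
  set.seed(7)
  u <- stats::runif(32); v <- stats::runif(32)
  prod <- outer(u, v)
  expect_true(is_ps2d_separable(prod, tol = 1e-3)$separable)
  noisy <- prod + 0.1 * mean(prod) * matrix(stats::runif(32 * 32), 32, 32)
  expect_false(is_ps2d_separable(noisy, tol = 1e-3)$separable)
  # all-zero pattern: trivially separable with zero profiles
  z <- is_ps2d_separable(matrix(0, 4, 4))
  expect_true(z$separable)
  expect_equal(z$profile_x, numeric(4))
})

test_that("two-photon rendering squares intensities and enhances contrast", {
  expect_equal(two_photon_render(matrix(2, 3, 3)), matrix(1, 3, 3))
  spots <- matrix(0, 4, 4); spots[1, 1] <- 2; spots[3, 3] <- 1
  r <- two_photon_render(spots)
  expect_equal(r[1, 1] / r[3, 3], 4)
  # speckled pattern: contrast strictly larger after squaring
  set.seed(5)
  speck <- matrix(stats::rexp(64), 8, 8)
  cv <- function(x) stats::sd(x) / mean(x)
  expect_gt(cv(as.vector(two_photon_render(speck))), cv(as.vector(speck)))
})
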