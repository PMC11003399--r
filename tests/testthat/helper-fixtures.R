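# Small optics used throughout the unit tests: 0.5 um/sample target pitch on
# a reduced grid, same sampling density as the package default.
small_optics <- function(n = 128) {
  optical_config(wavelength_nm = 940, n_grid = n,
                 pitch_holo_mm = 15 / 1024, focal_mm = 8 * n / 1024)
}

# random complex field samples with a fixed RNG scope
random_complex <- function(n, seed) {
  set.seed(seed)
  complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
}

# a one-sample point target at the grid center
point_target <- function(optics) {
  a <- numeric(optics$n_grid)
  a[optics$n_grid %/% 2 + 1] <- 1
  target_1d(a, optics = optics)
}

recon_amp <- function(h, optics, beam = beam_profile("uniform")) {
  Mod(field_samples(reconstruct_1d(h, optics, beam)))
}
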