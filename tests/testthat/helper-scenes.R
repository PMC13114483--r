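# Shared fixture builders. Everything is generated in code at test time.

# homogeneous planar scene rendered noiselessly and calibrated
planar_rd_pair <- function(mu_a, mu_s_prime, size = 32, fx_ac = 0.2) {
  map <- optical_property_map(matrix(mu_a, size, size),
                              matrix(mu_s_prime, size, size), 100 / size)
  stack <- render_stack(map, fx_ac = fx_ac, noise_sd = 0)
  ref <- render_reference_stack(fx_ac, c(size, size),
                                pixel_size_mm = 100 / size)
  c(demodulate_stack(stack, ref), list(map = map))
}

# scalar diffusion-model reflectance written out longhand, independent of
# the vectorized implementation: the brute-force oracle
oracle_rd <- function(mu_a, mu_s_prime, fx, n = 1.43) {
  reff <- 0.0636 * n + 0.668 + 0.71 / n - 1.44 / n / n
  a <- (1 - reff) / (2 * (1 + reff))
  mutr <- mu_a + mu_s_prime
  mueff <- sqrt(3 * mu_a * mutr + (2 * pi * fx)^2)
  3 * a * (mu_s_prime / mutr) / ((mueff / mutr + 1) * (mueff / mutr + 3 * a))
}

# small bruise-scene paired dataset on disk for translator tests
smoke_dataset <- function(dir, n = 40, size = 64, seed = 3) {
  sweep <- data.frame(mu_a = 0.0324,
                      mu_s_prime = seq(1.3, 2.2, length.out = n),
                      bruise_radius_mm = rep(c(0, 12, 15, 18),
                                             length.out = n),
                      severity = rep(c(0, 0.5, 1, 0.75), length.out = n))
  build_dataset(dir, sweep, size = size, seed = seed)
  load_paired_dataset(dir)
}

# validation NMAE of the reduced scattering channel for a generator
val_nmae_mus <- function(gen, data, size = 64) {
  mean(vapply(data$validation, function(s) {
    p <- predict_optical(gen, s$x, pixel_size_mm = 100 / size)
    ref <- decode_rgb_label(s$y, pixel_size_mm = 100 / size)
    nmae(p$mu_s_prime, ref$mu_s_prime)
  }, numeric(1)))
}
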