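test_that("fruit maps carry the bruise geometry and severity interpolation", {
  spec <- fruit_scene_spec("apple", size = 64, severity = 1, seed = 5)
  scene <- make_fruit_map(spec)
  expect_equal(unique(scene$map$mu_s_prime[scene$bruise_mask]), 1.215)
  expect_equal(unique(scene$map$mu_s_prime[!scene$bruise_mask]), 1.726)
  # equal-area sound annulus (within pixelization)
  expect_equal(sum(scene$sound_mask), sum(scene$bruise_mask),
               tolerance = 0.05)
  expect_false(any(scene$bruise_mask & scene$sound_mask))

  half <- make_fruit_map(fruit_scene_spec("apple", size = 64,
                                          severity = 0.5))
  expect_equal(unique(half$map$mu_s_prime[half$bruise_mask]),
               (1.726 + 1.215) / 2)
  sound <- make_fruit_map(fruit_scene_spec("apple", size = 64,
                                           severity = 0))
  expect_equal(unique(as.numeric(sound$map$mu_s_prime)), 1.726)
})

test_that("pear scenes add seeded speckle and exceed apple scattering", {
  p1 <- make_fruit_map(fruit_scene_spec("pear", size = 32, seed = 7))
  p2 <- make_fruit_map(fruit_scene_spec("pear", size = 32, seed = 7))
  expect_identical(p1$map$mu_s_prime, p2$map$mu_s_prime)
  p3 <- make_fruit_map(fruit_scene_spec("pear", size = 32, seed = 8))
  expect_false(identical(p1$map$mu_s_prime, p3$map$mu_s_prime))
  expect_gt(fruit_optics$pear$mu_s_prime, fruit_optics$apple$mu_s_prime)
  expect_gt(fruit_optics$pear$mu_s_prime_bruised,
            fruit_optics$apple$mu_s_prime_bruised)
  expect_error(make_fruit_map(fruit_scene_spec("apple", size = 16,
                                               bruise_radius_mm = 45)),
               "exceed")
})

test_that("rendering is deterministic and degenerates correctly", {
  map <- optical_property_map(matrix(0.05, 16, 16), matrix(1.5, 16, 16),
                              100 / 16)
  s1 <- render_stack(map, noise_sd = 0.01, seed = 11)
  s2 <- render_stack(map, noise_sd = 0.01, seed = 11)
  expect_identical(s1$i1, s2$i1)
  expect_identical(s1$i_dc, s2$i_dc)
  # zero modulation: all AC frames collapse onto the DC image
  s3 <- render_stack(map, a1 = 0, noise_sd = 0)
  expect_equal(s3$i1, s3$i_dc)
  expect_equal(s3$i2, s3$i3)
  expect_error(render_stack(map, a0 = 0.2, a1 = 0.5), "a0 >= a1")
})

test_that("reference stack self-calibrates to its reflectivity", {
  ref <- render_reference_stack(0.2, c(16, 16), pixel_size_mm = 100 / 16)
  cal <- demodulate_stack(ref, ref)
  expect_equal(unique(round(as.numeric(cal$rd_ac), 12)), 0.99)
  expect_equal(unique(round(as.numeric(cal$rd_dc), 12)), 0.99)
})

test_that("RGB label encoding hits the endpoints and round-trips", {
  m <- optical_property_map(matrix(c(0, 0.5), 1, 2),
                            matrix(c(1e-6, 4), 1, 2), 1)
  lab <- encode_rgb_label(m)
  expect_equal(lab[1, 1, ], c(0, 0, 0))
  expect_equal(lab[1, 2, ], c(255, 255, 0))
  expect_true(all(lab[, , 3] == 0))

  set.seed(21)
  mm <- optical_property_map(matrix(runif(64, 0, 0.5), 8),
                             matrix(runif(64, 0.05, 4), 8), 1)
  dec <- decode_rgb_label(encode_rgb_label(mm), pixel_size_mm = 1)
  expect_lte(max(abs(dec$mu_a - mm$mu_a)), 0.5 / 510 + 1e-12)
  expect_lte(max(abs(dec$mu_s_prime - mm$mu_s_prime)), 4 / 510 + 1e-12)

  bad <- optical_property_map(matrix(0.6, 2, 2), matrix(1, 2, 2), 1)
  expect_error(encode_rgb_label(bad), "norm_ranges")
})

test_that("small sweeps split 7:3 deterministically", {
  dir <- withr::local_tempdir()
  sweep <- expand.grid(mu_a = seq(0.05, 0.3, length.out = 2),
                       mu_s_prime = seq(1, 3, length.out = 5))
  man <- build_dataset(dir, sweep, size = 16, seed = 9)
  expect_equal(man$n_total, 10)
  expect_equal(man$n_train, 7)
  expect_equal(man$n_validation, 3)
  splits <- vapply(man$entries, function(e) e$split, character(1))
  expect_equal(sum(splits == "train"), 7)
  man2 <- build_dataset(withr::local_tempdir(), sweep, size = 16, seed = 9)
  expect_identical(vapply(man2$entries, function(e) e$split, character(1)),
                   splits)
  # files and manifest agree
  data <- load_paired_dataset(dir)
  expect_length(data$train, 7)
  expect_equal(dim(data$train[[1]]$y), c(16, 16, 3))
})
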