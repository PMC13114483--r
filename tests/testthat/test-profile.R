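test_that("four-step phase estimation returns the injected phase", {
  mk <- function(phi, b = 0.4) {
    f <- lapply(c(0, pi / 2, pi, 3 * pi / 2), function(psi) {
      matrix(0.5 + b * cos(phi + psi), 2, 2)
    })
    names(f) <- c("f1", "f2", "f3", "f4")
    f
  }
  expect_equal(wrapped_phase(mk(0.7))[1, 1], 0.7, tolerance = 1e-12)
  # wrapping convention: result lives in (-pi, pi]
  w <- wrapped_phase(mk(pi + 0.1))[1, 1]
  expect_equal(w, -pi + 0.1, tolerance = 1e-12)
  expect_gt(w, -pi)
  # zero modulation flags every pixel
  z <- wrapped_phase(mk(0.7, b = 0))
  expect_true(all(attr(z, "flagged")))
})

test_that("phase unwrapping restores a multi-period ramp", {
  size <- 48
  ramp <- matrix(seq(0, 6 * pi, length.out = size), size, size,
                 byrow = TRUE) +
    matrix(seq(0, 2 * pi, length.out = size), size, size)
  wrapped <- ramp - 2 * pi * round(ramp / (2 * pi))
  un <- unwrap_phase(wrapped)
  # output differs from the wrapped input by exact multiples of 2 pi
  k <- (un - wrapped) / (2 * pi)
  expect_lt(max(abs(k - round(k))), 1e-9)
  # and reproduces the ramp up to one global 2 pi multiple
  off <- un - ramp
  expect_lt(diff(range(off)), 1e-9)
  # already-continuous input is unchanged
  smooth <- matrix(seq(-1, 1, length.out = size), size, size)
  expect_equal(unwrap_phase(smooth), smooth, tolerance = 1e-12)
})

test_that("phase-to-height and the correction field follow their formulas", {
  expect_equal(phase_to_height(matrix(0, 2, 2), 5), matrix(0, 2, 2))
  dphi <- matrix(c(1, 2, 3, 4), 2)
  expect_equal(phase_to_height(dphi, 2), 2 * dphi)
  expect_equal(phase_to_height(dphi, 4), 2 * phase_to_height(dphi, 2))
  expect_error(phase_to_height(dphi, 0), "k_height")

  h <- matrix(c(0, 5, 10, 2), 2)
  cc <- correction_field(h, c_min = 0.05)
  expect_equal(cc[2, 1], 0.5)
  expect_equal(max(cc), 1)
  expect_equal(cc[1, 1], 0.05)          # clamped at the rim
  expect_true(attr(cc, "low_confidence")[1, 1])
  expect_error(correction_field(matrix(0, 2, 2)), "zero")
})

test_that("profile correction inverts the injected curved-surface distortion", {
  spec <- fruit_scene_spec("apple", size = 64, surface = "spherical_cap",
                           height_max_mm = 20, severity = 1, seed = 13)
  scene <- render_curved_scene(spec, noise_sd = 0)
  # center pixel is undistorted
  expect_equal(max(scene$correction), 1)
  # with the exact injected field the correction is an exact inverse
  ref <- render_reference_stack(0.2, c(64, 64), pixel_size_mm = 100 / 64)
  cal <- demodulate_stack(scene$stack, ref)
  flat <- diffuse_reflectance(scene$map$mu_a, scene$map$mu_s_prime, 0.2)
  fixed <- correct_reflectance(cal$rd_ac, scene$correction)
  expect_equal(max(abs(fixed - flat)), 0, tolerance = 1e-9)
  # identity when c is one everywhere
  expect_identical(correct_reflectance(flat, matrix(1, 64, 64)), flat)
})

test_that("profilometry recovers the cap height and reduces reflectance CV", {
  for (seed in c(13, 29)) {
    spec <- fruit_scene_spec("apple", size = 64, surface = "spherical_cap",
                             height_max_mm = 20, severity = 1, seed = seed)
    scene <- render_curved_scene(spec, noise_sd = 0)
    res <- profile_correct_scene(scene)
    expect_lt(max(abs(res$height - scene$height)) / 20, 0.02)
    cv_un <- coefficient_of_variation(res$rd_ac_raw)
    cv_corr <- coefficient_of_variation(res$rd_ac)
    expect_lt(cv_corr, cv_un)
    # corrected reflectance close to the flat-scene value away from the rim
    flat <- diffuse_reflectance(scene$map$mu_a, scene$map$mu_s_prime, 0.2)
    core <- scene$correction > 0.2
    expect_lt(max(abs((res$rd_ac[core] - flat[core]) / flat[core])), 0.02)
  }
})
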