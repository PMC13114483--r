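test_that("effective reflection coefficient matches the polynomial", {
  expect_equal(effective_reflection_coefficient(1.0), 0.0016)
  expect_equal(effective_reflection_coefficient(1.43),
               0.0636 * 1.43 + 0.668 + 0.71 / 1.43 - 1.44 / 1.43^2)
  expect_equal(effective_reflection_coefficient(1.43), 0.5513,
               tolerance = 1e-4)
  # determinism
  expect_identical(effective_reflection_coefficient(1.43),
                   effective_reflection_coefficient(1.43))
  expect_error(effective_reflection_coefficient(0.9), "refractive")
})

test_that("proportionality constant follows the boundary formula", {
  expect_equal(proportionality_constant(0), 0.5)
  reff <- effective_reflection_coefficient(1.43)
  expect_equal(proportionality_constant(reff), (1 - reff) / (2 * (1 + reff)))
  expect_equal(proportionality_constant(reff), 0.1446, tolerance = 5e-4)
  expect_lt(proportionality_constant(1 - 1e-9), 1e-8)   # A -> 0 as Reff -> 1
  expect_error(proportionality_constant(1), "\\[0, 1\\)")
})

test_that("diffuse reflectance hits the lossless limit and the scalar oracle", {
  # lossless medium at DC reflects everything
  expect_equal(diffuse_reflectance(0, 1.3, 0), 1)
  expect_equal(diffuse_reflectance(0, 0.4, 0), 1)
  # scalar longhand evaluation (sound-apple coefficients)
  expect_equal(diffuse_reflectance(0.0324, 1.726, 0.2),
               oracle_rd(0.0324, 1.726, 0.2), tolerance = 1e-12)
  expect_error(diffuse_reflectance(0.1, 0, 0.2), "degenerate")
})

test_that("reflectance is monotone and bounded over the phantom design sweep", {
  mu_a <- seq(0, 0.5, length.out = 20)
  mu_s <- seq(0.2, 4, length.out = 20)
  for (fx in c(0, 0.2)) {
    rd <- outer(mu_a, mu_s, function(a, s) diffuse_reflectance(a, s, fx))
    expect_true(all(rd > 0 & rd <= 1))
  }
  # monotonicity holds where the diffusion approximation is valid
  # (scattering-dominated media); outside it the model is not monotone
  mu_a_pos <- seq(0.002, 0.5, length.out = 20)
  mu_s_dif <- seq(0.8, 4, length.out = 20)
  for (fx in c(0, 0.2)) {
    rd <- outer(mu_a_pos, mu_s_dif,
                function(a, s) diffuse_reflectance(a, s, fx))
    # strictly decreasing in absorption (rows), increasing in scattering
    expect_true(all(diff(rd) < 0))
    if (fx == 0) expect_true(all(t(diff(t(rd))) > 0))
  }
  # strictly decreasing in spatial frequency
  rd_low <- diffuse_reflectance(0.05, 1.5, 0.1)
  rd_high <- diffuse_reflectance(0.05, 1.5, 0.3)
  expect_lt(rd_high, rd_low)
})

test_that("the two effective-attenuation dialects agree only at DC", {
  expect_identical(diffuse_reflectance(0.05, 1.5, 0, mueff_dialect = "squared"),
                   diffuse_reflectance(0.05, 1.5, 0, mueff_dialect = "printed"))
  expect_false(isTRUE(all.equal(
    diffuse_reflectance(0.05, 1.5, 0.2, mueff_dialect = "squared"),
    diffuse_reflectance(0.05, 1.5, 0.2, mueff_dialect = "printed"))))
})
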