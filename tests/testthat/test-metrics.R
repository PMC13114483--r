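test_that("NMAE matches hand arithmetic and is scale invariant", {
  expect_equal(nmae(matrix(1, 2, 2), matrix(1, 2, 2)), 0)
  expect_equal(nmae(matrix(c(1, 3), 1), matrix(c(2, 2), 1)), 0.5)
  set.seed(41)
  p <- matrix(runif(16), 4); r <- matrix(runif(16) + 0.5, 4)
  expect_equal(nmae(3 * p, 3 * r), nmae(p, r))
  expect_error(nmae(p, r * 0), "zero")
})

test_that("PSNR reproduces the uniform-offset closed form", {
  r <- matrix(runif(100) * 200, 10)
  expect_equal(psnr(r + 1, r), 10 * log10(255^2), tolerance = 1e-12)
  expect_equal(psnr(r, r), Inf)
  expect_equal(psnr(matrix(255, 3, 3), matrix(0, 3, 3)), 0)
})

test_that("SSIM is 1 on identity, symmetric, negative when anti-correlated", {
  r <- matrix(runif(100) * 255, 10)
  expect_equal(ssim(r, r), 1)
  p <- r + matrix(rnorm(100, sd = 10), 10)
  expect_equal(ssim(p, r), ssim(r, p))
  expect_lt(ssim(255 - r, r), 0)
  # direct-formula cross-check of the anti-correlated case
  mp <- mean(255 - r); mr <- mean(r)
  vp <- mean((255 - r - mp)^2); vr <- mean((r - mr)^2)
  cv <- mean((255 - r - mp) * (r - mr))
  c1 <- (0.01 * 255)^2; c2 <- (0.03 * 255)^2
  expect_equal(ssim(255 - r, r),
               ((2 * mp * mr + c1) * (2 * cv + c2)) /
                 ((mp^2 + mr^2 + c1) * (vp + vr + c2)))
})

test_that("paired t-test agrees with the closed-form statistic", {
  a <- c(1, 2, 3); b <- c(1.5, 2.1, 3.4)
  res <- paired_ttest(a, b)
  d <- a - b
  t_oracle <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  p_oracle <- 2 * stats::pt(-abs(t_oracle), df = 2)
  expect_equal(res$t, t_oracle)
  expect_equal(res$p, p_oracle)
  # antisymmetry
  swapped <- paired_ttest(b, a)
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p, res$p)
  # degenerate identical inputs
  same <- paired_ttest(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)
})

test_that("metric reports aggregate per coefficient channel", {
  maps <- lapply(1:3, function(i) {
    optical_property_map(matrix(0.05 + 0.01 * i, 8, 8),
                         matrix(1.5 + 0.1 * i, 8, 8), 1)
  })
  noisy <- lapply(maps, function(m) {
    optical_property_map(m$mu_a + 0.001, m$mu_s_prime + 0.01, 1)
  })
  rep_ <- metric_report(noisy, maps)
  expect_equal(nrow(rep_), 6)
  expect_true(all(rep_$nmae >= 0))
  expect_true(all(rep_$ssim <= 1))
  agg <- summarize_metrics(rep_)
  expect_equal(nrow(agg), 2)
})
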