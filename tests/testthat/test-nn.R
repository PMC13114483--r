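# numeric gradient of a scalar-valued function of an array
numeric_grad <- function(f, x, h = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

test_that("layer backward passes match numeric gradients", {
  set.seed(71)
  x <- array(rnorm(5 * 5 * 3 * 2), c(5, 5, 3, 2))
  layers <- list(
    conv = sfdibruise:::nn_conv(3, 3, 4),
    res = sfdibruise:::nn_resblock(3),
    ca = sfdibruise:::nn_channel_attention(3, 2),
    sa = sfdibruise:::nn_spatial_attention(3),
    cbam = sfdibruise:::nn_cbam(3, 2, 3))
  for (nm in names(layers)) {
    l <- layers[[nm]]
    out <- l$forward(x)
    proj <- array(rnorm(length(out)), dim(out))
    l$forward(x)
    dx <- l$backward(proj)
    gnum <- numeric_grad(function(z) sum(l$forward(z) * proj), x)
    expect_lt(max(abs(dx - gnum)), 1e-6, label = paste(nm, "input gradient"))
  }
})

test_that("attention gates stay in (0,1) and preserve shapes", {
  set.seed(72)
  x <- array(rnorm(8 * 8 * 6 * 2), c(8, 8, 6, 2))
  ca <- sfdibruise:::nn_channel_attention(6, 16)   # ratio clipped to channels
  out <- ca$forward(x)
  expect_equal(dim(out), dim(x))
  expect_true(all(ca$wc > 0 & ca$wc < 1))
  # constant features make the avg and max pooled summaries coincide
  xc <- array(2, c(4, 4, 3, 1))
  ca2 <- sfdibruise:::nn_channel_attention(3, 2)
  ca2$forward(xc)
  expect_equal(ca2$avg, ca2$mx)

  sa <- sfdibruise:::nn_spatial_attention(5)
  out2 <- sa$forward(x)
  expect_equal(dim(out2), dim(x))
  expect_true(all(sa$ws > 0 & sa$ws < 1))
  # channel permutation leaves the (mean, max) statistics invariant
  xp <- x[, , sample(6), , drop = FALSE]
  sa$forward(x); w1 <- sa$ws
  sa$forward(xp); w2 <- sa$ws
  expect_equal(w1, w2)
})

test_that("generator and discriminator have the stated shapes and wiring", {
  set.seed(73)
  cfg <- generator_config(depth = 3, base_channels = 4, cbam_reduction = 2,
                          cbam_spatial_kernel = 3)
  g <- build_generator(cfg)
  x <- array(rnorm(16 * 16), c(16, 16, 1, 1))
  y <- g$forward(x)
  expect_equal(dim(y), c(16, 16, 3, 1))
  expect_true(all(is.finite(y)))
  expect_true(all(y > 0 & y < 1))
  # one attention block after each encoder stage and before each decoder
  n_cbam <- length(g$enc) + length(g$dec)
  expect_equal(n_cbam, 2 * cfg$depth)
  # inference is deterministic with fixed weights
  expect_identical(g$forward(x), g$forward(x))

  d <- build_discriminator(discriminator_config(8))
  s <- d$forward(x, y)
  expect_true(all(s > 0 & s < 1))
  expect_equal(dim(s)[3], 1)
  expect_equal(length(d$layers), 3)   # exactly three conv layers
})

test_that("loss functions satisfy their closed forms", {
  half <- array(0.5, c(2, 2, 1, 2))
  expect_equal(gan_loss(half, half), -2 * log(2))
  # well-separated discriminator drives the loss to 0
  expect_gt(gan_loss(array(1, dim(half)), array(0, dim(half))), -1e-5)
  y <- array(runif(24), c(2, 2, 3, 2))
  expect_equal(l1_loss(y, y), 0)
  expect_equal(total_loss(1, 0.5, 60), 31)
  expect_equal(total_loss(0, 0.5, 120) - total_loss(0, 0.5, 60), 30)
  # batch-order permutation invariance
  d1 <- array(runif(8), c(2, 2, 1, 2))
  d2 <- d1[, , , 2:1, drop = FALSE]
  expect_equal(gan_loss(d1, d1), gan_loss(d2, d2))
})

test_that("paired composites assemble and split losslessly", {
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  y <- array(runif(8 * 8 * 3), c(8, 8, 3))
  comp <- assemble_pair(x, y)
  expect_equal(dim(comp), c(8, 16, 3))
  sp <- split_pair(comp)
  expect_identical(sp$x, x)
  expect_identical(sp$y, y)
  # widths add and the left half is the input
  expect_identical(comp[, 1:8, ], x)
  expect_error(assemble_pair(array(0, c(4, 8, 3)), y), "incompatible")
})
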