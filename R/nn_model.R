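#' Generator configuration
#'
#' @param depth Number of down/up-sampling stages (>= 2); the input side
#'   length must be divisible by `2^depth`.
#' @param base_channels Channels after the stem convolution; doubled per
#'   stage up to `max_channels`.
#' @param max_channels Channel cap.
#' @param res_blocks Residual blocks per stage.
#' @param cbam_reduction Channel-attention reduction ratio.
#' @param cbam_spatial_kernel Spatial-attention kernel size.
#' @return Configuration list.
#' @export
generator_config <- function(depth = 6, base_channels = 32,
                             max_channels = 256, res_blocks = 1,
                             cbam_reduction = 16, cbam_spatial_kernel = 7) {
  stopifnot(depth >= 2, base_channels >= 1, res_blocks >= 1)
  list(depth = depth, base_channels = base_channels,
       max_channels = max_channels, res_blocks = res_blocks,
       cbam_reduction = cbam_reduction,
       cbam_spatial_kernel = cbam_spatial_kernel)
}

#' Discriminator configuration
#'
#' The discriminator is a conditional three-convolution fully convolutional
#' classifier scoring (input, candidate-label) pairs patchwise.
#'
#' @param channels Channels of the first conv layer (doubled in the
#'   second; the third maps to one score channel).
#' @return Configuration list.
#' @export
discriminator_config <- function(channels = 32) {
  list(channels = channels, n_conv_layers = 3L)
}

#' Build the attention-gated adversarial U-Net generator
#'
#' Encoder-decoder U-Net with skip connections and residual blocks; a
#' channel+spatial attention block sits after each down-sampling stage and
#' before each up-sampling stage (2 x depth attention blocks in total).
#' Maps an H x W x 1 reflectance image to an H x W x 3 coefficient label in
#' `[0, 1]` through a sigmoid output head. Inputs are expected normalized
#' to `[-1, 1]`.
#'
#' @param cfg A [generator_config()].
#' @return Generator object (environment) with `forward`, `backward` and
#'   the layer tree; use with [train_gan()] / [predict_optical()].
#' @export
build_generator <- function(cfg = generator_config()) {
  d <- cfg$depth
  ch <- pmin(cfg$base_channels * 2^(0:d), cfg$max_channels)
  g <- new.env(parent = emptyenv())
  g$cfg <- cfg
  g$stem <- nn_conv(3, 1, ch[1])
  g$stem_act <- nn_lrelu()
  g$enc <- lapply(seq_len(d), function(i) {
    list(pool = nn_avgpool2(),
         conv = nn_conv(3, ch[i], ch[i + 1]),
         act = nn_lrelu(),
         res = lapply(seq_len(cfg$res_blocks),
                      function(j) nn_resblock(ch[i + 1])),
         cbam = nn_cbam(ch[i + 1], cfg$cbam_reduction,
                        cfg$cbam_spatial_kernel))
  })
  g$dec <- lapply(seq_len(d), function(i) {      # i = 1 is the deepest stage
    lev <- d - i + 1
    list(cbam = nn_cbam(ch[lev + 1], cfg$cbam_reduction,
                        cfg$cbam_spatial_kernel),
         up = nn_upsample2(),
         conv = nn_conv(3, ch[lev + 1] + ch[lev], ch[lev]),
         act = nn_relu(),
         res = lapply(seq_len(cfg$res_blocks),
                      function(j) nn_resblock(ch[lev])))
  })
  g$head <- nn_conv(3, ch[1], 3)
  g$head_act <- nn_sigmoid()
  g$layers <- c(list(g$stem), unlist(g$enc, recursive = FALSE),
                unlist(g$dec, recursive = FALSE), list(g$head))
  g$layers <- .flatten_layer_list(g$layers)

  g$forward <- function(x) {
    skips <- vector("list", d + 1)
    h <- g$stem_act$forward(g$stem$forward(x))
    skips[[1]] <- h
    for (i in seq_len(d)) {
      st <- g$enc[[i]]
      h <- st$act$forward(st$conv$forward(st$pool$forward(h)))
      for (rb in st$res) h <- rb$forward(h)
      h <- st$cbam$forward(h)
      if (i < d) skips[[i + 1]] <- h
    }
    for (i in seq_len(d)) {
      st <- g$dec[[i]]
      h <- st$up$forward(st$cbam$forward(h))
      skip <- skips[[d - i + 1]]
      h <- .concat_ch(h, skip)
      g$dec_split[[i]] <- c(dim(h)[3] - dim(skip)[3], dim(skip)[3])
      h <- st$act$forward(st$conv$forward(h))
      for (rb in st$res) h <- rb$forward(h)
    }
    g$head_act$forward(g$head$forward(h))
  }
  g$dec_split <- vector("list", d)
  g$backward <- function(dout) {
    dh <- g$head$backward(g$head_act$backward(dout))
    dskips <- vector("list", d + 1)
    for (i in rev(seq_len(d))) {
      st <- g$dec[[i]]
      for (rb in rev(st$res)) dh <- rb$backward(dh)
      dh <- st$conv$backward(st$act$backward(dh))
      sp <- g$dec_split[[i]]
      dskips[[d - i + 1]] <- dh[, , sp[1] + seq_len(sp[2]), , drop = FALSE]
      dh <- dh[, , seq_len(sp[1]), , drop = FALSE]
      dh <- st$cbam$backward(st$up$backward(dh))
    }
    for (i in rev(seq_len(d))) {
      st <- g$enc[[i]]
      if (i < d) dh <- dh + dskips[[i + 1]]
      dh <- st$cbam$backward(dh)
      for (rb in rev(st$res)) dh <- rb$backward(dh)
      dh <- st$pool$backward(st$conv$backward(st$act$backward(dh)))
    }
    dh <- dh + dskips[[1]]
    g$stem$backward(g$stem_act$backward(dh))
  }
  g
}

.concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

.flatten_layer_list <- function(lst) {
  out <- list()
  walk <- function(x) {
    if (is.environment(x)) out[[length(out) + 1]] <<- x
    else if (is.list(x)) for (el in x) walk(el)
  }
  walk(lst)
  out
}

#' Build the conditional patch discriminator
#'
#' Exactly three convolutional layers over the channelwise concatenation of
#' the reflectance input and a candidate label, with stride-2 average
#' pooling between them; outputs a patch grid of scores in `(0, 1)`.
#'
#' @param cfg A [discriminator_config()].
#' @return Discriminator object (environment).
#' @export
build_discriminator <- function(cfg = discriminator_config()) {
  cc <- cfg$channels
  dd <- new.env(parent = emptyenv())
  dd$cfg <- cfg
  dd$conv1 <- nn_conv(3, 4, cc);     dd$act1 <- nn_lrelu()
  dd$pool1 <- nn_avgpool2()
  dd$conv2 <- nn_conv(3, cc, 2 * cc); dd$act2 <- nn_lrelu()
  dd$pool2 <- nn_avgpool2()
  dd$conv3 <- nn_conv(3, 2 * cc, 1)
  dd$out_act <- nn_sigmoid()
  dd$layers <- list(dd$conv1, dd$conv2, dd$conv3)
  dd$forward <- function(x, y) {
    h <- .concat_ch(x, y)
    h <- dd$pool1$forward(dd$act1$forward(dd$conv1$forward(h)))
    h <- dd$pool2$forward(dd$act2$forward(dd$conv2$forward(h)))
    dd$out_act$forward(dd$conv3$forward(h))
  }
  dd$backward <- function(dout) {
    dh <- dd$conv3$backward(dd$out_act$backward(dout))
    dh <- dd$conv2$backward(dd$act2$backward(dd$pool2$backward(dh)))
    dh <- dd$conv1$backward(dd$act1$backward(dd$pool1$backward(dh)))
    list(dx = dh[, , 1, , drop = FALSE], dy = dh[, , 2:4, , drop = FALSE])
  }
  dd
}

#' Adversarial loss of a discriminator against real and generated pairs
#'
#' `L_GAN = E[log D(x, y)] + E[log(1 - D(x, G(x)))]` with natural
#' logarithms and expectations taken over the batch and the patch grid.
#' Discriminator outputs are clamped to `[eps, 1 - eps]`.
#'
#' @param d_real Discriminator scores on real pairs (any array).
#' @param d_fake Discriminator scores on generated pairs.
#' @param eps Clamp width.
#' @return Scalar loss value.
#' @export
gan_loss <- function(d_real, d_fake, eps = 1e-7) {
  d_real <- pmin(pmax(d_real, eps), 1 - eps)
  d_fake <- pmin(pmax(d_fake, eps), 1 - eps)
  mean(log(d_real)) + mean(log(1 - d_fake))
}

#' Pixelwise L1 loss
#'
#' Mean absolute deviation between a label and a generated image.
#'
#' @param y,y_hat Equal-shape arrays.
#' @return Scalar loss.
#' @export
l1_loss <- function(y, y_hat) {
  if (!all(dim(y) == dim(y_hat))) stop("shapes differ")
  mean(abs(y - y_hat))
}

#' Composite adversarial + weighted L1 objective
#'
#' `L_total = L_GAN + lambda * L1`.
#'
#' @param gan Adversarial loss value.
#' @param l1 L1 loss value.
#' @param lambda_l1 Regularization weight (default 60).
#' @return Scalar loss.
#' @export
total_loss <- function(gan, l1, lambda_l1 = 60) gan + lambda_l1 * l1

#' Assemble / split a paired training composite
#'
#' Pairs are stored as a single image with the reflectance input and the
#' RGB label concatenated along the width: a H x W input and H x W label
#' form a H x 2W composite whose left half is the input.
#'
#' @param x Input image (H x W matrix or H x W x C array).
#' @param y Label (H x W x C array with the same H).
#' @return `assemble_pair()`: H x 2W x C array (a single-channel `x` is
#'   broadcast to the label's channel count for storage);
#'   `split_pair()`: list `(x, y)`.
#' @export
assemble_pair <- function(x, y) {
  if (length(dim(x)) == 2) {
    x <- array(rep(x, dim(y)[3]), c(dim(x), dim(y)[3]))
  }
  if (dim(x)[1] != dim(y)[1] || !identical(dim(x)[3], dim(y)[3])) {
    stop("input and label sizes are incompatible")
  }
  out <- array(0, c(dim(x)[1], dim(x)[2] + dim(y)[2], dim(y)[3]))
  out[, seq_len(dim(x)[2]), ] <- x
  out[, dim(x)[2] + seq_len(dim(y)[2]), ] <- y
  out
}

#' @rdname assemble_pair
#' @param composite H x 2W x C array from `assemble_pair()`.
#' @export
split_pair <- function(composite) {
  w <- dim(composite)[2]
  if (w %% 2 != 0) stop("composite width must be even")
  list(x = composite[, seq_len(w / 2), , drop = FALSE],
       y = composite[, w / 2 + seq_len(w / 2), , drop = FALSE])
}

# stack a list of H x W x C arrays into a [H, W, C, N] batch
.stack_batch <- function(lst) {
  d <- dim(lst[[1]])
  out <- array(0, c(d, length(lst)))
  for (i in seq_along(lst)) out[, , , i] <- lst[[i]]
  out
}

#' Train the adversarial translator on a paired dataset
#'
#' Alternating discriminator / generator updates with Adam
#' (lr 2e-4, beta = (0.5, 0.999)). The discriminator maximizes
#' `log D(x,y) + log(1 - D(x,G(x)))`; the generator minimizes the
#' non-saturating adversarial term `-log D(x, G(x))` plus
#' `lambda * L1(y, G(x))`. Per-epoch training and validation losses (both
#' L1 and MSE) are logged and the parameter snapshot with the best
#' validation L1 is kept.
#'
#' @param data List with `train` and `validation`, each a list of samples;
#'   a sample is a list with `x` (H x W matrix, reflectance in `[0, 1]`)
#'   and `y` (H x W x 3 array, label in `[0, 1]`).
#' @param generator,discriminator Prebuilt networks (built fresh from the
#'   configs when `NULL`).
#' @param epochs,batch_size Training schedule.
#' @param lambda_l1 L1 weight of the composite loss.
#' @param lr,beta1,beta2 Adam hyperparameters.
#' @param seed Seed fixing initialization and batch order.
#' @param gen_cfg,disc_cfg Configurations used when networks are not
#'   supplied.
#' @param verbose Print per-epoch losses.
#' @return List of class `sfdi_gan` with the generator (best-validation
#'   weights restored), discriminator, and `history` data frame.
#' @export
train_gan <- function(data, generator = NULL, discriminator = NULL,
                      epochs = 20, batch_size = 4, lambda_l1 = 60,
                      lr = 2e-4, beta1 = 0.5, beta2 = 0.999, seed = 1L,
                      gen_cfg = generator_config(),
                      disc_cfg = discriminator_config(),
                      verbose = FALSE) {
  if (!length(data$train) || !length(data$validation)) {
    stop("both train and validation splits must be non-empty")
  }
  set.seed(seed)
  if (is.null(generator)) generator <- build_generator(gen_cfg)
  if (is.null(discriminator)) discriminator <- build_discriminator(disc_cfg)
  g_opt <- nn_adam(generator$layers, lr, beta1, beta2)
  d_opt <- nn_adam(discriminator$layers, lr, beta1, beta2)
  eps <- 1e-7

  prep_x <- function(s) array(2 * s$x - 1, c(dim(s$x)[1], dim(s$x)[2], 1))
  val_x <- .stack_batch(lapply(data$validation, prep_x))
  val_y <- .stack_batch(lapply(data$validation, function(s) s$y))

  n_train <- length(data$train)
  history <- data.frame(epoch = integer(), train_l1 = numeric(),
                        train_mse = numeric(), val_l1 = numeric(),
                        val_mse = numeric(), d_loss = numeric(),
                        g_adv = numeric())
  best_val <- Inf
  best_params <- NULL

  for (ep in seq_len(epochs)) {
    ord <- sample.int(n_train)
    ep_l1 <- ep_mse <- ep_d <- ep_adv <- 0
    nb <- 0
    for (s0 in seq(1, n_train, by = batch_size)) {
      idx <- ord[s0:min(s0 + batch_size - 1, n_train)]
      xb <- .stack_batch(lapply(data$train[idx], prep_x))
      yb <- .stack_batch(lapply(data$train[idx], function(s) s$y))

      # --- discriminator update (generator output detached) ---
      y_fake <- generator$forward(xb)
      d_real <- discriminator$forward(xb, yb)
      dr <- pmin(pmax(d_real, eps), 1 - eps)
      # maximize log D(real): d(-loss)/dD = -1/D
      grad_real <- -1 / dr / length(dr)
      discriminator$backward(grad_real)
      gr_real <- lapply(.collect_layers(discriminator$layers),
                        function(l) l$grads)
      d_fake <- discriminator$forward(xb, y_fake)
      df <- pmin(pmax(d_fake, eps), 1 - eps)
      grad_fake <- 1 / (1 - df) / length(df)
      discriminator$backward(grad_fake)
      leaves_d <- .collect_layers(discriminator$layers)
      for (i in seq_along(leaves_d)) {
        for (nm in names(leaves_d[[i]]$grads)) {
          leaves_d[[i]]$grads[[nm]] <-
            leaves_d[[i]]$grads[[nm]] + gr_real[[i]][[nm]]
        }
      }
      d_opt$step()
      ep_d <- ep_d - gan_loss(d_real, d_fake)

      # --- generator update ---
      y_fake <- generator$forward(xb)
      d_fake <- discriminator$forward(xb, y_fake)
      df <- pmin(pmax(d_fake, eps), 1 - eps)
      adv <- -mean(log(df))                      # non-saturating form
      grad_d_out <- -1 / df / length(df)
      dpair <- discriminator$backward(grad_d_out)
      resid <- y_fake - yb
      dl1 <- lambda_l1 * sign(resid) / length(resid)
      generator$backward(dpair$dy + dl1)
      g_opt$step()

      ep_l1 <- ep_l1 + l1_loss(yb, y_fake)
      ep_mse <- ep_mse + mean((yb - y_fake)^2)
      ep_adv <- ep_adv + adv
      nb <- nb + 1
    }
    val_pred <- generator$forward(val_x)
    val_l1 <- l1_loss(val_y, val_pred)
    val_mse <- mean((val_y - val_pred)^2)
    history <- rbind(history, data.frame(
      epoch = ep, train_l1 = ep_l1 / nb, train_mse = ep_mse / nb,
      val_l1 = val_l1, val_mse = val_mse, d_loss = ep_d / nb,
      g_adv = ep_adv / nb))
    if (val_l1 < best_val) {
      best_val <- val_l1
      best_params <- nn_get_params(generator$layers)
    }
    if (verbose) {
      message(sprintf("epoch %3d  train L1 %.4f  val L1 %.4f",
                      ep, ep_l1 / nb, val_l1))
    }
  }
  if (!is.null(best_params)) nn_set_params(generator$layers, best_params)
  structure(list(generator = generator, discriminator = discriminator,
                 history = history, lambda_l1 = lambda_l1, seed = seed),
            class = "sfdi_gan")
}

#' Predict optical coefficients from a reflectance image
#'
#' Runs the generator on a (profile-corrected) diffuse reflectance image
#' and decodes the label-space output back to physical coefficient maps.
#'
#' @param model An `sfdi_gan` from [train_gan()], or a bare generator.
#' @param rd Reflectance image (H x W matrix in `[0, 1]`).
#' @param norm_ranges Label normalization ranges.
#' @param pixel_size_mm Pixel pitch recorded on the result.
#' @return An `optical_property_map`.
#' @export
predict_optical <- function(model, rd,
                            norm_ranges = list(mu_a = c(0, 0.5),
                                               mu_s_prime = c(0, 4)),
                            pixel_size_mm = 100 / 256) {
  gen <- if (inherits(model, "sfdi_gan")) model$generator else model
  x <- array(2 * rd - 1, c(dim(rd)[1], dim(rd)[2], 1, 1))
  y <- gen$forward(x)[, , , 1, drop = TRUE]     # H x W x 3 in [0, 1]
  decode_rgb_label(y, norm_ranges, pixel_size_mm)
}

#' Load a paired dataset from a manifest for training
#'
#' @param dir Dataset directory written by [build_dataset()].
#' @return List with `train` and `validation` sample lists as expected by
#'   [train_gan()].
#' @export
load_paired_dataset <- function(dir) {
  manifest <- read_manifest(dir)
  load_one <- function(entry) {
    x <- read_image(file.path(dir, entry$input))
    lab <- read_image(file.path(dir, entry$label), as_label = FALSE)
    list(x = x, y = lab)
  }
  splits <- vapply(manifest$entries, function(e) e$split, character(1))
  list(train = lapply(manifest$entries[splits == "train"], load_one),
       validation = lapply(manifest$entries[splits == "validation"],
                           load_one))
}
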