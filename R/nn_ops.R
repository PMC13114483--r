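# Low-level neural-network layers.
#
# Tensors are dense 4-D arrays [H, W, C, N] (rows, cols, channels, batch).
# Every layer is an environment exposing forward(x) / backward(dout), with
# learnable parameters in $params and matching gradients in $grads; the
# forward pass caches whatever the analytic backward pass needs.
# Convolutions are im2col + a single BLAS matrix product.

.tensor_dims <- function(x) {
  d <- dim(x)
  if (length(d) != 4) stop("expected a [H, W, C, N] tensor")
  d
}

# im2col for a k x k same-padding, stride-1 convolution.
# Returns a (H*W*N) x (k*k*C) matrix; row order is (h, w, n), column
# blocks ordered (dy, dx) with channel fastest inside each block.
.im2col <- function(x, k) {
  d <- .tensor_dims(x)
  h <- d[1]; w <- d[2]; cc <- d[3]; n <- d[4]
  p <- (k - 1) %/% 2
  xp <- array(0, c(h + 2 * p, w + 2 * p, cc, n))
  xp[p + seq_len(h), p + seq_len(w), , ] <- x
  out <- matrix(0, h * w * n, k * k * cc)
  j <- 0L
  for (dy in seq_len(k)) {
    for (dx in seq_len(k)) {
      slice <- xp[dy + seq_len(h) - 1L, dx + seq_len(w) - 1L, , , drop = FALSE]
      slice <- aperm(slice, c(1, 2, 4, 3))      # [H, W, N, C]
      dim(slice) <- c(h * w * n, cc)
      out[, j + seq_len(cc)] <- slice
      j <- j + cc
    }
  }
  out
}

# adjoint of .im2col: scatter-add column gradients back onto the input
.col2im <- function(cols, dims, k) {
  h <- dims[1]; w <- dims[2]; cc <- dims[3]; n <- dims[4]
  p <- (k - 1) %/% 2
  gp <- array(0, c(h + 2 * p, w + 2 * p, cc, n))
  j <- 0L
  for (dy in seq_len(k)) {
    for (dx in seq_len(k)) {
      blk <- cols[, j + seq_len(cc), drop = FALSE]
      dim(blk) <- c(h, w, n, cc)
      blk <- aperm(blk, c(1, 2, 4, 3))          # back to [H, W, C, N]
      gp[dy + seq_len(h) - 1L, dx + seq_len(w) - 1L, , ] <-
        gp[dy + seq_len(h) - 1L, dx + seq_len(w) - 1L, , ,
           drop = FALSE] + blk
      j <- j + cc
    }
  }
  gp[p + seq_len(h), p + seq_len(w), , , drop = FALSE]
}

# weight array [k, k, cin, cout] -> (k*k*cin) x cout matrix matching .im2col
.wmat <- function(w) {
  d <- dim(w)
  m <- aperm(w, c(3, 2, 1, 4))                  # cin fastest, then dx, dy
  dim(m) <- c(d[1] * d[2] * d[3], d[4])
  m
}

.wmat_inv <- function(m, k, cin, cout) {
  dim(m) <- c(cin, k, k, cout)
  aperm(m, c(3, 2, 1, 4))
}

nn_conv <- function(k, cin, cout, init_gain = 1) {
  e <- new.env(parent = emptyenv())
  sd <- init_gain * sqrt(2 / (k * k * cin))     # He initialization
  e$params <- list(w = array(stats::rnorm(k * k * cin * cout, sd = sd),
                             c(k, k, cin, cout)),
                   b = numeric(cout))
  e$grads <- list(w = NULL, b = NULL)
  e$forward <- function(x) {
    d <- .tensor_dims(x)
    e$in_dims <- d
    e$xcol <- .im2col(x, k)
    out <- e$xcol %*% .wmat(e$params$w)
    out <- sweep(out, 2, e$params$b, "+")
    dim(out) <- c(d[1], d[2], d[4], cout)
    aperm(out, c(1, 2, 4, 3))
  }
  e$backward <- function(dout) {
    d <- e$in_dims
    dy <- aperm(dout, c(1, 2, 4, 3))
    dim(dy) <- c(d[1] * d[2] * d[4], cout)
    e$grads$w <- .wmat_inv(crossprod(e$xcol, dy), k, cin, cout)
    e$grads$b <- colSums(dy)
    dxcol <- tcrossprod(dy, .wmat(e$params$w))
    .col2im(dxcol, d, k)
  }
  e
}

nn_dense <- function(cin, cout, init_gain = 1) {
  e <- new.env(parent = emptyenv())
  e$params <- list(w = matrix(stats::rnorm(cin * cout,
                                           sd = init_gain * sqrt(2 / cin)),
                              cin, cout),
                   b = numeric(cout))
  e$grads <- list(w = NULL, b = NULL)
  e$forward <- function(x) {                    # x: [cin, n]
    e$x <- x
    sweep(crossprod(e$params$w, x), 1, e$params$b, "+")
  }
  e$backward <- function(dout) {                # dout: [cout, n]
    e$grads$w <- tcrossprod(e$x, dout)
    e$grads$b <- rowSums(dout)
    e$params$w %*% dout
  }
  e
}

nn_relu <- function() {
  e <- new.env(parent = emptyenv())
  e$params <- list(); e$grads <- list()
  e$forward <- function(x) { e$mask <- x > 0; x * e$mask }
  e$backward <- function(dout) dout * e$mask
  e
}

nn_lrelu <- function(alpha = 0.2) {
  e <- new.env(parent = emptyenv())
  e$params <- list(); e$grads <- list()
  e$forward <- function(x) { e$mask <- x > 0; ifelse(e$mask, x, alpha * x) }
  e$backward <- function(dout) ifelse(e$mask, dout, alpha * dout)
  e
}

nn_sigmoid <- function() {
  e <- new.env(parent = emptyenv())
  e$params <- list(); e$grads <- list()
  e$forward <- function(x) { e$y <- 1 / (1 + exp(-x)); e$y }
  e$backward <- function(dout) dout * e$y * (1 - e$y)
  e
}

nn_avgpool2 <- function() {
  e <- new.env(parent = emptyenv())
  e$params <- list(); e$grads <- list()
  e$forward <- function(x) {
    d <- .tensor_dims(x)
    e$in_dims <- d
    (x[seq(1, d[1], 2), seq(1, d[2], 2), , , drop = FALSE] +
       x[seq(2, d[1], 2), seq(1, d[2], 2), , , drop = FALSE] +
       x[seq(1, d[1], 2), seq(2, d[2], 2), , , drop = FALSE] +
       x[seq(2, d[1], 2), seq(2, d[2], 2), , , drop = FALSE]) / 4
  }
  e$backward <- function(dout) {
    d <- e$in_dims
    dx <- array(0, d)
    g <- dout / 4
    dx[seq(1, d[1], 2), seq(1, d[2], 2), , ] <- g
    dx[seq(2, d[1], 2), seq(1, d[2], 2), , ] <- g
    dx[seq(1, d[1], 2), seq(2, d[2], 2), , ] <- g
    dx[seq(2, d[1], 2), seq(2, d[2], 2), , ] <- g
    dx
  }
  e
}

nn_upsample2 <- function() {
  e <- new.env(parent = emptyenv())
  e$params <- list(); e$grads <- list()
  e$forward <- function(x) {
    d <- .tensor_dims(x)
    e$in_dims <- d
    out <- array(0, c(2 * d[1], 2 * d[2], d[3], d[4]))
    out[seq(1, 2 * d[1], 2), seq(1, 2 * d[2], 2), , ] <- x
    out[seq(2, 2 * d[1], 2), seq(1, 2 * d[2], 2), , ] <- x
    out[seq(1, 2 * d[1], 2), seq(2, 2 * d[2], 2), , ] <- x
    out[seq(2, 2 * d[1], 2), seq(2, 2 * d[2], 2), , ] <- x
    out
  }
  e$backward <- function(dout) {
    d <- e$in_dims
    dout[seq(1, 2 * d[1], 2), seq(1, 2 * d[2], 2), , , drop = FALSE] +
      dout[seq(2, 2 * d[1], 2), seq(1, 2 * d[2], 2), , , drop = FALSE] +
      dout[seq(1, 2 * d[1], 2), seq(2, 2 * d[2], 2), , , drop = FALSE] +
      dout[seq(2, 2 * d[1], 2), seq(2, 2 * d[2], 2), , , drop = FALSE]
  }
  e
}

# residual block: conv-relu-conv plus identity shortcut
nn_resblock <- function(cc, k = 3) {
  e <- new.env(parent = emptyenv())
  e$conv1 <- nn_conv(k, cc, cc)
  e$conv2 <- nn_conv(k, cc, cc, init_gain = 0.1)
  e$act <- nn_relu()
  e$params <- list(); e$grads <- list()
  e$children <- list(e$conv1, e$conv2)
  e$forward <- function(x) {
    x + e$conv2$forward(e$act$forward(e$conv1$forward(x)))
  }
  e$backward <- function(dout) {
    dout + e$conv1$backward(e$act$backward(e$conv2$backward(dout)))
  }
  e
}

#' Channel-attention weights of a feature tensor
#'
#' Global average pooling and global max pooling summarize each feature
#' channel; a shared two-layer bottleneck MLP (reduction ratio `r`) maps
#' both summaries to channel logits, whose sigmoid-ed sum gates the
#' channels. Implemented as an internal layer of the attention block; see
#' [build_generator()].
#'
#' @name channel_attention
#' @keywords internal
NULL

nn_channel_attention <- function(cc, reduction = 16) {
  e <- new.env(parent = emptyenv())
  r <- max(1L, min(reduction, cc))              # clip ratio to channel count
  e$fc1 <- nn_dense(cc, max(1L, cc %/% r))
  e$fc2 <- nn_dense(max(1L, cc %/% r), cc)
  e$children <- list(e$fc1, e$fc2)
  e$params <- list(); e$grads <- list()
  e$forward <- function(x) {
    d <- .tensor_dims(x)
    e$in_dims <- d
    e$x <- x
    flat <- x
    dim(flat) <- c(d[1] * d[2], d[3] * d[4])
    avg <- matrix(colMeans(flat), d[3], d[4])
    mx_idx <- max.col(t(flat), ties.method = "first")
    mx <- matrix(flat[cbind(mx_idx, seq_len(d[3] * d[4]))], d[3], d[4])
    e$mx_idx <- mx_idx
    # shared MLP on both pooled summaries (two passes; caches kept apart)
    relu_ <- function(z) pmax(z, 0)
    e$h_avg <- sweep(crossprod(e$fc1$params$w, avg), 1, e$fc1$params$b, "+")
    e$h_mx <- sweep(crossprod(e$fc1$params$w, mx), 1, e$fc1$params$b, "+")
    e$avg <- avg; e$mx <- mx
    z <- sweep(crossprod(e$fc2$params$w, relu_(e$h_avg)), 1,
               e$fc2$params$b, "+") +
      sweep(crossprod(e$fc2$params$w, relu_(e$h_mx)), 1, e$fc2$params$b, "+")
    e$wc <- 1 / (1 + exp(-z))                   # [C, N]
    gate <- array(rep(e$wc, each = d[1] * d[2]), d)
    x * gate
  }
  e$backward <- function(dout) {
    d <- e$in_dims
    gate <- array(rep(e$wc, each = d[1] * d[2]), d)
    dx <- dout * gate
    # gradient reaching the channel weights
    prod_flat <- dout * e$x
    dim(prod_flat) <- c(d[1] * d[2], d[3] * d[4])
    dwc <- matrix(colSums(prod_flat), d[3], d[4])
    dz <- dwc * e$wc * (1 - e$wc)
    relu_ <- function(z) pmax(z, 0)
    # shared-MLP backward, accumulated over the avg and max branches
    h_avg_r <- relu_(e$h_avg); h_mx_r <- relu_(e$h_mx)
    e$fc2$grads$w <- tcrossprod(h_avg_r, dz) + tcrossprod(h_mx_r, dz)
    e$fc2$grads$b <- rowSums(dz) * 2
    dh_avg <- (e$fc2$params$w %*% dz) * (e$h_avg > 0)
    dh_mx <- (e$fc2$params$w %*% dz) * (e$h_mx > 0)
    e$fc1$grads$w <- tcrossprod(e$avg, dh_avg) + tcrossprod(e$mx, dh_mx)
    e$fc1$grads$b <- rowSums(dh_avg) + rowSums(dh_mx)
    davg <- e$fc1$params$w %*% dh_avg           # [C, N]
    dmx <- e$fc1$params$w %*% dh_mx
    # route avg-pool gradient uniformly, max-pool gradient to the argmax
    dx_flat <- dx
    dim(dx_flat) <- c(d[1] * d[2], d[3] * d[4])
    dx_flat <- dx_flat +
      matrix(rep(as.numeric(davg) / (d[1] * d[2]), each = d[1] * d[2]),
             d[1] * d[2], d[3] * d[4])
    dx_flat[cbind(e$mx_idx, seq_len(d[3] * d[4]))] <-
      dx_flat[cbind(e$mx_idx, seq_len(d[3] * d[4]))] + as.numeric(dmx)
    dim(dx_flat) <- d
    dx_flat
  }
  e
}

#' Spatial-attention weights of a feature tensor
#'
#' The channel-wise mean and maximum maps are stacked and passed through a
#' k x k convolution and a sigmoid, producing a per-pixel gate. Internal
#' layer of the attention block; see [build_generator()].
#'
#' @name spatial_attention
#' @keywords internal
NULL

nn_spatial_attention <- function(k = 7) {
  e <- new.env(parent = emptyenv())
  e$conv <- nn_conv(k, 2, 1)
  e$children <- list(e$conv)
  e$params <- list(); e$grads <- list()
  e$forward <- function(x) {
    d <- .tensor_dims(x)
    e$in_dims <- d
    e$x <- x
    perm <- aperm(x, c(3, 1, 2, 4))             # [C, H, W, N]
    dim(perm) <- c(d[3], d[1] * d[2] * d[4])
    mean_map <- colMeans(perm)
    mx_idx <- max.col(t(perm), ties.method = "first")
    e$mx_idx <- mx_idx
    max_map <- perm[cbind(mx_idx, seq_len(d[1] * d[2] * d[4]))]
    stats_map <- array(0, c(d[1], d[2], 2, d[4]))
    stats_map[, , 1, ] <- array(mean_map, c(d[1], d[2], d[4]))
    stats_map[, , 2, ] <- array(max_map, c(d[1], d[2], d[4]))
    z <- e$conv$forward(stats_map)
    e$ws <- 1 / (1 + exp(-z))                   # [H, W, 1, N]
    gate <- array(e$ws[, , 1, ], c(d[1], d[2], 1, d[4]))[, , rep(1, d[3]),
                                                         , drop = FALSE]
    e$gate <- gate
    x * gate
  }
  e$backward <- function(dout) {
    d <- e$in_dims
    dx <- dout * e$gate
    dws_full <- dout * e$x                      # sum over channels
    dws <- array(0, c(d[1], d[2], 1, d[4]))
    dws[, , 1, ] <- apply(dws_full, c(1, 2, 4), sum)
    dz <- dws * e$ws * (1 - e$ws)
    dstats <- e$conv$backward(dz)               # [H, W, 2, N]
    dmean <- dstats[, , 1, , drop = FALSE]
    dmax <- dstats[, , 2, , drop = FALSE]
    # mean path: spread evenly over channels
    dx <- dx + array(dmean[, , 1, ], c(d[1], d[2], 1, d[4]))[
      , , rep(1, d[3]), , drop = FALSE] / d[3]
    # max path: route to the argmax channel
    dx_perm <- aperm(dx, c(3, 1, 2, 4))
    dim(dx_perm) <- c(d[3], d[1] * d[2] * d[4])
    idx <- cbind(e$mx_idx, seq_len(d[1] * d[2] * d[4]))
    dx_perm[idx] <- dx_perm[idx] + as.numeric(dmax)
    dim(dx_perm) <- c(d[3], d[1], d[2], d[4])
    aperm(dx_perm, c(2, 3, 1, 4))
  }
  e
}

# channel attention followed by spatial attention
nn_cbam <- function(cc, reduction = 16, spatial_kernel = 7) {
  e <- new.env(parent = emptyenv())
  e$ca <- nn_channel_attention(cc, reduction)
  e$sa <- nn_spatial_attention(spatial_kernel)
  e$children <- list(e$ca, e$sa)
  e$params <- list(); e$grads <- list()
  e$forward <- function(x) e$sa$forward(e$ca$forward(x))
  e$backward <- function(dout) e$ca$backward(e$sa$backward(dout))
  e
}

# collect every parameter-bearing layer reachable from a list of layers
.collect_layers <- function(layers) {
  out <- list()
  walk <- function(l) {
    if (length(l$params)) out[[length(out) + 1]] <<- l
    if (!is.null(l$children)) for (ch in l$children) walk(ch)
  }
  for (l in layers) walk(l)
  out
}

# Adam optimizer over a list of parameter-bearing layers
nn_adam <- function(layers, lr = 2e-4, beta1 = 0.5, beta2 = 0.999,
                    eps = 1e-8) {
  leaves <- .collect_layers(layers)
  state <- lapply(leaves, function(l) {
    lapply(l$params, function(p) list(m = p * 0, v = p * 0))
  })
  t <- 0L
  step <- function() {
    t <<- t + 1L
    for (i in seq_along(leaves)) {
      l <- leaves[[i]]
      for (nm in names(l$params)) {
        g <- l$grads[[nm]]
        if (is.null(g)) next
        st <- state[[i]][[nm]]
        st$m <- beta1 * st$m + (1 - beta1) * g
        st$v <- beta2 * st$v + (1 - beta2) * g^2
        state[[i]][[nm]] <<- st
        mhat <- st$m / (1 - beta1^t)
        vhat <- st$v / (1 - beta2^t)
        l$params[[nm]] <- l$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
  }
  list(step = step, leaves = leaves)
}

# snapshot / restore all parameters of a network (list of top-level layers)
nn_get_params <- function(layers) {
  lapply(.collect_layers(layers), function(l) l$params)
}

nn_set_params <- function(layers, snapshot) {
  leaves <- .collect_layers(layers)
  stopifnot(length(leaves) == length(snapshot))
  for (i in seq_along(leaves)) leaves[[i]]$params <- snapshot[[i]]
  invisible(NULL)
}
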