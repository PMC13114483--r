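#' Normalized mean absolute error
#'
#' `NMAE = sum(|pred - ref|) / sum(ref)`: the summed absolute deviation
#' normalized by the summed reference signal, eliminating dimensional
#' effects. Smaller is better; 0 means identical maps.
#'
#' @param pred,ref Equal-shape numeric arrays; `sum(ref)` must be > 0.
#' @return Scalar NMAE.
#' @export
nmae <- function(pred, ref) {
  if (!all(dim(pred) == dim(ref)) || length(pred) != length(ref)) {
    stop("prediction and reference shapes differ")
  }
  denom <- sum(ref, na.rm = TRUE)
  if (!(denom > 0)) stop("reference sums to zero; NMAE undefined")
  sum(abs(pred - ref), na.rm = TRUE) / denom
}

#' Peak signal-to-noise ratio on the 0-255 scale
#'
#' `PSNR = 10 log10(255^2 / MSE)` in dB, with inputs expected on the 0-255
#' gray-level scale (coefficient maps should be rescaled by their
#' normalization ranges first, see [scale_to_gray()]). Identical images
#' yield `Inf`.
#'
#' @param pred,ref Equal-shape arrays on the 0-255 scale.
#' @return PSNR in dB (`Inf` when MSE is 0).
#' @export
psnr <- function(pred, ref) {
  if (!all(dim(pred) == dim(ref))) stop("shapes differ")
  mse <- mean((pred - ref)^2, na.rm = TRUE)
  if (mse == 0) return(Inf)
  10 * log10(255^2 / mse)
}

#' Structural similarity index (global statistics)
#'
#' Single-window SSIM computed from global image statistics:
#' `SSIM = (2 mu_p mu_r + C1)(2 cov + C2) /
#' ((mu_p^2 + mu_r^2 + C1)(var_p + var_r + C2))` with
#' `C1 = (0.01 * 255)^2`, `C2 = (0.03 * 255)^2` on 0-255-scaled inputs. A
#' Gaussian-windowed mean SSIM is available with `windowed = TRUE`.
#'
#' @param pred,ref Equal-shape matrices on the 0-255 scale.
#' @param windowed Use an 11x11 Gaussian-weighted local SSIM averaged over
#'   the image instead of global statistics.
#' @return Scalar SSIM in `[-1, 1]`.
#' @export
ssim <- function(pred, ref, windowed = FALSE) {
  if (!all(dim(pred) == dim(ref))) stop("shapes differ")
  c1 <- (0.01 * 255)^2
  c2 <- (0.03 * 255)^2
  if (!windowed) {
    mp <- mean(pred)
    mr <- mean(ref)
    vp <- mean((pred - mp)^2)
    vr <- mean((ref - mr)^2)
    cov <- mean((pred - mp) * (ref - mr))
    return(((2 * mp * mr + c1) * (2 * cov + c2)) /
             ((mp^2 + mr^2 + c1) * (vp + vr + c2)))
  }
  # 11x11 Gaussian window, sd 1.5 (separable convolution, edge-renormalized)
  g <- stats::dnorm(-5:5, sd = 1.5)
  g <- g / sum(g)
  smooth <- function(x) {
    ones <- matrix(1, nrow(x), ncol(x))
    conv1 <- function(m) {
      t(apply(apply(m, 2, function(v) stats::filter(v, g, sides = 2)), 1,
              function(v) stats::filter(v, g, sides = 2)))
    }
    num <- conv1(replace(x, is.na(x), 0))
    den <- conv1(ones * !is.na(x))
    num / den
  }
  mp <- smooth(pred); mr <- smooth(ref)
  vp <- smooth(pred^2) - mp^2
  vr <- smooth(ref^2) - mr^2
  cov <- smooth(pred * ref) - mp * mr
  s <- ((2 * mp * mr + c1) * (2 * cov + c2)) /
    ((mp^2 + mr^2 + c1) * (vp + vr + c2))
  mean(s, na.rm = TRUE)
}

#' Rescale a coefficient map to the 0-255 gray-level convention
#'
#' @param x Coefficient map in physical units.
#' @param range Normalization range `c(lo, hi)` of the coefficient.
#' @return Map on the 0-255 scale (not quantized).
#' @export
scale_to_gray <- function(x, range) {
  255 * (x - range[1]) / (range[2] - range[1])
}

#' Two-tailed paired Student's t-test on model errors
#'
#' Wraps the standard paired t-test on matched per-sample error vectors and
#' reports the significance band at the conventional 0.05 / 0.01 / 0.001
#' levels. Zero-variance differences are degenerate and flagged instead of
#' producing a spurious statistic.
#'
#' @param errors_a,errors_b Equal-length paired error vectors (n >= 2).
#' @return List with `t`, `p`, `df`, `significance` (one of `"ns"`,
#'   `"p<0.05"`, `"p<0.01"`, `"p<0.001"`) and `degenerate`.
#' @export
paired_ttest <- function(errors_a, errors_b) {
  if (length(errors_a) != length(errors_b)) stop("paired vectors differ in length")
  if (length(errors_a) < 2) stop("need at least two pairs")
  d <- errors_a - errors_b
  if (stats::sd(d) == 0) {
    return(list(t = if (all(d == 0)) 0 else sign(d[1]) * Inf,
                p = if (all(d == 0)) 1 else 0,
                df = length(d) - 1, significance = "ns", degenerate = TRUE))
  }
  ht <- stats::t.test(errors_a, errors_b, paired = TRUE,
                      alternative = "two.sided")
  p <- ht$p.value
  band <- if (p < 0.001) "p<0.001" else if (p < 0.01) "p<0.01" else
    if (p < 0.05) "p<0.05" else "ns"
  list(t = unname(ht$statistic), p = p, df = unname(ht$parameter),
       significance = band, degenerate = FALSE)
}

#' Per-image quality report for predicted coefficient maps
#'
#' Computes NMAE, PSNR and SSIM per image and coefficient channel, plus
#' aggregate mean and standard deviation, in the conventional
#' model x bruise level x coefficient table layout.
#'
#' @param preds,refs Lists of `optical_property_map` objects (matched).
#' @param norm_ranges Normalization ranges used for the 0-255 rescaling of
#'   PSNR/SSIM inputs.
#' @param model,level Optional annotation columns.
#' @return Data frame with one row per image and coefficient.
#' @export
metric_report <- function(preds, refs,
                          norm_ranges = list(mu_a = c(0, 0.5),
                                             mu_s_prime = c(0, 4)),
                          model = "model", level = "all") {
  stopifnot(length(preds) == length(refs))
  rows <- list()
  for (i in seq_along(preds)) {
    for (coef in c("mu_a", "mu_s_prime")) {
      p <- preds[[i]][[coef]]
      r <- refs[[i]][[coef]]
      pg <- scale_to_gray(p, norm_ranges[[coef]])
      rg <- scale_to_gray(r, norm_ranges[[coef]])
      rows[[length(rows) + 1]] <- data.frame(
        model = model, level = level, image = i, coefficient = coef,
        nmae = nmae(p, r), psnr = psnr(pg, rg), ssim = ssim(pg, rg))
    }
  }
  do.call(rbind, rows)
}

#' Aggregate a metric report to mean +/- sd
#'
#' @param report Output of [metric_report()].
#' @return Data frame aggregated over images.
#' @export
summarize_metrics <- function(report) {
  agg <- stats::aggregate(
    report[c("nmae", "psnr", "ssim")],
    by = report[c("model", "level", "coefficient")],
    FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  agg
}
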