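#' Wrapped phase of a four-step fringe stack
#'
#' For fringe images `F_i = a + b cos(phi + psi_i)` at phases 0, pi/2, pi,
#' 3pi/2, the wrapped phase is `atan2(F4 - F2, F1 - F3)`, returned in
#' `(-pi, pi]`. Pixels with no fringe modulation (`F1 = F3` and `F2 = F4`)
#' are undefined and flagged.
#'
#' @param fringes A `fringe_stack` (see [render_curved_scene()]) or a list
#'   with elements `f1`..`f4`.
#' @param amp_tol Modulation amplitude below which a pixel is flagged.
#' @return Phase matrix in `(-pi, pi]` with a logical `flagged` attribute.
#' @export
wrapped_phase <- function(fringes, amp_tol = 1e-12) {
  s <- fringes$f4 - fringes$f2
  c_ <- fringes$f1 - fringes$f3
  flagged <- sqrt(s^2 + c_^2) < amp_tol
  phi <- atan2(s, c_)
  phi[phi <= -pi] <- pi       # wrap convention: (-pi, pi]
  phi[flagged] <- NA_real_
  attr(phi, "flagged") <- flagged
  phi
}

# wrap any angle into (-pi, pi]
.wrap_angle <- function(x) {
  w <- x - 2 * pi * round(x / (2 * pi))
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w
}

#' Unwrap a wrapped phase map
#'
#' Row-wise removal of 2pi jumps followed by a column-seam reconciliation
#' through the first column, so that the output differs from the input by
#' integer multiples of 2pi everywhere. Flagged (`NA`) pixels are filled by
#' nearest-neighbor interpolation along rows before unwrapping.
#'
#' @param wrapped Phase matrix from [wrapped_phase()].
#' @return Continuous phase matrix.
#' @export
unwrap_phase <- function(wrapped) {
  x <- wrapped
  # fill NAs along rows from the nearest valid neighbor
  if (anyNA(x)) {
    for (r in seq_len(nrow(x))) {
      row <- x[r, ]
      if (anyNA(row) && any(!is.na(row))) {
        idx <- which(!is.na(row))
        row <- stats::approx(idx, row[idx], xout = seq_along(row),
                             method = "constant", rule = 2)$y
        x[r, ] <- row
      }
    }
    x[is.na(x)] <- 0
  }
  unwrap_vec <- function(v) {
    d <- .wrap_angle(diff(v))
    cumsum(c(v[1], d))
  }
  out <- t(apply(x, 1, unwrap_vec))
  # reconcile rows: the first column must itself be continuous
  col1 <- unwrap_vec(x[, 1])
  offset <- 2 * pi * round((col1 - out[, 1]) / (2 * pi))
  out + offset
}

#' Convert a phase difference to surface height
#'
#' Linear phase-to-height mapping `h = k_height * dphi`, floored at zero.
#'
#' @param dphi Unwrapped phase minus the reference-plane phase (radians).
#' @param k_height Calibration constant in mm/rad (> 0).
#' @return Height map in mm (class `matrix`).
#' @export
phase_to_height <- function(dphi, k_height) {
  if (k_height <= 0) stop("k_height must be > 0")
  pmax(k_height * dphi, 0)
}

#' Per-pixel correction coefficient from a height map
#'
#' `c = h / max(h)`, clamped to `[c_min, 1]`. Pixels clamped at `c_min`
#' (typically the fruit rim) are flagged low-confidence.
#'
#' @param h Height map in mm with `max(h) > 0`.
#' @param c_min Lower clamp avoiding division blow-up at the rim.
#' @return Correction field in `[c_min, 1]` with a `low_confidence`
#'   attribute.
#' @export
correction_field <- function(h, c_min = 0.05) {
  hmax <- max(h, na.rm = TRUE)
  if (!(hmax > 0)) stop("height map is identically zero")
  cc <- pmin(pmax(h / hmax, c_min), 1)
  attr(cc, "low_confidence") <- h / hmax < c_min
  cc
}

#' Correct curved-surface reflectance
#'
#' Divides an uncorrected diffuse reflectance map by the profile correction
#' coefficient: `R_correct = R_uncorrect / c`.
#'
#' @param r_uncorrect Uncorrected reflectance map.
#' @param cc Correction field from [correction_field()].
#' @return Corrected reflectance map.
#' @export
correct_reflectance <- function(r_uncorrect, cc) {
  if (!all(dim(r_uncorrect) == dim(cc))) {
    stop("reflectance map and correction field shapes differ")
  }
  r_uncorrect / cc
}

#' Run the full profilometry + correction pipeline on a curved scene
#'
#' Recovers the surface height from the sample and reference fringe stacks,
#' builds the correction field and corrects both calibrated reflectance
#' channels.
#'
#' @param scene Output of [render_curved_scene()].
#' @param reference A flat-reference `phase_shift_stack` for calibration
#'   (rendered internally when `NULL`).
#' @param c_min Correction-field clamp.
#' @return List with `height`, `correction`, `rd_dc`, `rd_ac` (corrected
#'   maps) and the uncorrected `rd_dc_raw`, `rd_ac_raw`.
#' @export
profile_correct_scene <- function(scene, reference = NULL, c_min = 0.05) {
  phi_s <- unwrap_phase(wrapped_phase(scene$fringes))
  phi_r <- unwrap_phase(wrapped_phase(scene$fringes_reference))
  h <- phase_to_height(phi_s - phi_r, scene$k_height)
  cc <- correction_field(h, c_min)
  size <- dim(scene$stack$i_dc)
  ref <- if (is.null(reference)) {
    render_reference_stack(scene$stack$fx_ac, size,
                           pixel_size_mm = scene$stack$pixel_size_mm)
  } else reference
  cal <- demodulate_stack(scene$stack, ref)
  list(height = h, correction = cc,
       rd_dc = correct_reflectance(cal$rd_dc, cc),
       rd_ac = correct_reflectance(cal$rd_ac, cc),
       rd_dc_raw = cal$rd_dc, rd_ac_raw = cal$rd_ac)
}
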