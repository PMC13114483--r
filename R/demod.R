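#' Three-phase AC amplitude demodulation
#'
#' Extracts the AC amplitude envelope from three images of a sinusoidally
#' modulated illumination acquired at phase shifts 0, 2pi/3 and 4pi/3:
#' `M_AC = (2/3) * sqrt((I1-I2)^2 + (I2-I3)^2 + (I3-I1)^2)` pixelwise.
#'
#' The 2/3 prefactor is retained as-is; the conventional sqrt(2)/3 variant
#' differs only by a global factor that cancels under reference calibration
#' (see [calibrate()]).
#'
#' @param i1,i2,i3 Equal-shape nonnegative intensity images (matrices).
#' @param prefactor Demodulation prefactor; `2/3` by default.
#' @return AC amplitude map, same shape as the inputs.
#' @export
demodulate_ac <- function(i1, i2, i3, prefactor = 2 / 3) {
  if (!all(dim(i1) == dim(i2)) || !all(dim(i1) == dim(i3))) {
    stop("phase-shifted images must have identical shapes")
  }
  prefactor * sqrt((i1 - i2)^2 + (i2 - i3)^2 + (i3 - i1)^2)
}

#' DC amplitude of the unmodulated frame
#'
#' The dedicated fx = 0 frame is used directly as the DC amplitude; the same
#' treatment is applied to sample and reference so any common constant
#' cancels in calibration.
#'
#' @param i_dc Intensity image acquired at spatial frequency 0.
#' @return The DC amplitude map (identical to `i_dc`).
#' @export
demodulate_dc <- function(i_dc) i_dc

#' Calibrate an amplitude map against a reference standard
#'
#' Converts a demodulated sample amplitude to quantitative diffuse
#' reflectance using a reference of known reflectivity measured under the
#' same illumination: `Rd = (M_sample / M_reference) * R_ref`.
#'
#' Pixels where the reference amplitude is not strictly positive cannot be
#' calibrated and are returned as `NA` with their positions in the
#' `invalid` attribute. Values above `saturation` are flagged (attribute
#' `saturated`) but not altered.
#'
#' @param m_sample Demodulated sample amplitude map.
#' @param m_reference Demodulated reference amplitude map (same shape and
#'   spatial frequency).
#' @param r_ref Reflectivity of the reference standard (default 0.99).
#' @param saturation Threshold above which reflectance is flagged.
#' @return Diffuse reflectance map with attributes `invalid` and
#'   `saturated` (logical matrices).
#' @export
calibrate <- function(m_sample, m_reference, r_ref = 0.99,
                      saturation = 1.05) {
  if (!all(dim(m_sample) == dim(m_reference))) {
    stop("sample and reference maps must have identical shapes")
  }
  bad <- !(m_reference > 0)
  rd <- m_sample / m_reference * r_ref
  rd[bad] <- NA_real_
  attr(rd, "invalid") <- bad
  attr(rd, "saturated") <- !bad & rd > saturation
  rd
}

#' Demodulate and calibrate a full phase-shift stack
#'
#' Convenience wrapper running [demodulate_ac()] / [demodulate_dc()] on a
#' sample stack and a reference stack rendered (or acquired) under the same
#' illumination, then calibrating both frequency channels.
#'
#' @param stack Sample `phase_shift_stack` (see [render_stack()]).
#' @param reference Reference `phase_shift_stack`.
#' @param r_ref Reference reflectivity.
#' @return List with `rd_dc` and `rd_ac` reflectance maps and `fx_ac`.
#' @export
demodulate_stack <- function(stack, reference, r_ref = 0.99) {
  stopifnot(inherits(stack, "phase_shift_stack"),
            inherits(reference, "phase_shift_stack"))
  if (!isTRUE(all.equal(stack$fx_ac, reference$fx_ac))) {
    stop("sample and reference stacks were rendered at different fx")
  }
  m_ac <- demodulate_ac(stack$i1, stack$i2, stack$i3)
  m_ac_ref <- demodulate_ac(reference$i1, reference$i2, reference$i3)
  m_dc <- demodulate_dc(stack$i_dc)
  m_dc_ref <- demodulate_dc(reference$i_dc)
  list(rd_dc = calibrate(m_dc, m_dc_ref, r_ref),
       rd_ac = calibrate(m_ac, m_ac_ref, r_ref),
       fx_ac = stack$fx_ac)
}
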