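#' Simulate a bruise-discrimination cohort
#'
#' Generates a seeded cohort of synthetic fruit scenes (non-bruised, and
#' bruised at the requested severities), renders each through the
#' structured-illumination model, demodulates and calibrates against a
#' shared reference, and inverts to optical property maps. The result is a
#' sample list directly consumable by [two_step_pipeline()].
#'
#' @param n_non_bruised,n_bruised Number of sound / bruised samples.
#' @param fruit_kind `"apple"`, `"pear"` or `"phantom"`.
#' @param severity Scalar or vector of severities assigned to the bruised
#'   samples (recycled); severity 0.5 corresponds to a mild impact and
#'   1.0 to a severe one.
#' @param size Image side length in pixels.
#' @param fx_ac AC spatial frequency, mm^-1.
#' @param noise_sd Render noise sd (fraction of the nominal full scale of
#'   1 intensity unit).
#' @param seed Master seed; per-scene seeds are derived from it.
#' @param jitter_sd Relative lognormal jitter of each sample's base
#'   coefficients, emulating biological between-fruit variation.
#' @param invert_method `"lut"` (default) or `"nls"`.
#' @return List of samples with `mu_s_prime`, `mu_a`, `bruise_mask`,
#'   `sound_mask`, `valid`, `truth_bruised`, `truth_severity`.
#' @export
simulate_cohort <- function(n_non_bruised = 20, n_bruised = 20,
                            fruit_kind = "apple", severity = 1.0,
                            size = 64, fx_ac = 0.2, noise_sd = 0.005,
                            seed = 42L, jitter_sd = 0.02,
                            invert_method = "lut") {
  n <- n_non_bruised + n_bruised
  sev <- rep_len(severity, n_bruised)
  reference <- render_reference_stack(fx_ac, c(size, size),
                                      pixel_size_mm = 100 / size)
  lut <- if (invert_method == "lut") build_inversion_lut(fx_ac) else NULL
  set.seed(seed)
  scene_seeds <- sample.int(.Machine$integer.max - 1L, n)
  jit <- matrix(exp(stats::rnorm(2 * n, sd = jitter_sd)), n, 2)
  base <- fruit_optics[[fruit_kind]]
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    bruised <- i > n_non_bruised
    s <- if (bruised) sev[i - n_non_bruised] else 0
    spec <- fruit_scene_spec(
      fruit_kind, size = size,
      base_mu_a = base$mu_a * jit[i, 1],
      base_mu_s_prime = base$mu_s_prime * jit[i, 2],
      bruise_radius_mm = if (bruised) 15 else 0,
      severity = s, seed = scene_seeds[i])
    scene <- make_fruit_map(spec)
    stack <- render_stack(scene$map, fx_ac = fx_ac, noise_sd = noise_sd,
                          seed = scene_seeds[i])
    cal <- demodulate_stack(stack, reference)
    est <- invert_map(cal$rd_dc, cal$rd_ac, fx_ac, method = invert_method,
                      lut = lut, pixel_size_mm = 100 / size)
    # grading masks: the nominal impact-site geometry, known for every
    # sample from the standardized impact protocol
    geom <- make_fruit_map(fruit_scene_spec(fruit_kind, size = size,
                                            bruise_radius_mm = 15,
                                            severity = 0))
    samples[[i]] <- list(
      mu_s_prime = est$mu_s_prime, mu_a = est$mu_a,
      bruise_mask = geom$bruise_mask, sound_mask = geom$sound_mask,
      valid = attr(est, "valid"),
      truth_bruised = bruised,
      truth_severity = if (!bruised) NA_character_
        else if (s >= 0.75) "severe" else "mild")
  }
  samples
}
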