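#' Reference optical coefficients for fruit tissue
#'
#' Mean absorption and reduced scattering coefficients (mm^-1) of sound and
#' bruised tissue for green apples and crown pears, as measured by
#' conventional SFDI, plus a texture-free phantom default. Bruising leaves
#' mu_a nearly unchanged and depresses mu_s_prime.
#'
#' @format Named list per fruit kind with `mu_a`, `mu_s_prime` (sound) and
#'   `mu_s_prime_bruised` (fully bruised) in mm^-1.
#' @export
fruit_optics <- list(
  apple   = list(mu_a = 0.0324, mu_s_prime = 1.726, mu_s_prime_bruised = 1.215),
  pear    = list(mu_a = 0.0418, mu_s_prime = 2.102, mu_s_prime_bruised = 1.702),
  phantom = list(mu_a = 0.05,   mu_s_prime = 1.0,   mu_s_prime_bruised = 0.7)
)

#' Construct an optical property map
#'
#' @param mu_a_map,mu_s_prime_map Equal-shape matrices of coefficients in
#'   mm^-1; `mu_a_map >= 0`, `mu_s_prime_map > 0` elementwise.
#' @param pixel_size_mm Pixel pitch in mm/px.
#' @return An object of class `optical_property_map`.
#' @export
optical_property_map <- function(mu_a_map, mu_s_prime_map,
                                 pixel_size_mm = 100 / 256) {
  if (!all(dim(mu_a_map) == dim(mu_s_prime_map))) {
    stop("coefficient maps must have identical shapes")
  }
  if (any(mu_a_map < 0) || any(mu_s_prime_map <= 0)) {
    stop("require mu_a >= 0 and mu_s_prime > 0 elementwise")
  }
  structure(list(mu_a = mu_a_map, mu_s_prime = mu_s_prime_map,
                 pixel_size_mm = pixel_size_mm),
            class = "optical_property_map")
}

#' Specify a synthetic fruit scene
#'
#' Describes a planar or spherical-cap fruit-like sample with an optional
#' circular subsurface bruise. At `severity = 1` the bruise disc carries the
#' fully bruised reduced scattering coefficient of the fruit kind; at 0 the
#' sample is sound. Pear scenes receive seeded multiplicative lognormal
#' speckle on mu_s_prime emulating lenticels and sporadic brown spots.
#'
#' @param fruit_kind `"apple"`, `"pear"` or `"phantom"`.
#' @param size Image side length in pixels (square scenes).
#' @param base_mu_a,base_mu_s_prime Sound-tissue coefficients, mm^-1;
#'   defaults taken from [fruit_optics].
#' @param bruise_center Pixel coordinates `c(row, col)` of the bruise
#'   center; defaults to the scene center.
#' @param bruise_radius_mm Bruise radius in mm; 0 means non-bruised.
#' @param severity Bruise severity in `[0, 1]`, linearly interpolating
#'   mu_s_prime from sound to fully bruised inside the disc.
#' @param lenticel_speckle_sd Standard deviation of the lognormal speckle
#'   applied to pear mu_s_prime maps (0 disables).
#' @param surface `"planar"` or `"spherical_cap"`.
#' @param height_max_mm Cap height at the scene center (spherical_cap only).
#' @param footprint_radius_mm Radius of the fruit footprint on the image
#'   plane (spherical_cap only).
#' @param pixel_size_mm Pixel pitch in mm/px; defaults to a 100 mm field.
#' @param seed Integer seed controlling the speckle and any render noise.
#' @return An object of class `fruit_scene_spec`.
#' @export
fruit_scene_spec <- function(fruit_kind = c("apple", "pear", "phantom"),
                             size = 256,
                             base_mu_a = NULL, base_mu_s_prime = NULL,
                             bruise_center = NULL,
                             bruise_radius_mm = 15,
                             severity = 1,
                             lenticel_speckle_sd = NULL,
                             surface = c("planar", "spherical_cap"),
                             height_max_mm = 20,
                             footprint_radius_mm = NULL,
                             pixel_size_mm = 100 / size,
                             seed = 1L) {
  fruit_kind <- match.arg(fruit_kind)
  surface <- match.arg(surface)
  ref <- fruit_optics[[fruit_kind]]
  if (is.null(base_mu_a)) base_mu_a <- ref$mu_a
  if (is.null(base_mu_s_prime)) base_mu_s_prime <- ref$mu_s_prime
  if (is.null(bruise_center)) bruise_center <- c(size, size) / 2 + 0.5
  if (is.null(lenticel_speckle_sd)) {
    lenticel_speckle_sd <- if (fruit_kind == "pear") 0.03 else 0
  }
  if (is.null(footprint_radius_mm)) {
    footprint_radius_mm <- 0.45 * size * pixel_size_mm
  }
  stopifnot(severity >= 0, severity <= 1, bruise_radius_mm >= 0)
  if (surface == "spherical_cap" && height_max_mm <= 0) {
    stop("spherical cap height_max_mm must be > 0")
  }
  structure(list(fruit_kind = fruit_kind, size = size,
                 base_mu_a = base_mu_a, base_mu_s_prime = base_mu_s_prime,
                 mu_s_prime_bruised = ref$mu_s_prime_bruised,
                 bruise_center = bruise_center,
                 bruise_radius_mm = bruise_radius_mm,
                 severity = severity,
                 lenticel_speckle_sd = lenticel_speckle_sd,
                 surface = surface, height_max_mm = height_max_mm,
                 footprint_radius_mm = footprint_radius_mm,
                 pixel_size_mm = pixel_size_mm, seed = as.integer(seed)),
            class = "fruit_scene_spec")
}

# squared distance (mm^2) of every pixel from a center given in pixel coords
.pixel_dist2_mm <- function(size, center_px, pixel_size_mm) {
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  ((rows - center_px[1])^2 + (cols - center_px[2])^2) * pixel_size_mm^2
}

#' Build the optical property map of a fruit scene
#'
#' Renders the per-pixel (mu_a, mu_s_prime) ground truth of a
#' [fruit_scene_spec()], together with the bruise disc mask and an
#' equal-area annulus of adjacent sound tissue used by the mean-ratio
#' grading statistic.
#'
#' @param spec A `fruit_scene_spec`.
#' @return List with `map` (an `optical_property_map`), `bruise_mask` and
#'   `sound_mask` (logical matrices).
#' @export
make_fruit_map <- function(spec) {
  stopifnot(inherits(spec, "fruit_scene_spec"))
  size <- spec$size
  d2 <- .pixel_dist2_mm(size, spec$bruise_center, spec$pixel_size_mm)
  r <- spec$bruise_radius_mm
  half_field <- size * spec$pixel_size_mm / 2
  if (r > 0 && r * sqrt(2) > half_field) {
    stop("bruise disc (and its sound annulus) exceed the field of view")
  }
  bruise_mask <- if (r > 0) d2 <= r^2 else matrix(FALSE, size, size)
  # annulus with outer radius r*sqrt(2) has the same area as the disc
  sound_mask <- if (r > 0) d2 > r^2 & d2 <= 2 * r^2 else !bruise_mask

  mu_a <- matrix(spec$base_mu_a, size, size)
  mu_s <- matrix(spec$base_mu_s_prime, size, size)
  bruised_val <- spec$base_mu_s_prime +
    spec$severity * (spec$mu_s_prime_bruised - spec$base_mu_s_prime)
  mu_s[bruise_mask] <- bruised_val
  if (spec$lenticel_speckle_sd > 0) {
    set.seed(spec$seed)
    speckle <- matrix(exp(stats::rnorm(size^2, mean = 0,
                                       sd = spec$lenticel_speckle_sd)),
                      size, size)
    mu_s <- mu_s * speckle
  }
  list(map = optical_property_map(mu_a, mu_s, spec$pixel_size_mm),
       bruise_mask = bruise_mask, sound_mask = sound_mask)
}

#' Render a phase-shift stack from an optical property map
#'
#' Analytic structured-illumination renderer: for illumination offset `a0`
#' and modulation `a1`, each AC frame is
#' `I_i = g * (a0 * Rd(0) + a1 * cos(2 pi fx_ac x + psi_i) * Rd(fx_ac))`
#' plus optional Gaussian read noise (clipped at 0), and the DC frame is
#' `I_dc = g * a0 * Rd(0)`. `x` is the column coordinate in mm; phases are
#' 0, 2pi/3, 4pi/3.
#'
#' @param map An `optical_property_map`.
#' @param fx_ac AC spatial frequency, mm^-1 (> 0).
#' @param a0,a1 Illumination offset and modulation; require `a0 >= a1 >= 0`.
#' @param gain Fixed detector gain.
#' @param noise_sd Gaussian read-noise standard deviation in intensity
#'   units; default 0.5% of the full scale `gain * (a0 + a1)`.
#' @param seed Integer seed for the noise (ignored when `noise_sd = 0`).
#' @param n Refractive index passed to the forward model.
#' @param mueff_dialect Forward-model dialect.
#' @return An object of class `phase_shift_stack` with elements `i_dc`,
#'   `i1`, `i2`, `i3`, `fx_ac`, `pixel_size_mm`.
#' @export
render_stack <- function(map, fx_ac = 0.2, a0 = 0.5, a1 = 0.5, gain = 1,
                         noise_sd = 0.005 * gain * (a0 + a1), seed = 1L,
                         n = 1.43,
                         mueff_dialect = c("squared", "printed")) {
  stopifnot(inherits(map, "optical_property_map"))
  if (fx_ac < 0) stop("fx_ac must be >= 0")
  if (!(a0 >= a1 && a1 >= 0)) stop("require a0 >= a1 >= 0 (nonnegative illumination)")
  mueff_dialect <- match.arg(mueff_dialect)
  rd0 <- diffuse_reflectance(map$mu_a, map$mu_s_prime, 0, n, mueff_dialect)
  rdf <- diffuse_reflectance(map$mu_a, map$mu_s_prime, fx_ac, n, mueff_dialect)
  .render_from_rd(rd0, rdf, fx_ac, map$pixel_size_mm, a0, a1, gain,
                  noise_sd, seed)
}

.render_from_rd <- function(rd0, rdf, fx_ac, pixel_size_mm, a0, a1, gain,
                            noise_sd, seed) {
  size <- dim(rd0)
  x_mm <- matrix((seq_len(size[2]) - 1) * pixel_size_mm,
                 size[1], size[2], byrow = TRUE)
  phases <- c(0, 2 * pi / 3, 4 * pi / 3)
  frames <- lapply(phases, function(psi) {
    gain * (a0 * rd0 + a1 * cos(2 * pi * fx_ac * x_mm + psi) * rdf)
  })
  i_dc <- gain * a0 * rd0
  if (noise_sd > 0) {
    set.seed(seed)
    addn <- function(img) {
      pmax(img + matrix(stats::rnorm(length(img), sd = noise_sd),
                        nrow(img), ncol(img)), 0)
    }
    frames <- lapply(frames, addn)
    i_dc <- addn(i_dc)
  }
  structure(list(i_dc = i_dc, i1 = frames[[1]], i2 = frames[[2]],
                 i3 = frames[[3]], fx_ac = fx_ac,
                 pixel_size_mm = pixel_size_mm),
            class = "phase_shift_stack")
}

#' Render the calibration-reference stack
#'
#' Same renderer as [render_stack()] with the diffuse reflectance fixed at
#' the reference reflectivity (0.99) at both frequencies, emulating the
#' standard reflectance reference.
#'
#' @param fx_ac AC spatial frequency, mm^-1.
#' @param shape `c(rows, cols)` of the images.
#' @inheritParams render_stack
#' @param pixel_size_mm Pixel pitch in mm/px.
#' @param r_ref Reference reflectivity.
#' @return A `phase_shift_stack`.
#' @export
render_reference_stack <- function(fx_ac = 0.2, shape = c(256, 256),
                                   a0 = 0.5, a1 = 0.5, gain = 1,
                                   noise_sd = 0, seed = 1L,
                                   pixel_size_mm = 100 / shape[2],
                                   r_ref = 0.99) {
  rd <- matrix(r_ref, shape[1], shape[2])
  .render_from_rd(rd, rd, fx_ac, pixel_size_mm, a0, a1, gain, noise_sd, seed)
}

#' Encode / decode optical coefficient maps as 8-bit RGB labels
#'
#' The label convention stores mu_a in the R channel and mu_s_prime in the G
#' channel, each normalized to `[0, 1]` by `norm_ranges` and quantized to
#' 8 bits; the B channel is fixed at zero. Decoding inverts the mapping; the
#' round-trip error is at most half a quantization step per coefficient.
#'
#' @param map An `optical_property_map` with values inside `norm_ranges`.
#' @param norm_ranges List with `mu_a` and `mu_s_prime` ranges in mm^-1.
#' @return `encode_rgb_label()`: an H x W x 3 integer array in 0..255.
#' @export
encode_rgb_label <- function(map,
                             norm_ranges = list(mu_a = c(0, 0.5),
                                                mu_s_prime = c(0, 4))) {
  stopifnot(inherits(map, "optical_property_map"))
  ra <- norm_ranges$mu_a
  rs <- norm_ranges$mu_s_prime
  if (any(map$mu_a < ra[1]) || any(map$mu_a > ra[2]) ||
      any(map$mu_s_prime < rs[1]) || any(map$mu_s_prime > rs[2])) {
    stop("coefficient values fall outside norm_ranges; refusing to clip")
  }
  size <- dim(map$mu_a)
  lab <- array(0L, c(size, 3))
  lab[, , 1] <- as.integer(round(255 * (map$mu_a - ra[1]) / diff(ra)))
  lab[, , 2] <- as.integer(round(255 * (map$mu_s_prime - rs[1]) / diff(rs)))
  lab
}

#' @rdname encode_rgb_label
#' @param label H x W x 3 array with values in 0..255 (or 0..1 as read from
#'   an 8-bit PNG, detected automatically).
#' @param pixel_size_mm Pixel pitch recorded on the decoded map.
#' @export
decode_rgb_label <- function(label,
                             norm_ranges = list(mu_a = c(0, 0.5),
                                                mu_s_prime = c(0, 4)),
                             pixel_size_mm = 100 / 256) {
  stopifnot(length(dim(label)) == 3, dim(label)[3] >= 2)
  scale <- if (max(label) <= 1) 1 else 255
  ra <- norm_ranges$mu_a
  rs <- norm_ranges$mu_s_prime
  mu_a <- ra[1] + label[, , 1] / scale * diff(ra)
  mu_s <- rs[1] + label[, , 2] / scale * diff(rs)
  # quantization can land mu_s_prime exactly on 0; keep it strictly positive
  mu_s[mu_s <= 0] <- .Machine$double.eps
  optical_property_map(mu_a, mu_s, pixel_size_mm)
}

#' Render a curved (spherical-cap) scene with fringe projection
#'
#' Emulates the center-bright / edge-dark distortion that curved fruit
#' surfaces imprint on structured-illumination images. The surface is a
#' spherical cap of height `height_max_mm` over the fruit footprint; every
#' rendered intensity image is multiplied pixelwise by the correction
#' coefficient `c = h / h_max` (clamped below at `c_min`), so that dividing
#' the demodulated reflectance by `c` inverts the distortion exactly. A
#' four-phase fringe stack (phases 0, pi/2, pi, 3pi/2) is emitted whose
#' phase offset relative to a flat reference plane is `h / k_height`.
#'
#' @param spec A `fruit_scene_spec` with `surface = "spherical_cap"`.
#' @param fx_ac AC spatial frequency for the reflectance stack.
#' @param fringe_freq Fringe-pattern frequency in mm^-1.
#' @param k_height Height-to-phase calibration constant, mm/rad.
#' @param c_min Lower clamp of the correction coefficient.
#' @param noise_sd Render noise (0 for a noiseless scene).
#' @return List with `stack` (distorted `phase_shift_stack`), `fringes` and
#'   `fringes_reference` (class `fringe_stack`), `height` (ground-truth
#'   height map, mm), `correction` (the injected `c` field), `map`,
#'   `bruise_mask`, `sound_mask`, `k_height`.
#' @export
render_curved_scene <- function(spec, fx_ac = 0.2, fringe_freq = 0.1,
                                k_height = 5, c_min = 0.05, noise_sd = 0) {
  stopifnot(inherits(spec, "fruit_scene_spec"))
  if (spec$surface != "spherical_cap") {
    stop("render_curved_scene requires a spherical_cap surface")
  }
  scene <- make_fruit_map(spec)
  size <- spec$size
  center <- c(size, size) / 2 + 0.5
  d2 <- .pixel_dist2_mm(size, center, spec$pixel_size_mm)
  a <- spec$footprint_radius_mm
  hmax <- spec$height_max_mm
  rs <- (a^2 + hmax^2) / (2 * hmax)        # sphere radius from cap geometry
  h <- sqrt(pmax(rs^2 - d2, 0)) - (rs - hmax)
  h <- pmax(h, 0)
  h[d2 > a^2] <- 0

  # normalize by the realized pixel maximum so the most elevated pixel is
  # exactly undistorted (the cap apex falls between pixel centers)
  cfield <- pmin(pmax(h / max(h), c_min), 1)
  stack <- render_stack(scene$map, fx_ac = fx_ac, noise_sd = noise_sd,
                        seed = spec$seed)
  for (f in c("i_dc", "i1", "i2", "i3")) stack[[f]] <- stack[[f]] * cfield

  x_mm <- matrix((seq_len(size) - 1) * spec$pixel_size_mm,
                 size, size, byrow = TRUE)
  phi_ref <- 2 * pi * fringe_freq * x_mm
  phi <- phi_ref + h / k_height
  mk_fringes <- function(phase_map) {
    psis <- c(0, pi / 2, pi, 3 * pi / 2)
    fr <- lapply(psis, function(psi) 0.5 + 0.4 * cos(phase_map + psi))
    structure(list(f1 = fr[[1]], f2 = fr[[2]], f3 = fr[[3]], f4 = fr[[4]],
                   fringe_freq = fringe_freq),
              class = "fringe_stack")
  }
  list(stack = stack, fringes = mk_fringes(phi),
       fringes_reference = mk_fringes(phi_ref),
       height = h, correction = cfield, map = scene$map,
       bruise_mask = scene$bruise_mask, sound_mask = scene$sound_mask,
       k_height = k_height)
}

#' Batch-generate the paired simulation dataset
#'
#' Sweeps a grid of (mu_a, mu_s_prime) base values, renders each planar
#' scene, demodulates and calibrates it against a shared reference, and
#' writes paired samples: the calibrated AC diffuse reflectance image
#' (float TIFF), the 8-bit RGB coefficient label (PNG) and the ground-truth
#' coefficient maps (float TIFF with recorded ranges). Samples are shuffled
#' deterministically and split 7:3 into training and validation sets.
#'
#' The default sweep covers 20 absorption levels crossed with 40 reduced
#' scattering levels, i.e. exactly 800 paired samples (560 train / 240
#' validation).
#'
#' @param out_dir Output directory (created if missing).
#' @param sweep Data frame with columns `mu_a` and `mu_s_prime` (mm^-1); one
#'   scene per row. Defaults to [default_sweep()].
#' @param size Image side length in pixels.
#' @param fx_ac AC spatial frequency, mm^-1.
#' @param noise_sd Render noise sd (default 0.5% of full scale).
#' @param seed Integer seed driving render noise and the split shuffle.
#' @param train_fraction Fraction of samples tagged `train`.
#' @param write_truth Also write the unquantized ground-truth maps.
#' @return The dataset manifest (list), invisibly also written as
#'   `manifest.json` in `out_dir`.
#' @export
build_dataset <- function(out_dir, sweep = default_sweep(), size = 256,
                          fx_ac = 0.2, noise_sd = 0.005, seed = 1L,
                          train_fraction = 0.7, write_truth = TRUE) {
  stopifnot(nrow(sweep) >= 1, all(c("mu_a", "mu_s_prime") %in% names(sweep)))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir)
  }
  pixel_size <- 100 / size
  reference <- render_reference_stack(fx_ac, c(size, size),
                                      pixel_size_mm = pixel_size)
  n <- nrow(sweep)
  entries <- vector("list", n)
  has_bruise <- !is.null(sweep$bruise_radius_mm)
  for (i in seq_len(n)) {
    if (has_bruise && sweep$bruise_radius_mm[i] > 0) {
      spec <- fruit_scene_spec("phantom", size = size,
                               base_mu_a = sweep$mu_a[i],
                               base_mu_s_prime = sweep$mu_s_prime[i],
                               bruise_radius_mm = sweep$bruise_radius_mm[i],
                               severity = if (!is.null(sweep$severity)) sweep$severity[i] else 1,
                               seed = seed + i)
      map <- make_fruit_map(spec)$map
    } else {
      map <- optical_property_map(matrix(sweep$mu_a[i], size, size),
                                  matrix(sweep$mu_s_prime[i], size, size),
                                  pixel_size)
    }
    stack <- render_stack(map, fx_ac = fx_ac, noise_sd = noise_sd,
                          seed = seed + i)
    cal <- demodulate_stack(stack, reference)
    stem <- sprintf("sample_%04d", i)
    input_path <- file.path(out_dir, paste0(stem, "_rd.tif"))
    label_path <- file.path(out_dir, paste0(stem, "_label.png"))
    write_image(pmin(pmax(cal$rd_ac, 0), 1), input_path)
    write_image(encode_rgb_label(map), label_path)
    truth_path <- NA_character_
    if (write_truth) {
      truth_path <- file.path(out_dir, paste0(stem, "_mus.tif"))
      write_image(map$mu_s_prime, truth_path, range = c(0, 4))
    }
    entries[[i]] <- list(input = basename(input_path),
                         label = basename(label_path),
                         truth = if (is.na(truth_path)) NULL else basename(truth_path),
                         mu_a = sweep$mu_a[i], mu_s_prime = sweep$mu_s_prime[i])
  }
  set.seed(seed)
  ord <- sample.int(n)
  n_train <- floor(train_fraction * n)
  split <- character(n)
  split[ord[seq_len(n_train)]] <- "train"
  split[ord[-seq_len(n_train)]] <- "validation"
  for (i in seq_len(n)) entries[[i]]$split <- split[i]
  manifest <- list(seed = seed, size = size, fx_ac = fx_ac,
                   noise_sd = noise_sd, pixel_size_mm = pixel_size,
                   n_total = n, n_train = n_train,
                   n_validation = n - n_train,
                   sweep = "grid over (mu_a, mu_s_prime) base values",
                   coordinates = "row-major, origin top-left, sinusoid along columns",
                   entries = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Default optical-coefficient sweep of the dataset generator
#'
#' 20 absorption levels spanning 0.01-0.45 mm^-1 crossed with 40 reduced
#' scattering levels spanning 0.2-3.9 mm^-1: 800 combinations covering the
#' design ranges of fruit-mimicking phantoms.
#'
#' @return Data frame with columns `mu_a`, `mu_s_prime`.
#' @export
default_sweep <- function() {
  expand.grid(mu_a = seq(0.01, 0.45, length.out = 20),
              mu_s_prime = seq(0.2, 3.9, length.out = 40))
}
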