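#' Phantom specification
#'
#' Geometry and optics of the synthetic imaging phantom: a turbid slab of
#' 1% intralipid with a blood-filled capillary inserted diagonally, so the
#' vessel depth varies continuously along the image. Intralipid defaults
#' are literature-typical for a 1% dilution: reduced scattering
#' 10 cm^-1 at 550 nm with 1/lambda scaling, absorption 0.02 cm^-1,
#' anisotropy 0.7, refractive index 1.33.
#'
#' @param medium_thickness slab thickness, mm.
#' @param vessel_diameter capillary inner diameter, mm.
#' @param depth_range vessel-top depth at the two image edges, mm (the
#'   diagonal insertion: depth ramps linearly along image columns).
#' @param blood a [blood_spec()] for the capillary contents.
#' @param mus_prime_550 reduced scattering of the medium at 550 nm, cm^-1.
#' @param mu_a_medium medium absorption, cm^-1.
#' @param g_medium,n_medium medium anisotropy and refractive index.
#' @param noise_sd multiplicative Gaussian noise sigma on detected counts.
#' @param read_noise additive Gaussian detector read noise, counts (the
#'   noise floor that ultimately limits detection of deep vessels).
#' @param source_counts reference (unattenuated) intensity, counts.
#' @param dark_counts dark offset, counts.
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(medium_thickness = 2, vessel_diameter = 0.5,
                         depth_range = c(0, 1.5), blood = blood_spec(0.98),
                         mus_prime_550 = 10, mu_a_medium = 0.02,
                         g_medium = 0.7, n_medium = 1.33,
                         noise_sd = 0.01, read_noise = 2,
                         source_counts = 1000, dark_counts = 20) {
  stopifnot(medium_thickness > 0, vessel_diameter >= 0, noise_sd >= 0,
            read_noise >= 0, all(depth_range >= 0),
            all(depth_range + vessel_diameter <= medium_thickness + 1e-9),
            inherits(blood, "blood_spec"))
  structure(list(medium_thickness = medium_thickness,
                 vessel_diameter = vessel_diameter,
                 depth_range = depth_range, blood = blood,
                 mus_prime_550 = mus_prime_550, mu_a_medium = mu_a_medium,
                 g_medium = g_medium, n_medium = n_medium,
                 noise_sd = noise_sd, read_noise = read_noise,
                 source_counts = source_counts,
                 dark_counts = dark_counts), class = "phantom_spec")
}

# effective attenuation coefficient of the medium at wavelength lambda
phantom_mu_eff <- function(spec, lambda) {
  musp <- spec$mus_prime_550 * 550 / lambda
  sqrt(3 * spec$mu_a_medium * (spec$mu_a_medium + musp))
}

# lateral blur of the vessel image by the scattering overburden: Gaussian
# sigma (mm) per mm of vessel depth. Reflective light crosses the turbid
# overburden twice and is strongly blurred; transmissive detection keeps
# near-single-vessel resolution (its collected light is quasi-ballistic),
# so its blur constant is small
blur_k <- c(reflective = 1.0, transmissive = 0.05)

# 1-D Gaussian blur along rows with edge replication
blur_column <- function(v, sigma_px) {
  if (sigma_px < 0.3) return(v)
  half <- max(1L, ceiling(3 * sigma_px))
  kern <- stats::dnorm(-half:half, sd = sigma_px)
  kern <- kern / sum(kern)
  padded <- c(rep(v[1], half), v, rep(v[length(v)], half))
  stats::convolve(padded, rev(kern), type = "filter")
}

#' Generate a synthetic hyperspectral phantom stack
#'
#' Forward-generates a (rows x cols x bands) stack with known ground truth.
#' Two fidelity levels:
#' * `"fast"`: the band-wise background transmission/reflectance of the
#'   turbid slab comes from a 1-D depth-integrated attenuation
#'   approximation (effective attenuation coefficient
#'   `sqrt(3 mu_a (mu_a + mu_s'))`), so a full stack generates in
#'   milliseconds;
#' * `"mc"`: the background level per band comes from a cached Monte Carlo
#'   sweep of the slab.
#'
#' In both cases vessel pixels are additionally attenuated by the modified
#' Beer-Lambert absorbance of the local cylinder chord. The scattering
#' overburden above the vessel blurs the detected image: each column of the
#' transmission image is convolved with a Gaussian whose width grows with
#' the local vessel depth (1.0 mm of blur per mm of depth in reflective
#' mode, where light crosses the overburden twice; 0.05 in transmissive
#' mode, which keeps near-single-vessel resolution as quasi-ballistic
#' transmitted light does). Together with the detector read noise this
#' reproduces
#' the swift loss of reflective vessel contrast with depth and the much
#' slower transmissive one. Reference and dark frames are emitted; detected
#' counts get multiplicative Gaussian noise plus read noise. Reproducible
#' per seed.
#'
#' @param spec a [phantom_spec()].
#' @param shape image shape `c(rows, cols)`.
#' @param grid wavelength grid, nm.
#' @param seed integer seed.
#' @param mode detection geometry.
#' @param fidelity `"fast"` or `"mc"`.
#' @param pixel_size mm/pixel.
#' @param photons photon packets per band for `"mc"` fidelity.
#' @return list with `stack` (a [spectral_stack()]) and `truth` (list:
#'   `so2` matrix, `vessel_mask`, `depth_mm` per pixel, `chord_mm`).
#' @export
generate_stack <- function(spec, shape = c(48, 96),
                           grid = wavelength_grid(), seed = 1,
                           mode = c("transmissive", "reflective"),
                           fidelity = c("fast", "mc"),
                           pixel_size = 0.05, photons = 2e4) {
  mode <- match.arg(mode)
  fidelity <- match.arg(fidelity)
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- shape[1]; nc <- shape[2]
  rad_mm <- spec$vessel_diameter / 2
  axis_row <- (nr - 1) / 2
  dy_mm <- (0:(nr - 1) - axis_row) * pixel_size
  if (all(abs(dy_mm) > rad_mm) && spec$vessel_diameter > 0)
    stop("vessel lies outside the field of view")
  depth_col <- seq(spec$depth_range[1], spec$depth_range[2],
                   length.out = nc)
  chord_mm <- ifelse(abs(dy_mm) <= rad_mm,
                     2 * sqrt(pmax(0, rad_mm^2 - dy_mm^2)), 0)
  vessel_mask <- matrix(chord_mm > 0, nr, nc)
  depth_mm <- matrix(depth_col, nr, nc, byrow = TRUE)
  chord_mat <- matrix(chord_mm, nr, nc)

  mu_eff <- phantom_mu_eff(spec, grid)
  d_cm <- spec$medium_thickness / 10
  if (fidelity == "fast") {
    bg_level <- if (mode == "transmissive") exp(-mu_eff * d_cm)
                else {
                  musp <- spec$mus_prime_550 * 550 / grid
                  musp / (musp + 8 * spec$mu_a_medium)  # diffuse albedo-like
                }
  } else {
    slab <- tissue_model(list(optical_layer(
      d_cm, spec$mu_a_medium,
      spec$mus_prime_550 * 550 / 550 / (1 - spec$g_medium),
      g = spec$g_medium, n = spec$n_medium)))
    sw <- spectral_sweep(slab, grid = grid, photons = photons, seed = seed,
                         tag = 99)
    bg_level <- if (mode == "transmissive") sw$transmitted_fraction
                else sw$reflected_fraction
  }

  # per-band absorbance of a unit (1 mm) chord through the vessel blood
  a_unit <- theoretical_absorbance(spec$blood, path_length = 0.1,
                                   offset = 0, grid = grid)
  nb <- length(grid)
  data <- array(0, c(nr, nc, nb))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sigma_px <- blur_k[[mode]] * depth_col / pixel_size
  for (b in seq_len(nb)) {
    a_vessel <- chord_mat * a_unit[b]
    tr <- bg_level[b] * 10^(-a_vessel)
    for (j in seq_len(nc))
      tr[, j] <- blur_column(tr[, j], sigma_px[j])
    counts <- spec$dark_counts + tr * (spec$source_counts - spec$dark_counts)
    if (spec$noise_sd > 0)
      counts <- spec$dark_counts + (counts - spec$dark_counts) *
        (1 + stats::rnorm(nr * nc, sd = spec$noise_sd))
    if (spec$read_noise > 0)
      counts <- counts + stats::rnorm(nr * nc, sd = spec$read_noise)
    data[, , b] <- pmax(matrix(counts, nr, nc), 0)
  }
  stack <- spectral_stack(data, grid,
                          reference = rep(spec$source_counts, nb),
                          dark = rep(spec$dark_counts, nb),
                          pixel_size = pixel_size, mode = mode)
  so2_truth <- matrix(NA_real_, nr, nc)
  so2_truth[vessel_mask] <- spec$blood$so2
  list(stack = stack,
       truth = list(so2 = so2_truth, vessel_mask = vessel_mask,
                    depth_mm = depth_mm, chord_mm = chord_mat))
}

#' Study design for the depth/sensitivity simulation studies
#'
#' @param depths_mm vessel depths, mm (>= 0).
#' @param presets SO2 presets, fractions in `[0.5, 1]`. The default ramp
#'   98, 90, ..., 50% is the sensitivity protocol; the pair (0.98, 0.75)
#'   covers the arterial/venous depth curves.
#' @param modes detection modes.
#' @param photons photon packets per band.
#' @param seed master seed.
#' @return An object of class `"study_design"`.
#' @export
study_design <- function(depths_mm = seq(0, 2, by = 0.25),
                         presets = c(0.98, 0.90, 0.80, 0.70, 0.60, 0.50),
                         modes = c("reflective", "transmissive"),
                         photons = 1e5, seed = 42) {
  stopifnot(all(depths_mm >= 0), all(presets >= 0.5 & presets <= 1),
            photons >= 1)
  modes <- match.arg(modes, several.ok = TRUE)
  structure(list(depths_mm = depths_mm, presets = presets, modes = modes,
                 photons = photons, seed = seed), class = "study_design")
}

#' Run the vessel-depth simulation study
#'
#' For every (depth, preset) cell: builds the layered skin model with the
#' vascular layer at that depth and saturation, runs paired Monte Carlo
#' detections against the matched background, forms the vascular absorbance
#' and unmixes it, for each requested detection mode. One background sweep
#' per depth is shared across presets (background optics do not depend on
#' the preset); every sample sweep runs on its own stream. With
#' `engine = "analytic"` the Monte Carlo transport is bypassed and the
#' noise-free modified Beer-Lambert forward spectrum is unmixed directly
#' (identity transport; useful as an exactness baseline).
#'
#' @param design a [study_design()].
#' @param model_args extra arguments passed to [skin_model()].
#' @param beam a [beam_spec()].
#' @param grid wavelength grid.
#' @param engine `"mc"` or `"analytic"`.
#' @return Tidy data.frame: depth_mm, mode, preset, so2_hat, pearson_r,
#'   accepted, reason, photons, seed. Failed cells are marked, never
#'   aborted.
#' @export
run_depth_study <- function(design, model_args = list(),
                            beam = beam_spec(), grid = wavelength_grid(),
                            engine = c("mc", "analytic")) {
  stopifnot(inherits(design, "study_design"))
  engine <- match.arg(engine)
  x <- design_matrix(grid)
  rows <- list()
  for (di in seq_along(design$depths_mm)) {
    depth_cm <- design$depths_mm[di] / 10
    if (engine == "mc") {
      bg <- background_model(do.call(skin_model, c(
        list(vessel_depth = depth_cm), model_args)))
      sw_b <- spectral_sweep(bg, beam, grid, design$photons, design$seed,
                             tag = 1000 + di)
    }
    for (pi in seq_along(design$presets)) {
      preset <- design$presets[pi]
      model <- do.call(skin_model, c(
        list(vessel_depth = depth_cm, so2 = preset), model_args))
      if (engine == "mc") {
        sw_s <- spectral_sweep(model, beam, grid, design$photons,
                               design$seed,
                               tag = di * 64 + pi)
      }
      for (mode in design$modes) {
        u <- tryCatch({
          if (engine == "analytic") {
            vt <- model$layers[[model$vascular_index]]$thickness
            a <- theoretical_absorbance(model$blood, path_length = vt,
                                        offset = 0, grid = grid)
            unmix(a, x)
          } else {
            col <- if (mode == "reflective") "reflected_fraction"
                   else "transmitted_fraction"
            a <- vessel_absorbance(sw_s[[col]], sw_b[[col]], grid)
            unmix(a, x)
          }
        }, error = function(e)
          structure(list(c = rep(NA_real_, 3), so2 = NA_real_,
                         pearson_r = NA_real_, accepted = FALSE,
                         reason = paste("failed:", conditionMessage(e)),
                         n_bands = 0L), class = "unmix_result"))
        rows[[length(rows) + 1]] <- data.frame(
          depth_mm = design$depths_mm[di], mode = mode, preset = preset,
          so2_hat = u$so2, pearson_r = u$pearson_r, accepted = u$accepted,
          reason = if (is.na(u$reason)) NA_character_ else u$reason,
          photons = design$photons, seed = design$seed)
      }
    }
  }
  do.call(rbind, rows)
}

#' Detection sensitivity and error-ratio analysis
#'
#' From a depth-study table over an SO2 preset ramp, computes per
#' (depth, mode): the least-squares slope of recovered-vs-preset SO2 (the
#' detection sensitivity) and the mean absolute error of the recovered
#' relative SO2 change against the true relative change, both referenced to
#' the highest preset as baseline. Also reports, per depth, the fold-ratio
#' of reflective-mode to transmissive-mode error. Cells without a defined
#' SO2 estimate are excluded and counted.
#'
#' @param study tidy table from [run_depth_study()] (needs >= 5 presets per
#'   cell group for a meaningful slope; fewer is allowed but flagged by
#'   `n_used`).
#' @return list with `sensitivity` (depth_mm, mode, slope, mae, n_used,
#'   n_rejected) and `error_ratio` (depth_mm, reflective-over-transmissive
#'   fold-ratio of the mean absolute errors).
#' @export
sensitivity_analysis <- function(study) {
  stopifnot(all(c("depth_mm", "mode", "preset", "so2_hat") %in%
                  names(study)))
  baseline <- max(study$preset)
  groups <- unique(study[c("depth_mm", "mode")])
  sens <- do.call(rbind, lapply(seq_len(nrow(groups)), function(k) {
    g <- study[study$depth_mm == groups$depth_mm[k] &
                 study$mode == groups$mode[k], ]
    ok <- is.finite(g$so2_hat)
    base_hat <- g$so2_hat[ok & g$preset == baseline]
    slope <- NA_real_; mae <- NA_real_
    if (sum(ok) >= 2)
      slope <- stats::coef(stats::lm(so2_hat ~ preset, data = g[ok, ]))[2]
    if (length(base_hat) == 1 && is.finite(base_hat) && base_hat > 0) {
      sub <- g[ok & g$preset != baseline, ]
      if (nrow(sub) > 0) {
        rec_rel <- (sub$so2_hat - base_hat) / base_hat
        true_rel <- (sub$preset - baseline) / baseline
        mae <- mean(abs(rec_rel - true_rel))
      }
    }
    data.frame(depth_mm = groups$depth_mm[k], mode = groups$mode[k],
               slope = unname(slope), mae = mae, n_used = sum(ok),
               n_rejected = sum(!ok))
  }))
  depths <- unique(sens$depth_mm)
  ratio <- do.call(rbind, lapply(depths, function(d) {
    r <- sens$mae[sens$depth_mm == d & sens$mode == "reflective"]
    t <- sens$mae[sens$depth_mm == d & sens$mode == "transmissive"]
    data.frame(depth_mm = d,
               error_ratio = if (length(r) == 1 && length(t) == 1 &&
                                 is.finite(r) && is.finite(t) && t > 0)
                 r / t else NA_real_)
  }))
  list(sensitivity = sens, error_ratio = ratio)
}
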