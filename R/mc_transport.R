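#' Optical layer
#'
#' One homogeneous layer of a layered tissue model. All lengths are in cm,
#' absorption and scattering coefficients in cm^-1.
#'
#' @param thickness layer thickness, cm; `Inf` allowed for the last layer
#'   (reflective detection only).
#' @param mu_a absorption coefficient, cm^-1 (>= 0).
#' @param mu_s scattering coefficient, cm^-1 (>= 0).
#' @param g Henyey-Greenstein anisotropy factor, in (-1, 1).
#' @param n refractive index (>= 1).
#' @return An object of class `"optical_layer"`.
#' @export
optical_layer <- function(thickness, mu_a, mu_s, g = 0.9, n = 1.4) {
  stopifnot(thickness > 0, mu_a >= 0, mu_s >= 0, g > -1, g < 1, n >= 1)
  structure(list(thickness = thickness, mu_a = mu_a, mu_s = mu_s,
                 g = g, n = n), class = "optical_layer")
}

#' Layered tissue model
#'
#' Ordered stack of [optical_layer()]s, top (illuminated) surface first.
#' One layer may be designated as the vascular layer: during spectral
#' sweeps its absorption coefficient is set per band from the blood forward
#' model ([blood_mu_a()]); its stored `mu_a` is the host-tissue absorption
#' used by the matched background model. The z axis points downward with
#' z = 0 at the illuminated surface.
#'
#' @param layers list of [optical_layer()]s, top to bottom.
#' @param vascular_index integer index of the vascular layer, or `NULL`.
#' @param blood a [blood_spec()] for the vascular layer (ignored when
#'   `vascular_index` is `NULL`).
#' @param ambient_n refractive index of the medium above and below.
#' @return An object of class `"tissue_model"`.
#' @seealso [skin_model()], [background_model()], [vessel_depth()]
#' @export
tissue_model <- function(layers, vascular_index = NULL, blood = NULL,
                         ambient_n = 1.0) {
  stopifnot(length(layers) >= 1,
            all(vapply(layers, inherits, TRUE, "optical_layer")))
  thick <- vapply(layers, `[[`, 0, "thickness")
  if (any(!is.finite(thick[-length(thick)])))
    stop("only the last layer may have infinite thickness")
  if (!is.null(vascular_index)) {
    stopifnot(vascular_index >= 1, vascular_index <= length(layers))
    if (is.null(blood))
      stop("a vascular layer requires a blood_spec")
    stopifnot(inherits(blood, "blood_spec"))
  }
  structure(list(layers = layers, vascular_index = vascular_index,
                 blood = blood, ambient_n = ambient_n),
            class = "tissue_model")
}

#' @export
print.tissue_model <- function(x, ...) {
  cat(sprintf("<tissue_model> %d layers, total %.3g cm\n",
              length(x$layers), sum(vapply(x$layers, `[[`, 0, "thickness"))))
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    tag <- if (!is.null(x$vascular_index) && i == x$vascular_index)
      " [vascular]" else ""
    cat(sprintf("  %d: d=%.4g mu_a=%.4g mu_s=%.4g g=%.2f n=%.2f%s\n",
                i, l$thickness, l$mu_a, l$mu_s, l$g, l$n, tag))
  }
  invisible(x)
}

#' Depth of the vascular layer
#'
#' Distance (cm) from the illuminated surface to the top of the vascular
#' layer.
#' @param model a [tissue_model()] with a vascular layer.
#' @return depth in cm.
#' @export
vessel_depth <- function(model) {
  stopifnot(inherits(model, "tissue_model"), !is.null(model$vascular_index))
  i <- model$vascular_index
  if (i == 1) 0 else
    sum(vapply(model$layers[seq_len(i - 1)], `[[`, 0, "thickness"))
}

#' Matched background model
#'
#' The identical layer stack with the vascular layer's blood absorption
#' replaced by its host-tissue absorption (the layer's stored `mu_a`);
#' geometry, scattering and refractive indices are unchanged. Used to ratio
#' out source and bulk-tissue terms when forming the vascular absorbance.
#'
#' @param model a [tissue_model()].
#' @return A [tissue_model()] without blood.
#' @export
background_model <- function(model) {
  stopifnot(inherits(model, "tissue_model"))
  model$blood <- NULL
  model$vascular_index <- NULL
  model
}

#' Default layered skin model with an embedded vascular layer
#'
#' Literature-typical skin optics: a 0.01 cm epidermis (mu_a 1.0, mu_s 150,
#' g 0.8, n 1.4) over dermis (mu_a 0.3, mu_s 120, g 0.9, n 1.4) containing a
#' 0.05 cm vascular layer whose absorption follows the blood forward model.
#' The vascular layer is modelled as a blood-rich plexus: its effective
#' hemoglobin concentration is `blood_fraction` times whole blood, which
#' puts the peak vascular absorbance near 1 OD. The epidermis (and upper
#' dermis) shrink as `vessel_depth` approaches 0 so the vascular layer can
#' sit at the surface.
#'
#' @param vessel_depth depth of the vascular layer top below the surface, cm.
#' @param so2 preset oxygen saturation of the vascular blood.
#' @param total_thickness total slab thickness, cm.
#' @param vascular_thickness thickness of the vascular layer, cm.
#' @param blood_fraction blood volume fraction of the vascular layer.
#' @param whole_blood_hb whole-blood hemoglobin concentration, mol/L.
#' @return A [tissue_model()].
#' @examples
#' skin_model(vessel_depth = 0.1, so2 = 0.98)  # vessel 1 mm deep
#' @export
skin_model <- function(vessel_depth = 0.1, so2 = 0.98,
                       total_thickness = 0.3, vascular_thickness = 0.05,
                       blood_fraction = 0.2, whole_blood_hb = 150 / 64500) {
  stopifnot(vessel_depth >= 0,
            vessel_depth + vascular_thickness < total_thickness)
  epi_d <- min(0.01, vessel_depth)
  upper_d <- vessel_depth - epi_d
  lower_d <- total_thickness - vessel_depth - vascular_thickness
  layers <- list()
  if (epi_d > 0)
    layers <- c(layers, list(optical_layer(epi_d, 1.0, 150, g = 0.8)))
  if (upper_d > 1e-9)
    layers <- c(layers, list(optical_layer(upper_d, 0.3, 120, g = 0.9)))
  vi <- length(layers) + 1L
  layers <- c(layers, list(optical_layer(vascular_thickness, 0.3, 120,
                                         g = 0.9)))
  layers <- c(layers, list(optical_layer(lower_d, 0.3, 120, g = 0.9)))
  tissue_model(layers, vascular_index = vi,
               blood = blood_spec(so2, total_hb = blood_fraction *
                                    whole_blood_hb))
}

#' Illumination beam
#'
#' Flat (top-hat) beam at normal incidence. Defaults follow the simulation
#' protocol: 4 cm diameter, 0.1 J per band.
#'
#' @param diameter beam diameter, cm.
#' @param energy pulse energy, J (bookkeeping only; tallies are fractions).
#' @return An object of class `"beam_spec"`.
#' @export
beam_spec <- function(diameter = 4, energy = 0.1) {
  stopifnot(diameter > 0, energy > 0)
  structure(list(diameter = diameter, energy = energy, profile = "flat"),
            class = "beam_spec")
}

# per-band layer parameter matrix; vascular mu_a from the blood model
layer_matrix <- function(model, wavelength = NULL,
                         table = hemoglobin_extinction()) {
  m <- t(vapply(model$layers, function(l)
    c(l$thickness, l$mu_a, l$mu_s, l$g, l$n), numeric(5)))
  colnames(m) <- c("thickness", "mu_a", "mu_s", "g", "n")
  if (!is.null(model$vascular_index) && !is.null(model$blood)) {
    if (is.null(wavelength))
      stop("a wavelength is required to evaluate the vascular layer")
    m[model$vascular_index, "mu_a"] <-
      blood_mu_a(model$blood, wavelength, table)
  }
  m
}

#' Monte Carlo simulation of one band
#'
#' Transports `photons` photon packets through the layered model and tallies
#' diffuse reflected and transmitted weight. Deterministic given
#' `(seed, stream, photons)`. Weight is conserved exactly:
#' `specular + reflected_total + transmitted_total + absorbed = 1` to
#' floating-point rounding; with a finite detection aperture the
#' within-aperture fractions `reflected_fraction`/`transmitted_fraction`
#' exclude the (small) `lost_fraction` exiting beyond the aperture.
#'
#' @param model a [tissue_model()].
#' @param wavelength band center, nm (needed when the model has a vascular
#'   layer; the layer's absorption is then taken from [blood_mu_a()]).
#' @param beam a [beam_spec()].
#' @param photons number of photon packets (>= 1).
#' @param seed master seed (integer).
#' @param stream stream id; runs with distinct `(seed, stream)` pairs use
#'   decorrelated random streams.
#' @param detection_radius co-axial detection aperture radius, cm; default
#'   is the beam radius; use `Inf` to tally every exiting photon.
#' @param radial_bins,radial_bin_width optional radial tally diagnostic:
#'   number of annular bins and their width (cm); the last bin collects
#'   overflow. Set `radial_bins = 0` to skip.
#' @param table extinction table.
#' @return A `"detection_record"`: list with the tallied fractions, their
#'   Monte Carlo standard errors, `wavelength`, `photons`, `seed`, `stream`
#'   and (if requested) a data.frame `radial` of annular exit weights.
#' @export
mc_simulate <- function(model, wavelength = NULL, beam = beam_spec(),
                        photons = 1e4, seed = 1, stream = 0,
                        detection_radius = NULL, radial_bins = 0,
                        radial_bin_width = 0.05,
                        table = hemoglobin_extinction()) {
  stopifnot(inherits(model, "tissue_model"), inherits(beam, "beam_spec"),
            photons >= 1)
  lm <- layer_matrix(model, wavelength, table)
  if (is.null(detection_radius)) detection_radius <- beam$diameter / 2
  res <- mc_run_cpp(lm, model$ambient_n, model$ambient_n,
                    beam$diameter / 2, detection_radius, photons,
                    seed, stream, as.integer(radial_bins), radial_bin_width)
  rec <- c(list(wavelength = if (is.null(wavelength)) NA_real_ else wavelength),
           res[c("reflected_fraction", "transmitted_fraction",
                 "absorbed_fraction", "specular_fraction",
                 "reflected_total", "transmitted_total", "lost_fraction",
                 "se_reflected", "se_transmitted",
                 "se_reflected_total", "se_transmitted_total")],
           list(photons = photons, seed = seed, stream = stream))
  if (radial_bins > 0) {
    edges <- seq(0, by = radial_bin_width, length.out = radial_bins + 1)
    rec$radial <- data.frame(
      r_inner = edges[-length(edges)], r_outer = edges[-1],
      reflected = res$radial_reflected / photons,
      transmitted = res$radial_transmitted / photons)
  }
  structure(rec, class = "detection_record")
}

#' @export
print.detection_record <- function(x, ...) {
  cat(sprintf(paste0("<detection_record> lambda=%s nm  R=%.5f  T=%.5f  ",
                     "A=%.5f  Rsp=%.5f (%g photons)\n"),
              format(x$wavelength), x$reflected_fraction,
              x$transmitted_fraction, x$absorbed_fraction,
              x$specular_fraction, x$photons))
  invisible(x)
}

# stream id for (model tag, band index); tags keep sample/background and
# repeated sweeps on decorrelated streams
band_stream <- function(tag, band) tag * 4096 + band

#' Spectral sweep of the Monte Carlo simulation
#'
#' Runs [mc_simulate()] once per band of `grid`. Only the vascular layer's
#' absorption varies with wavelength (via [blood_mu_a()]); every other
#' layer parameter is wavelength independent. Each band uses a stream
#' derived from `(seed, tag, band index)`, so a repeated sweep with the same
#' master seed is bitwise identical.
#'
#' @inheritParams mc_simulate
#' @param grid wavelength grid, nm.
#' @param tag integer model tag entering the per-band stream derivation
#'   (use distinct tags for sample and background sweeps).
#' @return A data.frame with one row per band in grid order: wavelength_nm,
#'   the tallied fractions, standard errors, photons, seed, stream.
#' @export
spectral_sweep <- function(model, beam = beam_spec(),
                           grid = wavelength_grid(), photons = 1e4,
                           seed = 1, tag = 0, detection_radius = NULL,
                           table = hemoglobin_extinction()) {
  validate_grid(grid)
  rows <- lapply(seq_along(grid), function(b) {
    r <- mc_simulate(model, wavelength = grid[b], beam = beam,
                     photons = photons, seed = seed,
                     stream = band_stream(tag, b),
                     detection_radius = detection_radius, table = table)
    data.frame(wavelength_nm = grid[b],
               reflected_fraction = r$reflected_fraction,
               transmitted_fraction = r$transmitted_fraction,
               absorbed_fraction = r$absorbed_fraction,
               specular_fraction = r$specular_fraction,
               lost_fraction = r$lost_fraction,
               se_reflected = r$se_reflected,
               se_transmitted = r$se_transmitted,
               photons = photons, seed = seed, stream = r$stream)
  })
  do.call(rbind, rows)
}

geometry_signature <- function(model) {
  m <- t(vapply(model$layers, function(l)
    c(l$thickness, l$mu_s, l$g, l$n), numeric(4)))
  list(m = m, ambient = model$ambient_n)
}

#' Paired sample/background detection
#'
#' Runs spectral sweeps of the sample model (with the vascular layer) and
#' its matched background model (blood absorption replaced by host
#' absorption, same geometry) and returns, for both detection modes, the
#' per-band detected fractions that feed [vessel_absorbance()]. Background
#' bands run on independent streams.
#'
#' @param sample_model a [tissue_model()] with a vascular layer.
#' @param bg_model matched background model; default
#'   `background_model(sample_model)`.
#' @inheritParams spectral_sweep
#' @param modes detection modes to report.
#' @return A data.frame with columns wavelength_nm, mode, sample_fraction,
#'   background_fraction, photons, seed (rows: bands x modes).
#' @export
paired_detection <- function(sample_model, bg_model = NULL,
                             beam = beam_spec(), grid = wavelength_grid(),
                             photons = 1e4, seed = 1,
                             modes = c("reflective", "transmissive"),
                             table = hemoglobin_extinction()) {
  stopifnot(inherits(sample_model, "tissue_model"))
  if (is.null(bg_model)) bg_model <- background_model(sample_model)
  gs <- geometry_signature(sample_model); gb <- geometry_signature(bg_model)
  if (!isTRUE(all.equal(gs, gb)))
    stop("sample and background models must share geometry, scattering and ",
         "refractive indices")
  modes <- match.arg(modes, several.ok = TRUE)
  if ("transmissive" %in% modes) {
    thick <- vapply(sample_model$layers, `[[`, 0, "thickness")
    if (!all(is.finite(thick)))
      stop("transmissive detection requires a finite total thickness")
  }
  sw_s <- spectral_sweep(sample_model, beam, grid, photons, seed, tag = 0,
                         table = table)
  sw_b <- spectral_sweep(bg_model, beam, grid, photons, seed, tag = 1,
                         table = table)
  out <- lapply(modes, function(mode) {
    col <- if (mode == "reflective") "reflected_fraction"
           else "transmitted_fraction"
    data.frame(wavelength_nm = grid, mode = mode,
               sample_fraction = sw_s[[col]],
               background_fraction = sw_b[[col]],
               photons = photons, seed = seed)
  })
  do.call(rbind, out)
}
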