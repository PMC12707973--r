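#' @useDynLib oxyhsi, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.oxyhsi_env <- new.env(parent = emptyenv())

#' Default wavelength grid for hyperspectral oximetry
#'
#' The visible band from 500 to 720 nm split into 23 narrow bands at a 10 nm
#' interval. Each band (7 nm FWHM on the instrument) is treated as a delta
#' function at its center wavelength; all computations are monochromatic at
#' the band centers.
#'
#' @param from,to,by band-center range and spacing in nm.
#' @return Strictly increasing numeric vector of band centers (nm); the
#'   default grid has length 23.
#' @examples
#' wavelength_grid()          # 500, 510, ..., 720
#' length(wavelength_grid())  # 23
#' @export
wavelength_grid <- function(from = 500, to = 720, by = 10) {
  grid <- seq(from, to, by = by)
  validate_grid(grid)
  grid
}

validate_grid <- function(grid) {
  if (length(grid) < 2 || any(diff(grid) <= 0))
    stop("wavelength grid must be strictly increasing with >= 2 bands")
  invisible(grid)
}

#' Hemoglobin molar extinction table
#'
#' Loads the vendored extinction table: decadic molar extinction coefficients
#' (cm^-1 M^-1) of oxy- and deoxyhemoglobin on a 1 nm grid covering
#' 450--1000 nm. The table is a synthetic parametric reconstruction (see
#' `data-raw/make_extinction_table.R` in the package sources): a log-space
#' spline through canonical landmark values reproducing the oxyhemoglobin
#' Q-band doublet (peaks near 542 and 577 nm, valley near 560 nm), the
#' deoxyhemoglobin peak near 555 nm, the classical isosbestic
#' neighbourhoods and the near-infrared crossover. It is not a published
#' compilation; absolute magnitudes are approximate. Because the same table
#' drives the forward model and the unmixing design matrix, saturation
#' estimates are self-consistent.
#'
#' @return A data.frame with columns `wavelength_nm`, `eps_oxy`, `eps_deoxy`.
#'   The table carries attributes `version` and `provenance`.
#' @export
hemoglobin_extinction <- function() {
  tab <- .oxyhsi_env$extinction
  if (is.null(tab)) {
    path <- system.file("extdata", "hemoglobin_extinction_synthetic.csv",
                        package = "oxyhsi", mustWork = TRUE)
    tab <- utils::read.csv(path, comment.char = "#")
    attr(tab, "version") <- "1"
    attr(tab, "provenance") <-
      "synthetic log-spline reconstruction of canonical hemoglobin landmarks"
    .oxyhsi_env$extinction <- tab
  }
  tab
}

#' Interpolate extinction coefficients at arbitrary wavelengths
#'
#' Linear interpolation within the table's support; wavelengths outside the
#' support are an error (the offending wavelength is named).
#'
#' @param wavelength numeric vector, nm.
#' @param table extinction table as from [hemoglobin_extinction()].
#' @return A list with numeric vectors `eps_oxy` and `eps_deoxy` (decadic,
#'   cm^-1 M^-1), same length as `wavelength`.
#' @export
extinction_at <- function(wavelength, table = hemoglobin_extinction()) {
  lo <- min(table$wavelength_nm); hi <- max(table$wavelength_nm)
  bad <- wavelength < lo | wavelength > hi
  if (any(bad))
    stop(sprintf("wavelength %g nm outside extinction table support [%g, %g]",
                 wavelength[which(bad)[1]], lo, hi))
  list(
    eps_oxy = stats::approx(table$wavelength_nm, table$eps_oxy, wavelength)$y,
    eps_deoxy = stats::approx(table$wavelength_nm, table$eps_deoxy, wavelength)$y
  )
}

#' Blood specification
#'
#' Total hemoglobin concentration and preset oxygen saturation of a blood
#' compartment. The default concentration is whole blood: 150 g/L hemoglobin
#' divided by 64,500 g/mol, about 2.326e-3 mol/L. For a perfused tissue
#' layer rather than whole blood, scale `total_hb` by the blood volume
#' fraction of the layer.
#'
#' @param so2 oxygen saturation preset, fraction in `[0, 1]`.
#' @param total_hb total hemoglobin concentration, mol/L.
#' @return An object of class `"blood_spec"`.
#' @examples
#' arterial <- blood_spec(so2 = 0.98)
#' venous   <- blood_spec(so2 = 0.75)
#' @export
blood_spec <- function(so2, total_hb = 150 / 64500) {
  stopifnot(is.numeric(so2), length(so2) == 1, so2 >= 0, so2 <= 1,
            is.numeric(total_hb), length(total_hb) == 1, total_hb > 0)
  structure(list(total_hb = total_hb, so2 = so2), class = "blood_spec")
}

#' @export
print.blood_spec <- function(x, ...) {
  cat(sprintf("<blood_spec> total Hb %.4g mol/L, SO2 %.1f%%\n",
              x$total_hb, 100 * x$so2))
  invisible(x)
}

#' Blood absorption coefficient spectrum
#'
#' Absorption coefficient of a blood compartment,
#' `mu_a(lambda) = ln(10) * B * [eps_oxy(lambda) * SO2 +
#' eps_deoxy(lambda) * (1 - SO2)]` in cm^-1. The `ln(10)` factor converts
#' the decadic extinction coefficients of the table to a natural-log
#' (transport) absorption coefficient.
#'
#' @param blood a [blood_spec()].
#' @param grid wavelength grid, nm (default [wavelength_grid()]).
#' @param table extinction table.
#' @return Numeric vector of absorption coefficients (cm^-1), one per band,
#'   all strictly positive.
#' @export
blood_mu_a <- function(blood, grid = wavelength_grid(),
                       table = hemoglobin_extinction()) {
  stopifnot(inherits(blood, "blood_spec"))
  eps <- extinction_at(grid, table)
  log(10) * blood$total_hb *
    (eps$eps_oxy * blood$so2 + eps$eps_deoxy * (1 - blood$so2))
}

#' Noise-free vascular absorbance under the modified Beer-Lambert law
#'
#' Decadic absorbance of a blood compartment of effective optical path
#' `path_length` plus a wavelength-flat offset that absorbs all
#' non-hemoglobin losses:
#' `A(lambda) = B * [eps_oxy * SO2 + eps_deoxy * (1 - SO2)] * L + xi`.
#' This is the forward model inverted by the unmixing module and, at
#' arterial saturation, shows the characteristic double-peaked "M-shape"
#' between roughly 520 and 600 nm.
#'
#' @param blood a [blood_spec()].
#' @param path_length effective optical path L, cm (>= 0).
#' @param offset wavelength-flat absorbance offset xi (>= 0).
#' @param grid,table as in [blood_mu_a()].
#' @return Numeric absorbance vector (base-10), one value per band.
#' @examples
#' A <- theoretical_absorbance(blood_spec(0.98), path_length = 0.05,
#'                             offset = 0.1)
#' @export
theoretical_absorbance <- function(blood, path_length, offset = 0,
                                   grid = wavelength_grid(),
                                   table = hemoglobin_extinction()) {
  stopifnot(path_length >= 0, offset >= 0)
  eps <- extinction_at(grid, table)
  blood$total_hb * (eps$eps_oxy * blood$so2 +
                    eps$eps_deoxy * (1 - blood$so2)) * path_length + offset
}
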