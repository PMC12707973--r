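#' Write a spectral stack as multi-page TIFF plus YAML sidecar
#'
#' Pages are ordered by ascending wavelength and stored as 32-bit float.
#' Writes `<prefix>.tif` (data), `<prefix>_reference.tif`,
#' `<prefix>_dark.tif` and `<prefix>.yaml` (wavelengths, pixel size, mode).
#'
#' @param stack a [spectral_stack()].
#' @param prefix output path prefix.
#' @return The sidecar path, invisibly.
#' @export
write_spectral_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "spectral_stack"))
  d <- dim(stack$data)
  # TIFF samples live in [0, 1]; intensities are stored divided by a
  # common scale recorded in the sidecar
  scale <- max(stack$data, stack$reference, stack$dark, 1)
  pages <- lapply(seq_len(d[3]), function(b) stack$data[, , b] / scale)
  tiff::writeTIFF(pages, paste0(prefix, ".tif"), bits.per.sample = 32)
  ref <- lapply(seq_len(d[3]), function(b)
    band_plane(stack$reference, b, d) / scale)
  tiff::writeTIFF(ref, paste0(prefix, "_reference.tif"),
                  bits.per.sample = 32)
  drk <- lapply(seq_len(d[3]), function(b)
    band_plane(stack$dark, b, d) / scale)
  tiff::writeTIFF(drk, paste0(prefix, "_dark.tif"), bits.per.sample = 32)
  side <- paste0(prefix, ".yaml")
  yaml::write_yaml(list(wavelengths_nm = stack$wavelengths,
                        pixel_size_mm = stack$pixel_size,
                        mode = stack$mode,
                        intensity_scale = scale), side)
  invisible(side)
}

read_pages <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (b in seq_along(pages)) {
    p <- pages[[b]]
    if (length(dim(p)) == 3) p <- p[, , 1]
    arr[, , b] <- p
  }
  arr
}

#' Read a spectral stack written by [write_spectral_stack()]
#'
#' @param prefix path prefix used when writing.
#' @return A [spectral_stack()].
#' @export
read_spectral_stack <- function(prefix) {
  side <- paste0(prefix, ".yaml")
  if (!file.exists(side)) stop("sidecar not found: ", side)
  meta <- yaml::read_yaml(side)
  scale <- meta$intensity_scale %||% 1
  data <- read_pages(paste0(prefix, ".tif")) * scale
  ref <- read_pages(paste0(prefix, "_reference.tif")) * scale
  drk <- read_pages(paste0(prefix, "_dark.tif")) * scale
  spectral_stack(data, meta$wavelengths_nm, reference = ref, dark = drk,
                 pixel_size = meta$pixel_size_mm, mode = meta$mode)
}

#' Write an SO2 map as float TIFF plus acceptance mask and CSV summary
#'
#' Writes `<prefix>_so2.tif` (32-bit float; rejected pixels 0),
#' `<prefix>_accepted.tif` (mask) and `<prefix>_summary.csv`.
#'
#' @param map an `"so2_map"` from [map_so2()].
#' @param prefix output path prefix.
#' @return The summary path, invisibly.
#' @export
write_so2_map <- function(map, prefix) {
  so2 <- map$so2
  so2[!map$accepted | is.na(so2)] <- 0
  tiff::writeTIFF(so2, paste0(prefix, "_so2.tif"), bits.per.sample = 32)
  tiff::writeTIFF(map$accepted * 1, paste0(prefix, "_accepted.tif"),
                  bits.per.sample = 8)
  summ <- data.frame(
    n_pixels = length(map$accepted),
    n_accepted = sum(map$accepted),
    median_so2 = if (any(map$accepted))
      stats::median(so2[map$accepted]) else NA_real_)
  path <- paste0(prefix, "_summary.csv")
  utils::write.csv(summ, path, row.names = FALSE)
  invisible(path)
}

#' Read a layered tissue model from a YAML configuration
#'
#' Expected keys: `layers` (list of maps with `thickness`, `mu_a`, `mu_s`,
#' `g`, `n`), optional `vascular_index`, `blood` (`so2`, optional
#' `total_hb`), `ambient_n`.
#'
#' @param path YAML file path.
#' @return A [tissue_model()].
#' @export
read_tissue_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  cfg <- yaml::read_yaml(path)
  layers <- lapply(cfg$layers, function(l)
    optical_layer(l$thickness, l$mu_a, l$mu_s,
                  g = l$g %||% 0.9, n = l$n %||% 1.4))
  blood <- NULL
  if (!is.null(cfg$blood))
    blood <- blood_spec(cfg$blood$so2,
                        total_hb = cfg$blood$total_hb %||% (150 / 64500))
  tissue_model(layers, vascular_index = cfg$vascular_index, blood = blood,
               ambient_n = cfg$ambient_n %||% 1.0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
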