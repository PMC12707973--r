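#' Hyperspectral image stack
#'
#' A (rows x cols x bands) intensity cube with its reference (flat-field)
#' and dark frames. Reference and dark may be scalars, per-band vectors, or
#' full cubes; they are broadcast per band as needed.
#'
#' @param data numeric array, rows x cols x bands, intensities >= 0.
#' @param wavelengths band-center wavelengths, nm, one per band, ascending.
#' @param reference reference intensities: length-`bands` vector or an array
#'   shaped like `data`.
#' @param dark dark (noise floor) intensities: scalar, length-`bands`
#'   vector, or array shaped like `data`.
#' @param pixel_size pixel pitch, mm/pixel.
#' @param mode detection geometry, `"reflective"` or `"transmissive"`.
#' @return An object of class `"spectral_stack"`.
#' @export
spectral_stack <- function(data, wavelengths, reference, dark = 0,
                           pixel_size = 0.01,
                           mode = c("transmissive", "reflective")) {
  mode <- match.arg(mode)
  stopifnot(is.array(data), length(dim(data)) == 3,
            dim(data)[3] == length(wavelengths),
            all(diff(wavelengths) > 0), min(data) >= 0, pixel_size > 0)
  if (is.array(reference) && length(dim(reference)) == 3) {
    stopifnot(all(dim(reference) == dim(data)))
  } else {
    stopifnot(length(reference) == length(wavelengths))
  }
  if (is.array(dark) && length(dim(dark)) == 3) {
    stopifnot(all(dim(dark) == dim(data)))
  } else if (length(dark) == 1) {
    dark <- rep(dark, length(wavelengths))
  } else {
    stopifnot(length(dark) == length(wavelengths))
  }
  structure(list(data = data, wavelengths = wavelengths,
                 reference = reference, dark = dark,
                 pixel_size = pixel_size, mode = mode),
            class = "spectral_stack")
}

#' @export
print.spectral_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spectral_stack> %d x %d pixels, %d bands (%g-%g nm), %s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              x$mode))
  invisible(x)
}

band_plane <- function(frames, b, dims) {
  if (is.array(frames) && length(dim(frames)) == 3) frames[, , b]
  else matrix(frames[b], dims[1], dims[2])
}

#' Reference- and dark-corrected intensity
#'
#' `(I - I_dark) / (I_ref - I_dark)` per pixel and band: normalizes out the
#' source spectrum and the detector noise floor. An error naming the band is
#' raised when the reference does not exceed the dark level.
#'
#' @param stack a [spectral_stack()].
#' @return rows x cols x bands array of corrected intensities.
#' @export
corrected_intensity <- function(stack) {
  stopifnot(inherits(stack, "spectral_stack"))
  d <- dim(stack$data)
  out <- array(NA_real_, d)
  for (b in seq_len(d[3])) {
    ref <- band_plane(stack$reference, b, d)
    drk <- band_plane(stack$dark, b, d)
    denom <- ref - drk
    if (any(denom <= 0))
      stop(sprintf(
        "calibration error at band %g nm: reference does not exceed dark",
        stack$wavelengths[b]))
    out[, , b] <- (stack$data[, , b] - drk) / denom
  }
  out
}

#' Background spectrum from an avascular region
#'
#' Per-band median of the corrected intensity over a user-designated
#' avascular region of interest; the median is robust to stray vessels
#' inside the ROI.
#'
#' @param stack a [spectral_stack()].
#' @param roi logical matrix (rows x cols), `TRUE` inside the avascular
#'   region.
#' @return numeric vector, one corrected background intensity per band.
#' @export
background_spectrum <- function(stack, roi) {
  stopifnot(is.matrix(roi), all(dim(roi) == dim(stack$data)[1:2]))
  if (!any(roi)) stop("background ROI is empty")
  ci <- corrected_intensity(stack)
  vapply(seq_len(dim(ci)[3]),
         function(b) stats::median(ci[, , b][roi]), 0)
}

#' Background-referenced intensity ratio
#'
#' Per-pixel, per-band ratio of corrected sample intensity to corrected
#' background intensity,
#' `[(I - I_dark)/(I_ref - I_dark)] / [(I_bg - I_dark)/(I_ref - I_dark)]`.
#' Its negative base-10 logarithm is the vascular absorbance.
#'
#' @param stack a [spectral_stack()].
#' @param background per-band background spectrum (corrected intensities),
#'   e.g. from [background_spectrum()].
#' @return rows x cols x bands array of ratios.
#' @export
corrected_ratio <- function(stack, background) {
  ci <- corrected_intensity(stack)
  d <- dim(ci)
  stopifnot(length(background) == d[3])
  if (any(!is.finite(background) | background <= 0))
    stop("background spectrum must be positive and finite in every band")
  sweep(ci, 3, background, "/")
}

#' Per-pixel oxygen saturation map
#'
#' Chains the full pipeline per pixel: reference/dark correction,
#' background ratio, vascular absorbance, non-negative least-squares
#' unmixing with the Pearson acceptance gate. Pixels are processed
#' independently; per-pixel failures become reject reasons, never an abort.
#'
#' @param stack a [spectral_stack()].
#' @param background_roi logical matrix marking an avascular region used to
#'   form the background spectrum (ignored when `background` is given).
#' @param background optional per-band background spectrum overriding the
#'   ROI.
#' @param r_min,min_bands acceptance parameters passed to [unmix()].
#' @param min_ratio detectability floor: bands whose background-referenced
#'   ratio falls below this value sit at the detector noise floor (the
#'   vessel is optically opaque there) and are flagged non-detectable for
#'   that pixel instead of contributing a noise-limited absorbance. The
#'   default corresponds to about 1.7 OD of usable dynamic range (a
#'   1000-count camera with a few counts of read noise).
#' @return An object of class `"so2_map"`: list with matrices `so2`
#'   (`NA` where undefined), `accepted`, `pearson`, `reason` (character,
#'   `NA` where accepted), plus `pixel_size` and `wavelengths`.
#' @export
map_so2 <- function(stack, background_roi = NULL, background = NULL,
                    r_min = 0.9, min_bands = 10, min_ratio = 0.02) {
  stopifnot(inherits(stack, "spectral_stack"))
  if (is.null(background)) {
    if (is.null(background_roi))
      stop("either a background ROI or a background spectrum is required")
    background <- background_spectrum(stack, background_roi)
  }
  ratio <- corrected_ratio(stack, background)
  d <- dim(ratio)
  x <- design_matrix(stack$wavelengths)
  so2 <- matrix(NA_real_, d[1], d[2])
  acc <- matrix(FALSE, d[1], d[2])
  pr <- matrix(NA_real_, d[1], d[2])
  reason <- matrix(NA_character_, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      rat <- ratio[i, j, ]
      a <- vessel_absorbance(rat, rep(1, d[3]), grid = stack$wavelengths)
      a$detectable <- a$detectable & rat >= min_ratio
      u <- unmix(a, x, r_min = r_min, min_bands = min_bands)
      so2[i, j] <- u$so2
      acc[i, j] <- u$accepted
      pr[i, j] <- u$pearson_r
      reason[i, j] <- u$reason
    }
  }
  structure(list(so2 = so2, accepted = acc, pearson = pr, reason = reason,
                 pixel_size = stack$pixel_size,
                 wavelengths = stack$wavelengths),
            class = "so2_map")
}

#' @export
print.so2_map <- function(x, ...) {
  n <- length(x$accepted)
  cat(sprintf("<so2_map> %d x %d pixels, %.1f%% accepted\n",
              nrow(x$so2), ncol(x$so2), 100 * sum(x$accepted) / n))
  if (any(x$accepted))
    cat(sprintf("  accepted SO2: median %.3f [%.3f, %.3f]\n",
                stats::median(x$so2[x$accepted]),
                min(x$so2[x$accepted]), max(x$so2[x$accepted])))
  invisible(x)
}

#' Oxygen saturation time series
#'
#' @param times sampling times, minutes, strictly increasing.
#' @param so2 SO2 value at each time (fraction or percent, consistently).
#' @param baseline_window length-2 interval (minutes) defining the
#'   pre-stimulus baseline; must contain at least one sample.
#' @return An object of class `"oxygen_time_series"`.
#' @export
oxygen_time_series <- function(times, so2,
                               baseline_window = c(min(times), 0)) {
  stopifnot(length(times) == length(so2), all(diff(times) > 0),
            length(baseline_window) == 2)
  inb <- times >= baseline_window[1] & times <= baseline_window[2]
  if (!any(inb)) stop("baseline window contains no samples")
  structure(list(times = times, so2 = so2,
                 baseline_window = baseline_window),
            class = "oxygen_time_series")
}

baseline_so2 <- function(series) {
  inb <- series$times >= series$baseline_window[1] &
    series$times <= series$baseline_window[2]
  mean(series$so2[inb])
}

#' Relative SO2 change
#'
#' `delta(t) = (SO2(t) - SO2_baseline) / SO2_baseline`, with the baseline
#' the mean over the baseline window. Invariant to rescaling the whole
#' series.
#'
#' @param series an [oxygen_time_series()].
#' @return numeric vector of relative changes, one per time point.
#' @export
delta_so2 <- function(series) {
  stopifnot(inherits(series, "oxygen_time_series"))
  bl <- baseline_so2(series)
  if (!is.finite(bl) || bl == 0)
    stop("baseline SO2 is zero or undefined; relative change is undefined")
  (series$so2 - bl) / bl
}

#' Peak response and recovery time of a hypoxic stimulus
#'
#' Peak response: maximal decrease of SO2 relative to baseline over
#' `t >= onset` (a positive fraction; 0 when SO2 never drops). Recovery
#' time: time from stimulus onset until SO2 first returns to (or above)
#' the baseline and stays there for `sustain` consecutive samples; the
#' crossing is linearly interpolated between samples. A series that never
#' recovers returns `recovery_time = NA` with a warning.
#'
#' @param series an [oxygen_time_series()].
#' @param onset stimulus onset time, minutes.
#' @param sustain number of consecutive at-or-above-baseline samples
#'   required to call recovery (guards against noise-triggered crossings).
#' @return list with `peak_response` (fraction of baseline) and
#'   `recovery_time` (minutes from onset, `NA` if never recovered).
#' @export
hypoxia_metrics <- function(series, onset, sustain = 2) {
  stopifnot(inherits(series, "oxygen_time_series"))
  d <- delta_so2(series)
  t <- series$times
  post <- t >= onset
  if (!any(post)) stop("series does not span the stimulus onset")
  peak <- max(0, -min(d[post]))
  if (peak == 0) {
    return(list(peak_response = 0, recovery_time = 0))
  }
  # first dip below baseline after onset
  ipost <- which(post)
  below <- d[ipost] < 0
  if (!any(below)) return(list(peak_response = peak, recovery_time = 0))
  i_dip <- ipost[which(below)[1]]
  # first index at/above baseline after the dip with `sustain` holds
  idx <- which(t > t[i_dip] & d >= 0)
  rec_i <- NA_integer_
  for (i in idx) {
    run <- i:min(i + sustain - 1, length(d))
    if (length(run) >= sustain && all(d[run] >= 0)) { rec_i <- i; break }
  }
  if (is.na(rec_i)) {
    warning("SO2 never recovers to baseline within the series")
    return(list(peak_response = peak, recovery_time = NA_real_))
  }
  # linear interpolation of the zero crossing between rec_i - 1 and rec_i
  t_rec <- t[rec_i]
  if (rec_i > 1 && d[rec_i - 1] < 0 && d[rec_i] > 0) {
    f <- -d[rec_i - 1] / (d[rec_i] - d[rec_i - 1])
    t_rec <- t[rec_i - 1] + f * (t[rec_i] - t[rec_i - 1])
  }
  list(peak_response = peak, recovery_time = t_rec - onset)
}

#' Concentric-annulus SO2 profile around a tumor center
#'
#' Mean accepted SO2 in concentric rings of `ring_width` mm out to
#' `max_radius` mm from the center. Ring membership is by pixel-center
#' distance. Rings with outer edge within 3 mm form the tumor region; the
#' remainder is the adjacent region. Rings without accepted pixels get
#' `NA` means and are flagged.
#'
#' @param map an `"so2_map"` from [map_so2()], or a list with matrices
#'   `so2` and `accepted` plus `pixel_size`.
#' @param center tumor center, `c(row, col)` in floating 0-based pixels.
#' @param pixel_size mm/pixel; defaults to the map's.
#' @param ring_width,max_radius ring geometry, mm.
#' @return data.frame with one row per ring: `r_inner`, `r_outer` (mm),
#'   `mean_so2`, `n_pixels`, `region` (`"tumor"`/`"adjacent"`), `empty`.
#' @export
annulus_profile <- function(map, center, pixel_size = map$pixel_size,
                            ring_width = 0.5, max_radius = 4.5) {
  stopifnot(length(center) == 2, ring_width > 0, max_radius > ring_width)
  so2 <- map$so2; acc <- map$accepted
  nr <- nrow(so2); nc <- ncol(so2)
  if (max_radius / pixel_size > max(nr, nc))
    stop("the outer annulus does not fit inside the image")
  # pixel-center distances, 0-based indexing
  rows <- matrix(0:(nr - 1), nr, nc)
  cols <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  dist_mm <- sqrt((rows - center[1])^2 + (cols - center[2])^2) * pixel_size
  edges <- seq(0, max_radius, by = ring_width)
  n_ring <- length(edges) - 1
  out <- data.frame(r_inner = edges[-length(edges)], r_outer = edges[-1])
  out$mean_so2 <- NA_real_
  out$n_pixels <- 0L
  for (k in seq_len(n_ring)) {
    inring <- dist_mm >= out$r_inner[k] & dist_mm < out$r_outer[k] & acc
    out$n_pixels[k] <- sum(inring)
    if (any(inring)) out$mean_so2[k] <- mean(so2[inring])
  }
  out$region <- ifelse(out$r_outer <= 3, "tumor", "adjacent")
  out$empty <- out$n_pixels == 0L
  out
}
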