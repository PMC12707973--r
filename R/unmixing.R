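#' Vascular absorbance from paired detections
#'
#' Base-10 absorbance attributable to the vascular compartment: the
#' background-referenced ratio cancels the source and bulk-tissue terms, so
#' `a_vessel(lambda) = log10(background_fraction / sample_fraction)`.
#' Bands where either fraction is zero or negative carry no information
#' (nothing was detected); they are flagged non-detectable rather than
#' silently dropped, and downstream fitting excludes them.
#'
#' @param sample_fraction,background_fraction per-band detected fractions
#'   (or corrected intensities) for the sample and the matched background.
#' @param grid wavelength grid, nm, same length.
#' @return An object of class `"absorbance_spectrum"`: data.frame with
#'   columns `wavelength_nm`, `a_vessel`, `detectable`.
#' @export
vessel_absorbance <- function(sample_fraction, background_fraction,
                              grid = wavelength_grid()) {
  stopifnot(length(sample_fraction) == length(grid),
            length(background_fraction) == length(grid))
  ok <- is.finite(sample_fraction) & is.finite(background_fraction) &
    sample_fraction > 0 & background_fraction > 0
  a <- rep(NA_real_, length(grid))
  a[ok] <- log10(background_fraction[ok] / sample_fraction[ok])
  structure(data.frame(wavelength_nm = grid, a_vessel = a, detectable = ok),
            class = c("absorbance_spectrum", "data.frame"))
}

#' Design matrix of the modified Beer-Lambert model
#'
#' Columns `[1, eps_oxy(lambda), eps_deoxy(lambda)]` evaluated on the grid.
#' The fitted coefficients are `c = (xi, B*SO2*L, B*(1-SO2)*L)`. On the
#' default 23-band grid the matrix has full column rank.
#'
#' @param grid wavelength grid, nm.
#' @param table extinction table.
#' @return Numeric matrix, `length(grid)` x 3, columns
#'   `offset`, `eps_oxy`, `eps_deoxy`.
#' @export
design_matrix <- function(grid = wavelength_grid(),
                          table = hemoglobin_extinction()) {
  eps <- extinction_at(grid, table)
  cbind(offset = 1, eps_oxy = eps$eps_oxy, eps_deoxy = eps$eps_deoxy)
}

#' Solve for oxygen saturation by non-negative least squares
#'
#' Fits `A ~ X c` with `c >= 0` elementwise (all three coefficients,
#' including the offset, are constrained non-negative) and reports
#' `SO2 = c2 / (c2 + c3)`. Goodness of fit is the Pearson correlation
#' between the measured and fitted spectra over the usable bands; the
#' estimate is accepted when `r >= r_min` (default 0.9) and the hemoglobin
#' coefficients are not degenerate. Rejections carry a reason code:
#' * `"bad_bands"`: fewer than `min_bands` usable (detectable, finite) bands;
#' * `"no_hemoglobin"`: `c2 + c3` numerically zero (e.g. a flat spectrum);
#' * `"low_r"`: correlation below the gate or undefined.
#'
#' @param a an `"absorbance_spectrum"` (from [vessel_absorbance()]) or a
#'   bare numeric vector of per-band absorbances.
#' @param x design matrix from [design_matrix()].
#' @param r_min Pearson acceptance gate.
#' @param min_bands minimum number of usable bands.
#' @return An object of class `"unmix_result"`: list with `c` (length-3
#'   coefficient vector), `so2` (clipped to `[0, 1]`; `NA` when
#'   undefined), `pearson_r`, `accepted`, `reason` (`NA` when accepted),
#'   `n_bands`.
#' @examples
#' A <- theoretical_absorbance(blood_spec(0.98), 0.05, 0.1)
#' unmix(A)$so2  # 0.98 to machine precision
#' @export
unmix <- function(a, x = design_matrix(), r_min = 0.9, min_bands = 10) {
  av <- if (inherits(a, "absorbance_spectrum")) a$a_vessel else as.numeric(a)
  if (length(av) != nrow(x))
    stop("absorbance length does not match the design matrix")
  use <- is.finite(av)
  if (inherits(a, "absorbance_spectrum")) use <- use & a$detectable
  res <- list(c = rep(NA_real_, 3), so2 = NA_real_, pearson_r = NA_real_,
              accepted = FALSE, reason = NA_character_,
              n_bands = sum(use))
  class(res) <- "unmix_result"
  if (sum(use) < min_bands) {
    res$reason <- "bad_bands"
    return(res)
  }
  xu <- x[use, , drop = FALSE]
  cc <- tryCatch(pracma::lsqnonneg(xu, av[use])$x,
                 error = function(e) nnls_exhaustive(xu, av[use]))
  names(cc) <- colnames(x)
  res$c <- cc
  fitted <- drop(x[use, , drop = FALSE] %*% cc)
  hem <- cc[2] + cc[3]
  if (hem > .Machine$double.eps * max(1, sum(abs(cc)))) {
    res$so2 <- min(1, max(0, cc[2] / hem))
  }
  r <- suppressWarnings(stats::cor(av[use], fitted))
  res$pearson_r <- r
  if (is.na(res$so2)) {
    res$reason <- "no_hemoglobin"
  } else if (!is.finite(r) || r < r_min) {
    res$reason <- "low_r"
  } else {
    res$accepted <- TRUE
  }
  res
}

# Exact NNLS for a small number of columns by enumerating active sets:
# the optimum is the best feasible unconstrained fit over some support.
# Used as a fallback when the iterative solver fails to converge on a
# degenerate spectrum.
nnls_exhaustive <- function(x, b) {
  p <- ncol(x)
  best <- rep(0, p)
  best_rss <- sum(b^2)
  for (mask in seq_len(2^p - 1)) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(p) - 1)))
    fit <- tryCatch(stats::lm.fit(x[, sel, drop = FALSE], b),
                    error = function(e) NULL)
    if (is.null(fit)) next
    beta <- fit$coefficients
    if (any(is.na(beta)) || any(beta < 0)) next
    rss <- sum(fit$residuals^2)
    if (rss < best_rss - 1e-12 * (1 + best_rss)) {
      best_rss <- rss
      best <- rep(0, p)
      best[sel] <- beta
    }
  }
  best
}

#' @export
print.unmix_result <- function(x, ...) {
  if (x$accepted)
    cat(sprintf("<unmix_result> SO2 = %.2f%% (r = %.4f, %d bands)\n",
                100 * x$so2, x$pearson_r, x$n_bands))
  else
    cat(sprintf("<unmix_result> rejected (%s; r = %s, %d bands)\n",
                x$reason, format(x$pearson_r, digits = 4), x$n_bands))
  invisible(x)
}
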