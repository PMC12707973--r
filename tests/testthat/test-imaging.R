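make_uniform_stack <- function(level = 0.5, nr = 6, nc = 8,
                               grid = wavelength_grid(),
                               reference = 1000, dark = 20) {
  data <- array(dark + level * (reference - dark),
                c(nr, nc, length(grid)))
  spectral_stack(data, grid, reference = rep(reference, length(grid)),
                 dark = rep(dark, length(grid)))
}

test_that("corrected ratio recovers unity for background-identical pixels", {
  st <- make_uniform_stack(0.5)
  ratio <- corrected_ratio(st, rep(0.5, 23))
  expect_equal(max(abs(ratio - 1)), 0, tolerance = 1e-12)
  # perfect reference, no dark: numerator is one
  st2 <- spectral_stack(array(1, c(4, 4, 23)), wavelength_grid(),
                        reference = rep(1, 23), dark = 0)
  expect_equal(max(abs(corrected_intensity(st2) - 1)), 0)
})

test_that("a reference at or below dark is a calibration error naming the band", {
  st <- make_uniform_stack()
  st$reference[5] <- st$dark[5]
  expect_error(corrected_intensity(st), "540")
})

test_that("the corrected ratio dips under the vessel at 550 nm", {
  sp <- phantom_spec(depth_range = c(0.2, 0.2), noise_sd = 0)
  g <- generate_stack(sp, shape = c(30, 40), seed = 2)
  bg <- background_spectrum(g$stack, !g$truth$vessel_mask)
  ratio <- corrected_ratio(g$stack, bg)
  b550 <- which(wavelength_grid() == 550)
  center <- which(g$truth$chord_mm == max(g$truth$chord_mm),
                  arr.ind = TRUE)[1, ]
  expect_lt(ratio[center[1], center[2], b550], 1)
})

test_that("a stack identical to its background rejects every pixel", {
  st <- make_uniform_stack(0.5)
  roi <- matrix(TRUE, 6, 8)
  m <- map_so2(st, background_roi = roi)
  expect_false(any(m$accepted))
  expect_true(all(m$reason == "no_hemoglobin"))
})

test_that("a shallow synthetic vessel round-trips through the map", {
  sp <- phantom_spec(depth_range = c(0.05, 0.05),
                     blood = blood_spec(0.98), noise_sd = 0.01)
  g <- generate_stack(sp, shape = c(40, 60), seed = 9)
  roi <- matrix(FALSE, 40, 60); roi[1:8, ] <- TRUE
  m <- map_so2(g$stack, background_roi = roi)
  on_vessel <- g$truth$vessel_mask & m$accepted
  expect_gt(sum(on_vessel), 100)
  expect_lt(median(abs(m$so2[on_vessel] - 0.98)), 0.02)
})

test_that("a 48 micron vessel is resolved in the accepted-pixel profile", {
  sp <- phantom_spec(vessel_diameter = 0.048,
                     depth_range = c(0.05, 0.05),
                     blood = blood_spec(0.98), noise_sd = 0.005)
  g <- generate_stack(sp, shape = c(25, 40), seed = 3, pixel_size = 0.016)
  roi <- matrix(FALSE, 25, 40); roi[1:5, ] <- TRUE
  m <- map_so2(g$stack, background_roi = roi)
  profile <- rowSums(m$accepted)   # accepted count across the vessel
  vessel_rows <- which(rowSums(g$truth$vessel_mask) > 0)
  bg_rows <- setdiff(seq_len(25), vessel_rows)
  expect_gt(max(profile[vessel_rows]), 3 * max(1, max(profile[bg_rows])))
})

test_that("mapping commutes with transposition", {
  sp <- phantom_spec(depth_range = c(0.1, 0.1), blood = blood_spec(0.9),
                     noise_sd = 0)
  g <- generate_stack(sp, shape = c(20, 30), seed = 4)
  st <- g$stack
  roi <- matrix(FALSE, 20, 30); roi[1:4, ] <- TRUE
  m <- map_so2(st, background_roi = roi)
  td <- array(0, c(30, 20, 23))
  for (b in 1:23) td[, , b] <- t(st$data[, , b])
  st_t <- spectral_stack(td, st$wavelengths, st$reference, st$dark,
                         st$pixel_size, st$mode)
  m_t <- map_so2(st_t, background_roi = t(roi))
  expect_equal(m_t$so2, t(m$so2))
  expect_equal(m_t$accepted, t(m$accepted))
})

test_that("relative SO2 change has the defined algebra", {
  ser <- oxygen_time_series(0:10, c(rep(0.8, 3), 0.6, 0.4, 0.4, 0.5,
                                    0.7, 0.8, 0.82, 0.81),
                            baseline_window = c(0, 2))
  d <- delta_so2(ser)
  expect_equal(d[1:3], rep(0, 3))
  expect_equal(d[5], -0.5)
  # invariant to rescaling the series
  ser2 <- oxygen_time_series(ser$times, 2.5 * ser$so2,
                             baseline_window = c(0, 2))
  expect_equal(delta_so2(ser2), d)
  expect_error(oxygen_time_series(0:3, rep(0.5, 4),
                                  baseline_window = c(-5, -4)),
               "baseline")
})

test_that("hypoxia metrics recover programmed waveforms", {
  flat <- oxygen_time_series(0:8, rep(0.7, 9), baseline_window = c(0, 2))
  expect_equal(hypoxia_metrics(flat, onset = 2),
               list(peak_response = 0, recovery_time = 0))
  # programmed dip of -0.4 recovering exactly at 4 minutes after onset
  t <- seq(0, 10, by = 0.5)
  base <- 0.8
  onset <- 3
  dip <- approx(x = c(0, 3, 4.5, 6, 7, 10),
                y = c(0, 0, -0.4, -0.1, 0.05, 0.05), xout = t)$y
  ser <- oxygen_time_series(t, base * (1 + dip), baseline_window = c(0, 3))
  met <- hypoxia_metrics(ser, onset = onset)
  expect_equal(met$peak_response, 0.4, tolerance = 1e-9)
  # linear recovery from -0.1 at t=6 to +0.05 at t=7 crosses zero at 6.667
  expect_equal(met$recovery_time, 6 + 0.1 / 0.15 - onset,
               tolerance = 1e-9)
  # a trace that never recovers is signalled
  stuck <- oxygen_time_series(0:6, c(0.8, 0.8, 0.6, 0.5, 0.5, 0.5, 0.5),
                              baseline_window = c(0, 1))
  expect_warning(ms <- hypoxia_metrics(stuck, onset = 1), "recover")
  expect_true(is.na(ms$recovery_time))
  expect_equal(ms$peak_response, 0.375)
})

test_that("annulus profiles average rings correctly", {
  n <- 201; px <- 0.05   # 10 mm field, center pixel (100, 100)
  acc <- matrix(TRUE, n, n)
  uni <- list(so2 = matrix(0.8, n, n), accepted = acc, pixel_size = px)
  prof <- annulus_profile(uni, center = c(100, 100))
  expect_equal(nrow(prof), 9)
  expect_equal(prof$r_outer, seq(0.5, 4.5, by = 0.5))
  expect_equal(prof$mean_so2, rep(0.8, 9))
  expect_equal(prof$region, c(rep("tumor", 6), rep("adjacent", 3)))

  # radial gradient: ring means match the analytic area-weighted value
  rows <- matrix(0:(n - 1), n, n); cols <- t(rows)
  r_mm <- sqrt((rows - 100)^2 + (cols - 100)^2) * px
  grad <- list(so2 = 0.5 + 0.05 * r_mm, accepted = acc, pixel_size = px)
  pg <- annulus_profile(grad, center = c(100, 100))
  r0 <- pg$r_inner; r1 <- pg$r_outer
  analytic <- 0.5 + 0.05 * (2 / 3) * (r1^3 - r0^3) / (r1^2 - r0^2)
  expect_lt(max(abs(pg$mean_so2 - analytic)), 0.005)

  # rotation invariance of a radially symmetric map
  rot <- list(so2 = t(grad$so2[n:1, ]), accepted = acc, pixel_size = px)
  pr <- annulus_profile(rot, center = c(100, 100))
  expect_lt(max(abs(pr$mean_so2 - pg$mean_so2)), 0.01)

  # empty rings are flagged, and an off-image radius errors
  holey <- list(so2 = matrix(0.8, n, n),
                accepted = r_mm > 1.1, pixel_size = px)
  ph <- annulus_profile(holey, center = c(100, 100))
  expect_true(ph$empty[1])
  expect_true(is.na(ph$mean_so2[1]))
  expect_error(annulus_profile(uni, center = c(100, 100),
                               pixel_size = 0.001), "fit")
})
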