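test_that("a vessel-free noiseless phantom has flat unit corrected ratio", {
  sp <- phantom_spec(vessel_diameter = 0, noise_sd = 0, read_noise = 0)
  g <- generate_stack(sp, shape = c(10, 12), seed = 1)
  expect_false(any(g$truth$vessel_mask))
  ci <- corrected_intensity(g$stack)
  bg <- background_spectrum(g$stack, matrix(TRUE, 10, 12))
  ratio <- corrected_ratio(g$stack, bg)
  expect_equal(max(abs(ratio - 1)), 0, tolerance = 1e-9)
  # bands are attenuated differently but uniformly across pixels
  expect_gt(max(ci) / min(ci), 1.0)
})

test_that("stacks are bitwise reproducible per seed", {
  sp <- phantom_spec()
  a <- generate_stack(sp, shape = c(12, 16), seed = 7)
  b <- generate_stack(sp, shape = c(12, 16), seed = 7)
  expect_identical(a$stack$data, b$stack$data)
  d <- generate_stack(sp, shape = c(12, 16), seed = 8)
  expect_false(identical(a$stack$data, d$stack$data))
})

test_that("vessel acceptance shrinks with depth, slower in transmission", {
  sp <- phantom_spec(depth_range = c(0, 1.5), blood = blood_spec(0.98),
                     noise_sd = 0.01)
  roi <- matrix(FALSE, 30, 64); roi[1:6, ] <- TRUE
  acc <- list()
  for (md in c("reflective", "transmissive")) {
    g <- generate_stack(sp, shape = c(30, 64), seed = 5, mode = md)
    m <- map_so2(g$stack, background_roi = roi)
    vm <- g$truth$vessel_mask
    deep <- g$truth$depth_mm > 0.75
    acc[[md]] <- c(shallow = mean(m$accepted[vm & !deep]),
                   deep = mean(m$accepted[vm & deep]))
  }
  # reflective detection loses the deep vessel
  expect_lt(acc$reflective["deep"], acc$reflective["shallow"])
  # transmissive detection retains acceptance deeper than reflective
  expect_gt(acc$transmissive["deep"], acc$reflective["deep"] + 0.2)
})

test_that("the default phantom round-trips in the shallow half", {
  sp <- phantom_spec(blood = blood_spec(0.98))
  g <- generate_stack(sp, shape = c(30, 64), seed = 11)
  roi <- matrix(FALSE, 30, 64); roi[1:6, ] <- TRUE
  m <- map_so2(g$stack, background_roi = roi)
  shallow <- g$truth$vessel_mask & m$accepted &
    g$truth$depth_mm <= max(g$truth$depth_mm) / 2
  expect_gt(sum(shallow), 50)
  expect_lt(median(abs(m$so2[shallow] - 0.98)), 0.03)
})

test_that("study designs validate their inputs", {
  expect_error(study_design(depths_mm = -1), "depths")
  expect_error(study_design(presets = c(0.4, 0.9)))
  d <- study_design(depths_mm = c(0, 1), presets = c(0.98, 0.75),
                    photons = 100, seed = 3)
  expect_s3_class(d, "study_design")
})

test_that("identity transport recovers the presets with unit sensitivity", {
  d <- study_design(depths_mm = c(0, 1),
                    presets = c(0.98, 0.9, 0.8, 0.7, 0.6, 0.5),
                    photons = 1, seed = 1)
  st <- run_depth_study(d, engine = "analytic")
  expect_true(all(st$accepted))
  expect_equal(st$so2_hat, st$preset, tolerance = 1e-6)
  sa <- sensitivity_analysis(st)
  expect_equal(sa$sensitivity$slope, rep(1, nrow(sa$sensitivity)),
               tolerance = 1e-6)
  expect_true(all(sa$sensitivity$mae < 1e-6))
})

test_that("a small Monte Carlo study runs end to end and is reproducible", {
  d <- study_design(depths_mm = 0, presets = c(0.98, 0.75),
                    photons = 2000, seed = 17, modes = "transmissive")
  st <- run_depth_study(d)
  expect_equal(nrow(st), 2)
  expect_true(all(is.finite(st$so2_hat)))
  # higher preset recovers higher
  expect_gt(st$so2_hat[st$preset == 0.98], st$so2_hat[st$preset == 0.75])
  st2 <- run_depth_study(d)
  expect_identical(st, st2)
})
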