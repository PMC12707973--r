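test_that("non-scattering slab reproduces the Beer-Lambert limit", {
  m <- tissue_model(list(optical_layer(1, 0.5, 0, g = 0, n = 1)))
  r <- mc_simulate(m, photons = 1e5, seed = 3, detection_radius = Inf)
  expect_lt(abs(r$transmitted_fraction - exp(-0.5)),
            3 * r$se_transmitted)
  expect_equal(r$reflected_fraction, 0)
})

test_that("weight is conserved", {
  # no absorption, matched indices: everything reflects or transmits
  m <- tissue_model(list(optical_layer(0.2, 0, 80, g = 0.8, n = 1)))
  r <- mc_simulate(m, photons = 2e4, seed = 9, detection_radius = Inf)
  expect_lt(abs(r$reflected_fraction + r$transmitted_fraction - 1), 1e-6)
  # absorbing, mismatched model: the five-way ledger closes exactly
  m2 <- tissue_model(list(optical_layer(0.05, 1, 150, 0.8, 1.4),
                          optical_layer(0.1, 0.3, 120, 0.9, 1.4),
                          optical_layer(0.1, 2, 100, 0.85, 1.37)))
  r2 <- mc_simulate(m2, photons = 2e4, seed = 10)
  total <- r2$reflected_total + r2$transmitted_total +
    r2$absorbed_fraction + r2$specular_fraction
  expect_lt(abs(total - 1), 1e-9)
  total5 <- r2$reflected_fraction + r2$transmitted_fraction +
    r2$lost_fraction + r2$absorbed_fraction + r2$specular_fraction
  expect_lt(abs(total5 - 1), 1e-9)
  frs <- unlist(r2[c("reflected_fraction", "transmitted_fraction",
                     "absorbed_fraction", "specular_fraction",
                     "lost_fraction")])
  expect_true(all(frs >= 0 & frs <= 1))
})

test_that("runs are deterministic in (seed, stream) and photon count", {
  m <- skin_model(0.05, 0.98)
  a <- mc_simulate(m, 560, photons = 5e3, seed = 4, stream = 2)
  b <- mc_simulate(m, 560, photons = 5e3, seed = 4, stream = 2)
  expect_identical(a[names(a) != "radial"], b[names(b) != "radial"])
  d <- mc_simulate(m, 560, photons = 5e3, seed = 4, stream = 3)
  expect_false(identical(a$reflected_fraction, d$reflected_fraction))
})

test_that("Monte Carlo standard error shrinks as one over root n", {
  m <- tissue_model(list(optical_layer(0.2, 0.3, 100, 0.9, 1.4)))
  se1 <- mc_simulate(m, photons = 1e4, seed = 5)$se_transmitted
  se4 <- mc_simulate(m, photons = 4e4, seed = 6)$se_transmitted
  expect_lt(abs(se1 / se4 - 2), 0.6)  # ratio 2 within 30%
})

test_that("transmission is reciprocal under slab flipping", {
  top <- optical_layer(0.08, 0.4, 90, 0.85, 1.4)
  bot <- optical_layer(0.12, 0.1, 140, 0.9, 1.35)
  m <- tissue_model(list(top, bot))
  f <- tissue_model(list(bot, top))
  rm_ <- mc_simulate(m, photons = 4e4, seed = 21, detection_radius = Inf)
  rf <- mc_simulate(f, photons = 4e4, seed = 22, detection_radius = Inf)
  se <- sqrt(rm_$se_transmitted_total^2 + rf$se_transmitted_total^2)
  expect_lt(abs(rm_$transmitted_total - rf$transmitted_total), 3 * se)
})

test_that("engine agrees with the independent reference implementation", {
  lay <- data.frame(thickness = c(0.1, 0.1), mu_a = 0.1,
                    mu_s = 100, g = 0.9, n = 1.4)
  ref <- ref_mc_transport(lay, photons = 1e5, seed = 31)
  m <- tissue_model(list(optical_layer(0.1, 0.1, 100, 0.9, 1.4),
                         optical_layer(0.1, 0.1, 100, 0.9, 1.4)))
  r <- mc_simulate(m, photons = 1e5, seed = 32, detection_radius = Inf)
  se_r <- sqrt(r$se_reflected_total^2 + ref$se_reflected^2)
  se_t <- sqrt(r$se_transmitted_total^2 + ref$se_transmitted^2)
  expect_lt(abs(r$reflected_total - ref$reflected), 3 * se_r)
  expect_lt(abs(r$transmitted_total - ref$transmitted), 3 * se_t)
})

test_that("spectral sweeps cover the grid deterministically", {
  m <- skin_model(0.05, 0.98)
  sw <- spectral_sweep(m, photons = 500, seed = 7)
  expect_equal(nrow(sw), 23)
  expect_equal(sw$wavelength_nm, wavelength_grid())
  sw2 <- spectral_sweep(m, photons = 500, seed = 7)
  expect_identical(sw, sw2)
  # presets share everything but the vascular absorption
  m75 <- skin_model(0.05, 0.75)
  expect_equal(background_model(m), background_model(m75))
})

test_that("paired detection of a vessel-free model gives unit ratios", {
  m <- tissue_model(list(optical_layer(0.15, 0.3, 120, 0.9, 1.4)))
  det <- paired_detection(m, photons = 5e3, seed = 13)
  expect_equal(nrow(det), 46)
  a <- vessel_absorbance(det$sample_fraction[det$mode == "transmissive"],
                         det$background_fraction[det$mode == "transmissive"])
  expect_lt(mean(abs(a$a_vessel)), 0.05)
})

test_that("a surface vessel produces the hemoglobin M-shape in reflection", {
  det <- paired_detection(skin_model(0, 0.98), photons = 2e4, seed = 14)
  d <- det[det$mode == "reflective", ]
  a <- vessel_absorbance(d$sample_fraction, d$background_fraction)
  theo <- theoretical_absorbance(blood_spec(0.98), 0.05, 0)
  expect_gt(cor(a$a_vessel, theo), 0.9)
})

test_that("configuration errors are caught", {
  semi <- tissue_model(list(optical_layer(0.1, 0.3, 100, 0.9, 1.4),
                            optical_layer(Inf, 0.3, 100, 0.9, 1.4)))
  expect_error(paired_detection(semi, photons = 100, seed = 1,
                                modes = "transmissive"), "finite")
  m <- skin_model(0.05)
  other <- tissue_model(list(optical_layer(0.3, 0.3, 120, 0.9, 1.4)))
  expect_error(paired_detection(m, bg_model = other, photons = 100,
                                seed = 1), "geometry")
  expect_error(tissue_model(list(optical_layer(Inf, 0.1, 10),
                                 optical_layer(0.1, 0.1, 10))),
               "infinite")
})
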