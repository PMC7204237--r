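test_that("generation is deterministic and produces the expected record counts", {
  cfg <- generator_config(n_cows = 84, obs_per_cow = 2, seed = 1)
  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds1$milkings, ds2$milkings)
  expect_identical(ds1$spectra, ds2$spectra)
  expect_identical(ds1$calorimetry, ds2$calorimetry)
  expect_identical(ds1$truth, ds2$truth)
  expect_equal(nrow(ds1$calorimetry), 168)
  expect_equal(nrow(ds1$milkings), 336)
  expect_equal(nrow(ds1$truth), 168)
  # each cow-day has exactly one AM and one PM milking
  per_day <- table(paste(ds1$milkings$cow_id, ds1$milkings$date),
                   ds1$milkings$session)
  expect_true(all(per_day == 1))
  # a different seed changes the draw
  expect_false(identical(generate_dataset(cfg, seed = 2)$spectra, ds1$spectra))
})

test_that("generated values respect the configured ranges", {
  ds <- shared_dataset()
  cfg <- ds$config
  expect_true(all(ds$calorimetry$bw_kg >= cfg$bw_range[1] &
                    ds$calorimetry$bw_kg <= cfg$bw_range[2]))
  daily <- tapply(ds$milkings$milk_yield_l,
                  paste(ds$milkings$cow_id, ds$milkings$date), sum)
  expect_true(all(daily >= cfg$daily_yield_range[1] - 1e-9 &
                    daily <= cfg$daily_yield_range[2] + 1e-9))
  expect_true(all(ds$milkings$milk_yield_l > 0))
  expect_true(all(ds$spectra > 0 & ds$spectra <= 1))
  expect_true(all(ds$calorimetry$v_o2 >= 0 & ds$calorimetry$v_ch4 >= 0))
  expect_true(all(ds$truth$hp_total_kj > 0))
})

test_that("noise-free generation reproduces the heat-production recipe exactly", {
  cfg <- generator_config(n_cows = 12, obs_per_cow = 1, hp_noise_sd = 0,
                          spectral_noise_sd = 0)
  ds <- generate_dataset(cfg, seed = 3)
  mbw <- metabolic_body_weight(ds$calorimetry$bw_kg)
  expected <- cfg$hp_maintenance_coeff * mbw +
    cfg$hp_milk_coeff * 1000 * ds$truth$milk_energy_mj
  expect_equal(ds$truth$hp_total_kj, expected, tolerance = 1e-12)
})

test_that("invalid generator configurations name the offending field", {
  expect_error(generator_config(am_fraction = 1.2), "am_fraction")
  expect_error(generator_config(bw_range = c(900, 500)), "bw_range")
  expect_error(generator_config(respiratory_quotient = 0), "respiratory_quotient")
  expect_error(generator_config(grid_spec = c(5000, 925, 100)), "grid_spec")
  expect_error(generator_config(spectral_noise_sd = -1), "spectral_noise_sd")
  bad_bands <- default_band_library()
  bad_bands$absorptivity[1] <- -0.1
  expect_error(generator_config(band_library = bad_bands), "band_library")
})

test_that("the band model builds spectra that are linear in composition", {
  grid <- seq(925, 5008, length.out = 400)
  zero <- c(fat = 0, protein = 0, lactose = 0)
  t0 <- synthesize_spectrum(zero, grid, noise_sd = 0, baseline = 0)
  water <- (grid >= 1577 & grid <= 1720) | grid > 3000
  expect_true(all(t0[!water] == 1))          # A = 0 outside water regions
  expect_equal(unique(t0[water]), 10^(-3))   # saturated constant inside

  # doubling fat doubles the absorbance at the 1750 band center
  i1750 <- which.min(abs(grid - 1750))
  a1 <- to_absorbance(synthesize_spectrum(c(fat = 20, protein = 0, lactose = 0),
                                          grid, noise_sd = 0, baseline = 0))
  a2 <- to_absorbance(synthesize_spectrum(c(fat = 40, protein = 0, lactose = 0),
                                          grid, noise_sd = 0, baseline = 0))
  expect_equal(a2[i1750], 2 * a1[i1750], tolerance = 1e-9)
  expect_error(synthesize_spectrum(zero, rev(grid)), "increasing")
  expect_error(synthesize_spectrum(c(fat = -1, protein = 0, lactose = 0), grid),
               "nonnegative")
})

test_that("fat-band absorbance tracks latent fat content across records", {
  ds <- shared_dataset()
  absorb <- to_absorbance(ds$spectra)
  i1750 <- which.min(abs(ds$grid - 1750))
  am_rows <- which(ds$milkings$session == "AM")
  # day-level fat drives the session band up to session-level jitter
  r <- cor(absorb[am_rows, i1750], ds$truth$fat_gkg)
  expect_gt(r, 0.9)
})

test_that("gas exchange back-solved from HP inverts the Brouwer equation", {
  g <- derive_gas_exchange(16.18, rq = 0, v_ch4 = 0, nu = 0)
  expect_equal(g$v_o2, 1)
  expect_equal(g$v_co2, 0)

  rq <- 7072 / 6740
  g2 <- derive_gas_exchange(142419.24, rq = rq, v_ch4 = 570, nu = 150)
  expect_equal(g2$v_o2, 6740, tolerance = 1e-6)
  expect_equal(g2$v_co2, 7072, tolerance = 1e-6)
  expect_equal(brouwer_heat_production(g2), 142419.24, tolerance = 1e-9)
  expect_error(derive_gas_exchange(-5, rq = 1), "positive")
})

test_that("artifact injection is the identity at zero magnitude and stays valid", {
  grid <- seq(925, 5008, length.out = 300)
  sp <- synthesize_spectrum(c(fat = 40, protein = 34, lactose = 48), grid,
                            noise_sd = 0.01, baseline = 0.05, seed = 5)
  expect_equal(inject_spectral_outlier(sp, grid, 0, 1300, 30), sp,
               tolerance = 1e-12)
  out <- inject_spectral_outlier(sp, grid, 0.4, 1300, 30)
  expect_true(all(out > 0 & out <= 1))
  i1300 <- which.min(abs(grid - 1300))
  expect_gt(to_absorbance(out)[i1300], to_absorbance(sp)[i1300])
  expect_error(inject_spectral_outlier(sp, grid, Inf, 1300, 30), "finite")
})
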