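test_that("absorbance transform is decadic and round-trips with transmittance", {
  expect_equal(to_absorbance(1), 0)
  expect_equal(to_absorbance(0.1), 1)
  expect_equal(to_absorbance(0.01), 2)
  expect_error(to_absorbance(c(0.5, 1.2)), "index 2")
  expect_error(to_absorbance(c(0, 0.5)), "index 1")
  a <- c(0, 0.3, 1.7, 2.5)
  expect_equal(to_absorbance(to_transmittance(a)), a, tolerance = 1e-12)
  t <- c(1, 0.8, 0.05)
  expect_equal(to_transmittance(to_absorbance(t)), t, tolerance = 1e-12)
})

test_that("region selection keeps exactly the channels inside closed intervals", {
  grid <- c(900, 1000, 1500, 1600, 1750, 2600, 3000)
  spec <- seq_along(grid)
  sel <- select_regions(grid, spec)
  expect_equal(sel$grid, c(1000, 1500, 1750, 2600))
  expect_equal(sel$spectrum, c(2, 3, 5, 6))
  # whole-grid region is the identity; selection is idempotent
  all_r <- list(range(grid))
  expect_equal(select_regions(grid, spec, all_r)$spectrum, spec)
  sel2 <- select_regions(sel$grid, sel$spectrum)
  expect_equal(sel2, sel)
  expect_error(select_regions(c(5000, 5005), c(1, 2)), "no channels retained")
  expect_error(select_regions(grid, spec, list(c(1000, 900))), "lower <= upper")
  expect_error(select_regions(grid, spec, list(c(900, 1600), c(1500, 2000))),
               "non-overlapping")
})

test_that("default-grid region selection matches a brute-force enumeration", {
  grid <- seq(925, 5008, length.out = 1060)
  spec <- rep(0.5, length(grid))
  sel <- select_regions(grid, spec)
  brute <- sum(vapply(grid, function(v)
    (v >= 968 & v <= 1577) | (v >= 1720 & v <= 1808) | (v >= 2564 & v <= 2965),
    logical(1)))
  expect_equal(length(sel$grid), brute)
  expect_equal(length(select_regions(grid, spec)$grid), brute)  # stable on repeat
})

test_that("gap-difference derivatives act as discrete derivatives", {
  expect_equal(apply_derivative(rep(3, 10), order = 1), rep(0, 9))
  ramp <- 2.5 * (1:12)
  expect_equal(apply_derivative(ramp, order = 1, gap = 1), rep(2.5, 11))
  quad <- (1:15)^2
  expect_equal(apply_derivative(quad, order = 2), rep(2, 13))
  expect_equal(length(apply_derivative(1:10, order = 2, gap = 3)), 4)
  expect_error(apply_derivative(1:3, order = 2, gap = 2), "too short")
  # linear operator
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(apply_derivative(2 * x + 3 * y, 1, 2),
               2 * apply_derivative(x, 1, 2) + 3 * apply_derivative(y, 1, 2))
})

test_that("the three fusion schemes obey their algebraic identities", {
  v <- c(0.1, 0.4, 0.2)
  w <- c(0.3, 0.0, 0.5)
  expect_equal(combine_m1(v, v), v)
  expect_equal(combine_m1(rep(0, 3), v), v / 2)
  expect_equal(combine_m1(v, w), combine_m1(w, v))

  # M2: total yield 1 reduces to M1; zero yields annihilate; homogeneous
  expect_equal(combine_m2(v, w, 0.4, 0.6), combine_m1(v, w))
  expect_equal(combine_m2(v, w, 0, 0), rep(0, 3))
  expect_equal(combine_m2(v, w, 8, 6), 2 * combine_m2(v, w, 4, 3))

  # M3: unit yields reduce to M1; with equal spectra it is half the M2
  # output (M2 applies the full daily yield to the mean spectrum, M3
  # averages the yield-multiplied sessions); one dry session halves
  expect_equal(combine_m3(v, w, 1, 1), combine_m1(v, w))
  expect_equal(combine_m3(v, v, 3, 7), combine_m2(v, v, 3, 7) / 2)
  expect_equal(combine_m3(v, v, 3, 7), v * (3 + 7) / 2)
  expect_equal(combine_m3(v, w, 5, 0), v * 5 / 2)
  expect_equal(combine_m3(v, w, 4, 6, divisor = "total_yield"),
               (4 * v + 6 * w) / 10)

  # linear in each spectrum argument
  u <- c(0.2, 0.6, 0.1)
  expect_equal(combine_m3(v + u, w, 4, 6),
               combine_m3(v, w, 4, 6) + combine_m3(u, rep(0, 3), 4, 6))
  expect_error(combine_m2(v, w[1:2], 1, 1), "same grid")
  expect_error(combine_m2(v, w, -1, 1), "nonnegative")
})

test_that("region selection commutes with absorbance and fusion", {
  grid <- seq(925, 5008, length.out = 200)
  set.seed(42)
  t_am <- to_transmittance(runif(200, 0, 2))
  t_pm <- to_transmittance(runif(200, 0, 2))
  y <- c(12, 9)
  # absorbance then select == select then absorbance
  a_then_s <- select_regions(grid, to_absorbance(t_am))$spectrum
  s_first <- select_regions(grid, t_am)
  expect_equal(a_then_s, to_absorbance(s_first$spectrum))
  # fusion then select == select then fusion
  fused <- combine_m3(to_absorbance(t_am), to_absorbance(t_pm), y[1], y[2])
  expect_equal(select_regions(grid, fused)$spectrum,
               combine_m3(select_regions(grid, to_absorbance(t_am))$spectrum,
                          select_regions(grid, to_absorbance(t_pm))$spectrum,
                          y[1], y[2]))
})

test_that("an artifact outside the retained regions escapes region-limited screening", {
  set.seed(11)
  cfg <- small_config()
  ds <- generate_dataset(cfg, seed = 11)
  absorb <- to_absorbance(ds$spectra)
  # inject at 4500 cm^-1, far outside the informative regions
  sp <- inject_spectral_outlier(ds$spectra[1, ], ds$grid, magnitude = 0.5,
                                center = 4500, width = 30)
  absorb[1, ] <- to_absorbance(sp)
  sel <- select_regions(ds$grid, absorb)
  y <- rep(normalize_hp(brouwer_heat_production(
    gas_exchange(ds$calorimetry$v_o2, ds$calorimetry$v_co2,
                 ds$calorimetry$v_ch4, ds$calorimetry$nu_g)),
    ds$calorimetry$bw_kg)$hp_per_mbw, each = 2)
  det <- detect_spectral_outliers(sel$spectrum, y, n_lv = 5)
  expect_false(det$flag[1])
})
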