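test_that("the thermal model obeys midpoint, plateau and symmetry identities", {
  expect_equal(thermal_model(309.30, 0.1, 0.9, 309.30, 3e5), 0.5)
  expect_equal(thermal_model(200, 0.1, 0.9, 309.30, 3e5), 0.1, tolerance = 1e-6)
  expect_equal(thermal_model(500, 0.1, 0.9, 309.30, 3e5), 0.9, tolerance = 1e-4)
  expect_equal(thermal_model(311.30, 0, 1, 309.30, 2.5e5), 0.6513,
               tolerance = 1e-4)
  # numerically stable far into the tails
  expect_equal(thermal_model(1000, 0, 1, 300, 1e7), 1)
  expect_equal(thermal_model(1, 0, 1, 300, 1e7), 0)
  # swapping plateaus and negating dH leaves predictions unchanged
  Tg <- seq(280, 330, by = 2.5)
  expect_equal(thermal_model(Tg, 0.05, 0.95, 309, 3.5e5),
               thermal_model(Tg, 0.95, 0.05, 309, -3.5e5), tolerance = 1e-12)
  # monotone in T for dH != 0
  expect_true(all(diff(thermal_model(Tg, 0, 1, 309, 3.5e5)) > 0))
  expect_error(thermal_model(-1, 0, 1, 309, 3e5), "> 0 K")
})

test_that("Kelvin/Celsius round trip is exact", {
  x <- c(-273.15, 0, 20, 36.15, 42, 100)
  expect_equal(kelvin_to_celsius(celsius_to_kelvin(x)), x, tolerance = 1e-12)
})

test_that("noise-free thermal fits recover the midpoint to 1e-4 C", {
  Tg <- seq(20, 42, length.out = 8)
  fr <- thermal_model(celsius_to_kelvin(Tg), 0, 1,
                      celsius_to_kelvin(36.15), 3.5e5)
  tf <- fit_thermal_transition(Tg, fr)
  expect_true(tf$converged)
  expect_equal(tf$Tm_C, 36.15, tolerance = 1e-4)
  expect_equal(tf$f0, 0, tolerance = 1e-6)
  expect_equal(tf$fmax, 1, tolerance = 1e-6)
  # falling orientation is fitted without re-flipping the data
  tff <- fit_thermal_transition(Tg, 1 - fr)
  expect_equal(tff$Tm_C, 36.15, tolerance = 1e-3)
  expect_true(tff$f0 > tff$fmax)
  # constrained percent-scale fit gives the same midpoint
  tfc <- fit_thermal_transition(Tg, 100 * fr, f0_fixed = 0, fmax_fixed = 100,
                                scale = "percent")
  expect_equal(tfc$Tm_C, tf$Tm_C, tolerance = 1e-4)
})

test_that("fit -> simulate -> fit is idempotent for the thermal model", {
  Tg <- seq(28, 44, by = 2)
  fr <- thermal_model(celsius_to_kelvin(Tg), 0.05, 0.9,
                      celsius_to_kelvin(35), 2.8e5)
  tf1 <- fit_thermal_transition(Tg, fr)
  pred <- thermal_model(celsius_to_kelvin(Tg), tf1$f0, tf1$fmax,
                        celsius_to_kelvin(tf1$Tm_C), tf1$dH_apparent)
  tf2 <- fit_thermal_transition(Tg, pred)
  expect_equal(tf2$Tm_C, tf1$Tm_C, tolerance = 1e-6)
  expect_equal(tf2$dH_apparent, tf1$dH_apparent, tolerance = 1e-4)
})

test_that("degenerate or out-of-range transitions are flagged or rejected", {
  Tg <- seq(30, 42, 2)
  expect_error(fit_thermal_transition(Tg, rep(0.4, 7)), "identical")
  expect_error(fit_thermal_transition(c(30, 35), c(0.1, 0.9)), "distinct")
  # both plateaus fixed allows a 2-point fit
  fr2 <- thermal_model(celsius_to_kelvin(c(34, 38)), 0, 1,
                       celsius_to_kelvin(36), 3.5e5)
  tf2 <- fit_thermal_transition(c(34, 38), fr2, f0_fixed = 0, fmax_fixed = 1)
  expect_equal(tf2$Tm_C, 36, tolerance = 1e-3)
  # midpoint outside the sampled range raises the extrapolation flag
  frx <- thermal_model(celsius_to_kelvin(Tg), 0, 1,
                       celsius_to_kelvin(46), 3.5e5)
  tfx <- fit_thermal_transition(Tg, frx, f0_fixed = 0, fmax_fixed = 1)
  expect_true(tfx$outside_sampled_range)
})

test_that("dH is labelled apparent, never as an unfolding enthalpy", {
  Tg <- seq(20, 42, length.out = 8)
  fr <- thermal_model(celsius_to_kelvin(Tg), 0, 1,
                      celsius_to_kelvin(36.15), 3.5e5)
  tf <- fit_thermal_transition(Tg, fr)
  expect_match(tf$note, "apparent")
  expect_match(paste(capture.output(print(tf)), collapse = " "), "apparent")
})

test_that("noise-free kinetics recover the rate essentially exactly", {
  tt <- c(10, 30, 60, 100, 300, 600, 1000)
  f <- exp(-0.018 * tt)
  kf <- fit_kinetics(tt, f)
  expect_true(kf$converged)
  expect_equal(kf$k_per_s, 0.018, tolerance = 1e-9)
  expect_equal(kf$f_start, 1, tolerance = 1e-8)
  expect_equal(kf$f_end, 0, tolerance = 1e-8)
  # rising orientation inferred from the data
  kr <- fit_kinetics(tt, 1 - exp(-0.0028 * tt))
  expect_equal(kr$k_per_s, 0.0028, tolerance = 1e-8)
  expect_lt(kr$f_start, kr$f_end)
  expect_error(fit_kinetics(tt, rep(0.5, 7)), "identical|decay")
  expect_error(fit_kinetics(c(10, 30, 60), exp(-0.01 * c(10, 30, 60))),
               "4 distinct")
})

test_that("noisy kinetics recover k within 10% (median over 20 seeds)", {
  tt <- c(10, 30, 60, 100, 300, 600, 1000)
  for (k_true in c(0.0028, 0.018)) {
    errs <- vapply(1:20, function(s) withr::with_seed(2000L + s, {
      f <- exp(-k_true * tt) + stats::rnorm(7, sd = 0.02)
      abs(fit_kinetics(tt, f)$k_per_s - k_true) / k_true
    }), numeric(1))
    expect_lt(stats::median(errs), 0.10)
  }
})

test_that("Arrhenius regression matches the closed form and a grid oracle", {
  # two points: Ea = R * T1 * T2 / (T2 - T1) * ln(k2 / k1)
  af <- arrhenius_fit(c(300, 310), c(1e-3, exp(1) * 1e-3))
  expect_equal(af$Ea_J_mol, GAS_CONSTANT * 300 * 310 / 10, tolerance = 1e-9)
  expect_equal(af$Ea_J_mol / 1000, 77.32, tolerance = 1e-4)
  # Ea = -slope * R exactly for the stored slope
  expect_equal(af$Ea_J_mol, -af$slope * GAS_CONSTANT)
  # equal rates: zero activation energy (perfect-fit warning from lm is fine)
  expect_equal(suppressWarnings(
    arrhenius_fit(c(300, 310, 320), rep(2e-3, 3))$Ea_J_mol), 0,
    tolerance = 1e-9)
  # >= 3 points: slope agrees with a brute-force grid search
  Tk <- c(35, 37, 39, 42) + 273.15
  k <- c(0.0028, 0.0038, 0.011, 0.018)
  af4 <- arrhenius_fit(Tk, k)
  s_grid <- slope_grid_search(1 / Tk, log(k), lo = -6e4, hi = -1e4)
  expect_equal(af4$slope, s_grid, tolerance = 1e-6 * abs(af4$slope))
  expect_error(arrhenius_fit(c(300, 310), c(1e-3, -1e-3)), "> 0")
  expect_error(arrhenius_fit(c(300, 300), c(1e-3, 2e-3)), "distinct")
})
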