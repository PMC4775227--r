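test_that("single-component limits put the envelope centroid on the component", {
  # scenarios whose peak grid is symmetric about the relevant centroid, so
  # grid-truncation contributions cancel in the weighted mean
  centroid_of <- function(cl)
    sum(cl$peaks$mz * cl$peaks$intensity) / sum(cl$peaks$intensity)
  sc_lo <- exchange_scenario(charge = 1L, isotope_spacing = 1, n_peaks = 13L,
                             mz_start = 1000, centroid_low = 1006,
                             centroid_high = 1009, sigma_true = 0.6,
                             noise_rel = 0)
  expect_equal(centroid_of(simulate_isotope_envelope(sc_lo, 0)), 1006,
               tolerance = 1e-9)
  sc_hi <- exchange_scenario(charge = 1L, isotope_spacing = 1, n_peaks = 13L,
                             mz_start = 1000, centroid_low = 1002,
                             centroid_high = 1006, sigma_true = 0.6,
                             noise_rel = 0)
  expect_equal(centroid_of(simulate_isotope_envelope(sc_hi, 1)), 1006,
               tolerance = 1e-9)
  # symmetric mixture: centroid at the midpoint of the two centroids
  sc_mid <- exchange_scenario(charge = 1L, isotope_spacing = 1, n_peaks = 13L,
                              mz_start = 1000, centroid_low = 1004.5,
                              centroid_high = 1007.5, sigma_true = 0.6,
                              noise_rel = 0)
  expect_equal(centroid_of(simulate_isotope_envelope(sc_mid, 0.5)), 1006,
               tolerance = 1e-9)
  # the default (asymmetrically truncated) scenario is exact to 1e-4 m/z
  sc <- exchange_scenario(noise_rel = 0)
  expect_equal(centroid_of(simulate_isotope_envelope(sc, 0)),
               sc$centroid_low, tolerance = 1e-7)
  expect_equal(centroid_of(simulate_isotope_envelope(sc, 1)),
               sc$centroid_high, tolerance = 1e-7)
})

test_that("noise-free peak intensities sum to the total area within 1%", {
  sc <- exchange_scenario(noise_rel = 0, total_area = 1e5)
  dmz <- sc$isotope_spacing / sc$charge
  for (f in c(0, 0.3, 0.7, 1)) {
    cl <- simulate_isotope_envelope(sc, f)
    expect_lt(abs(sum(cl$peaks$intensity) - sc$total_area) / sc$total_area,
              0.01)
    expect_true(all(cl$peaks$intensity >= 0))
    expect_equal(diff(cl$peaks$mz), rep(dmz, sc$n_peaks - 1L))
  }
})

test_that("scenario validation names the offending field", {
  expect_error(exchange_scenario(sigma_true = -1), "sigma_true")
  expect_error(exchange_scenario(centroid_low = 1005, centroid_high = 1002),
               "centroid_low")
  expect_error(exchange_scenario(n_peaks = 4), "n_peaks")
  expect_error(exchange_scenario(noise_rel = NaN), "noise_rel")
  expect_error(exchange_scenario(condition_values = c(30, 30, 35)),
               "condition_values")
  expect_error(simulate_isotope_envelope(exchange_scenario(), 1.2),
               "fraction_high")
})

test_that("series fractions follow the declared law exactly", {
  # thermal midpoint identity: fraction 1/2 at T = Tm
  sc <- exchange_scenario(
    condition_values = c(30, 33, 36.15, 39, 42),
    fraction_law = thermal_law(f0 = 0, fmax = 1, Tm_C = 36.15,
                               dH_J_mol = 3.5e5),
    noise_rel = 0)
  ser <- simulate_series(sc)
  expect_equal(ser$true_fractions[3], 0.5)
  expect_true(all(ser$true_fractions >= 0 & ser$true_fractions <= 1))
  expect_equal(ser$true_fractions,
               thermal_model(celsius_to_kelvin(sc$condition_values), 0, 1,
                             celsius_to_kelvin(36.15), 3.5e5))
  # exponential initial condition: fraction f_start at t = 0
  sk <- exchange_scenario(
    condition_axis = "time_s", condition_values = c(0, 10, 100, 1000),
    fraction_law = exponential_law(k_per_s = 0.018, f_start = 1, f_end = 0),
    noise_rel = 0)
  serk <- simulate_series(sk)
  expect_equal(serk$true_fractions[1], 1)
  expect_equal(serk$true_fractions, exp(-0.018 * sk$condition_values))
})

test_that("thermal fraction matches direct evaluation of the transition law", {
  # f = e^x / (1 + e^x) with x = (T - Tm) * dH / (R * T * Tm)
  x <- (311.30 - 309.30) * 2.5e5 / (GAS_CONSTANT * 311.30 * 309.30)
  expect_equal(x, 0.6246, tolerance = 1e-4)
  f <- thermal_model(311.30, 0, 1, 309.30, 2.5e5)
  expect_equal(f, exp(x) / (1 + exp(x)), tolerance = 1e-12)
  expect_equal(f, 0.6513, tolerance = 1e-4)
})

test_that("axis/law mismatches are rejected", {
  expect_error(simulate_series(exchange_scenario(
    condition_axis = "time_s", condition_values = c(1, 10, 100),
    fraction_law = thermal_law())), "temperature")
  expect_error(simulate_series(exchange_scenario(
    fraction_law = exponential_law(0.018))), "time")
  expect_error(simulate_series(exchange_scenario(
    fraction_law = explicit_law(c(0.1, 0.9)))), "match")
})

test_that("generators are deterministic under a fixed seed", {
  sc <- exchange_scenario(noise_rel = 0.02, seed = 42L)
  s1 <- simulate_series(sc)
  s2 <- simulate_series(sc)
  expect_identical(s1$clusters, s2$clusters)

  bsc <- binding_scenario(seed = 7L)
  expect_identical(simulate_anisotropy(bsc)$data, simulate_anisotropy(bsc)$data)

  tsc <- tm_scenario(dimer_model(), seed = 11L)
  expect_identical(simulate_tm_dataset(tsc), simulate_tm_dataset(tsc))
})

test_that("anisotropy generator respects its limiting cases", {
  # all-inactive protein: anisotropy flat at r_min
  sc0 <- binding_scenario(noise_sd = 0,
                          conditions = data.frame(
                            label = "dead", active_fraction = 0,
                            top_trimer_nM = 1000))
  d0 <- simulate_anisotropy(sc0)$data
  expect_equal(d0$anisotropy, rep(sc0$r_min, nrow(d0)))
  # saturation: top of curve within 1% of r_max
  sc1 <- binding_scenario(noise_sd = 0,
                          conditions = data.frame(
                            label = "hot", active_fraction = 1,
                            top_trimer_nM = 1e5))
  d1 <- simulate_anisotropy(sc1)$data
  expect_lt(abs(max(d1$anisotropy) - sc1$r_max) / (sc1$r_max - sc1$r_min),
            0.01)
  # monotone non-decreasing in trimer concentration (quadratic model property)
  sc <- binding_scenario(noise_sd = 0)
  d <- simulate_anisotropy(sc)$data
  for (cd in unique(d$condition)) {
    di <- d[d$condition == cd, ]
    expect_true(all(diff(di$anisotropy[order(di$trimer_nM)]) >= -1e-12))
  }
})

test_that("Tm dataset generator matches the setpoint model", {
  m <- dimer_model(330, 53, 33)
  d0 <- simulate_tm_dataset(tm_scenario(m, concentrations_nM = 1e-6,
                                        noise_sd_C = 0))
  expect_equal(d0$Tm_C, 53, tolerance = 1e-4)
  # at c = Kd the unit-fraction of dimer is exactly 1/2
  dk <- simulate_tm_dataset(tm_scenario(m, concentrations_nM = 330,
                                        noise_sd_C = 0))
  expect_equal(dk$Tm_C, (53 + 33) / 2)
  expect_error(tm_scenario(m, concentrations_nM = c(-5, 10)),
               "concentrations_nM")
})
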