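test_that("the bimodal equation reduces to known single-Gaussian values", {
  # peak height of a lone component
  expect_equal(evaluate_bimodal(1000, A1 = 2, A2 = 0, mu1 = 1000, mu2 = 1003,
                                sigma = 0.4),
               2 / (0.4 * sqrt(2 * pi)))
  # standard normal density one sigma from the centroid
  expect_equal(evaluate_bimodal(1001, A1 = 1, A2 = 0, mu1 = 1000, mu2 = 1005,
                                sigma = 1),
               0.24197, tolerance = 1e-5)
  # equal areas contribute equally at the midpoint
  mid <- (1000 + 1003) / 2
  expect_equal(evaluate_bimodal(mid, 1, 1, 1000, 1003, 0.5),
               2 * 1 * stats::dnorm(mid, 1000, 0.5))
  # component exchange with label swap is a symmetry of the model
  mus <- seq(999, 1004, by = 0.25)
  expect_equal(evaluate_bimodal(mus, 1.3, 0.6, 1000, 1003, 0.5),
               evaluate_bimodal(mus, 0.6, 1.3, 1003, 1000, 0.5))
  expect_error(evaluate_bimodal(1000, 1, 1, 1000, 1003, -0.1), "sigma")
})

test_that("noise-free global fit recovers all generating parameters", {
  fr <- c(0.05, 0.2, 0.35, 0.5, 0.65, 0.8, 0.95)
  sc <- exchange_scenario(noise_rel = 0, fraction_law = explicit_law(fr))
  ser <- simulate_series(sc)
  fit <- fit_bimodal_series(ser)
  expect_true(fit$converged)
  expect_equal(fit$mu1_bar, TRUE_MU1, tolerance = 1e-6)
  expect_equal(fit$mu2_bar, TRUE_MU2, tolerance = 1e-6)
  expect_equal(fit$sigma, TRUE_SIGMA, tolerance = 1e-6)
  expect_equal(fit$per_spectrum$f_high, fr, tolerance = 1e-6)
  expect_true(fit$mu1_bar < fit$mu2_bar)
})

test_that("a pure low-exchanging series flags the high centroid unidentifiable", {
  sc <- exchange_scenario(noise_rel = 0,
                          fraction_law = explicit_law(rep(0, 7)))
  fit <- fit_bimodal_series(simulate_series(sc))
  expect_true(fit$mu2_unidentifiable)
  expect_false(fit$mu1_unidentifiable)
  expect_true(all(fit$per_spectrum$A2 / (fit$per_spectrum$A1 +
                                         fit$per_spectrum$A2) < 0.02))
})

test_that("per-spectrum areas agree with a dense grid-search oracle", {
  fr <- c(0.2, 0.5, 0.8)
  sc <- exchange_scenario(n_peaks = 12L, mz_start = 1000.4,
                          noise_rel = 0.02, seed = 5L,
                          condition_values = c(32, 36, 40),
                          fraction_law = explicit_law(fr))
  ser <- simulate_series(sc)
  fit <- fit_bimodal_series(ser)
  dmz <- sc$isotope_spacing / sc$charge
  for (s in seq_along(ser$clusters)) {
    cl <- ser$clusters[[s]]
    a_max <- 2 * sum(cl$peaks$intensity) * dmz
    sse_grid <- area_grid_sse(cl$peaks$mz, cl$peaks$intensity,
                              fit$mu1_bar, fit$mu2_bar, fit$sigma,
                              a_max = a_max, n = 161)
    expect_lt(fit$per_spectrum$sse[s], sse_grid * 1.01)
  }
})

test_that("peak splitting conserves intensity exactly and is scale invariant", {
  sc <- exchange_scenario(noise_rel = 0.02, seed = 3L)
  ser <- simulate_series(sc)
  fit <- fit_bimodal_series(ser)
  cl <- ser$clusters[[4]]
  sp <- split_peak_intensities(cl, fit)
  expect_identical(sp$peaks$intensity_low + sp$peaks$intensity_high,
                   cl$peaks$intensity)
  expect_true(sp$f_high >= 0 && sp$f_high <= 1)
  expect_equal(sp$f_low, 1 - sp$f_high)
  # uniform intensity rescaling leaves the fraction unchanged
  cl2 <- cl
  cl2$peaks$intensity <- cl$peaks$intensity * 37.5
  sp2 <- split_peak_intensities(cl2, fit)
  expect_equal(sp2$f_high, sp$f_high, tolerance = 1e-12)
})

test_that("splitting recovers the generating fraction and its limits", {
  # noise-free: fraction 0.30 back within 0.005
  sc <- exchange_scenario(noise_rel = 0,
                          fraction_law = explicit_law(c(0, 0.3, 1)),
                          condition_values = c(30, 36, 42))
  ser <- simulate_series(sc)
  fit <- fit_bimodal_series(ser)
  expect_equal(split_peak_intensities(ser$clusters[[2]], fit)$f_high, 0.3,
               tolerance = 0.005)
  # a spectrum with A2 = 0 has f_high = 0
  fit0 <- fit
  fit0$per_spectrum$A2[1] <- 0
  # peaks beyond the surviving component's tail are flagged
  expect_warning(sp0 <- split_peak_intensities(ser$clusters[[1]], fit0),
                 "50/50")
  expect_equal(sp0$f_high, 0)
  # equal areas and equal widths: the midway peak splits 50/50
  mid_fit <- fit
  mid_fit$per_spectrum$A1[2] <- 1
  mid_fit$per_spectrum$A2[2] <- 1
  mid_mz <- (fit$mu1_bar + fit$mu2_bar) / 2
  g1 <- stats::dnorm(mid_mz, fit$mu1_bar, fit$sigma)
  g2 <- stats::dnorm(mid_mz, fit$mu2_bar, fit$sigma)
  expect_equal(g1, g2, tolerance = 1e-12)
})

test_that("fractions are recovered within 0.03 MAE at 2% noise over 20 seeds", {
  maes <- vapply(1:20, function(s) {
    sc <- exchange_scenario(noise_rel = 0.02, seed = 1000L + s)
    ser <- simulate_series(sc)
    fit <- fit_bimodal_series(ser)
    expect_true(fit$converged)
    mean(abs(fit$per_spectrum$f_high - ser$true_fractions))
  }, numeric(1))
  expect_lt(mean(maes), 0.03)
})

test_that("series with mixed peptides or too-few peaks are rejected with names", {
  sc <- exchange_scenario(noise_rel = 0)
  a <- simulate_isotope_envelope(sc, 0.2, condition_value = 30)
  b <- simulate_isotope_envelope(sc, 0.8, condition_value = 40)
  b$peptide_id <- "159-168"
  expect_error(fit_bimodal_series(list(a, b)), "share peptide_id")
  expect_error(isotope_cluster("x", 2, "temperature_C", 30,
                               mz = c(1000, 1000.5, 1001),
                               intensity = c(1, 2, 1)),
               "fewer than 4 peaks")
})

test_that("centroid uptake maps controls to 0 and full deuteration, linearly", {
  sc <- exchange_scenario(noise_rel = 0)
  unex <- simulate_isotope_envelope(sc, 0)
  unex$condition_type <- "control"; unex$condition_value <- "unexchanged"
  full <- simulate_isotope_envelope(sc, 1)
  full$condition_type <- "control"; full$condition_value <- "fully_deuterated"
  n_ex <- 8
  expect_equal(centroid_uptake(unex, unex, full, n_ex)$corrected_deuterons, 0,
               tolerance = 1e-9)
  expect_equal(centroid_uptake(full, unex, full, n_ex)$corrected_deuterons,
               n_ex, tolerance = 1e-9)
  mid <- simulate_isotope_envelope(sc, 0.5)
  up <- centroid_uptake(mid, unex, full, n_ex)
  expect_equal(up$corrected_deuterons, n_ex / 2, tolerance = 1e-4)
  # raw deuterons are the charge-corrected centroid shift
  expect_equal(up$deuterons,
               (up$centroid - sum(unex$peaks$mz * unex$peaks$intensity) /
                  sum(unex$peaks$intensity)) * sc$charge)
  expect_error(centroid_uptake(mid, full, unex, n_ex), "exceed")
})

test_that("uptake differences vanish at the reference and add SEMs in quadrature", {
  up <- data.frame(peptide_id = rep(c("p1", "p2"), each = 6),
                   condition_value = rep(rep(c(20, 30, 40), each = 2), 2),
                   replicate_id = rep(c("a", "b"), 6),
                   uptake = c(1.0, 1.2, 2.0, 2.2, 3.0, 3.2,
                              0.5, 0.5, 0.8, 0.9, 1.5, 1.4))
  d <- uptake_difference(up, reference_condition = 20)
  ref_rows <- d[d$condition_value == 20, ]
  expect_equal(ref_rows$delta_uptake, c(0, 0))
  # two replicates with SEM 0.1 each: quadrature gives sqrt(0.02)
  pre <- data.frame(peptide_id = "p", condition_value = c(20, 40),
                    uptake = c(0, 1), sem = c(0.1, 0.1))
  d2 <- uptake_difference(pre, 20)
  expect_equal(d2$sem_delta[d2$condition_value == 40], sqrt(0.02),
               tolerance = 1e-12)
  expect_error(uptake_difference(up[up$condition_value != 20, ], 20),
               "reference")
})

test_that("a rising-fraction peptide shows positive uptake differences", {
  sc <- exchange_scenario(noise_rel = 0, condition_values = c(20, 30, 36, 42),
                          fraction_law = thermal_law())
  ser <- simulate_series(sc)
  unex <- simulate_isotope_envelope(sc, 0)
  unex$condition_type <- "control"; unex$condition_value <- "unexchanged"
  full <- simulate_isotope_envelope(sc, 1)
  full$condition_type <- "control"; full$condition_value <- "fully_deuterated"
  up <- do.call(rbind, lapply(ser$clusters, function(cl)
    data.frame(peptide_id = cl$peptide_id,
               condition_value = as.numeric(cl$condition_value),
               uptake = centroid_uptake(cl, unex, full, 8)$corrected_deuterons,
               sem = 0.01)))
  d <- uptake_difference(up, 20)
  expect_true(all(d$delta_uptake[d$condition_value > 20] > 0))
})
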