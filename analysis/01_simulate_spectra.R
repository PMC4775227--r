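#!/usr/bin/env Rscript
# Stage 1: generate the synthetic HDX-MS datasets the rest of the analysis
# consumes. Because no raw spectra are deposited with the study, every
# downstream stage runs on synthetic isotope clusters whose subpopulation
# structure follows the fitted laws: a thermal two-state transition for the
# temperature series and single-exponential kinetics for the heat-shock time
# courses at four temperatures.

library(hdxtherm)

out <- "results"
dir.create(out, showWarnings = FALSE)
seed <- 20160623L

# temperature series: 7 pre-incubation temperatures spanning the transition
thermal_sc <- exchange_scenario(peptide_id = "378-395",
                                fraction_law = thermal_law(),
                                noise_rel = 0.02, seed = seed)
thermal_series <- simulate_series(thermal_sc)
write_spectra(thermal_series, file.path(out, "spectra_thermal.csv"))
write_truth(thermal_series, file.path(out, "truth_thermal.json"))
cat(sprintf("thermal series: %d spectra at %s C (true fractions %.3f-%.3f)\n",
            length(thermal_series$clusters),
            paste(thermal_sc$condition_values, collapse = "/"),
            min(thermal_series$true_fractions),
            max(thermal_series$true_fractions)))

# kinetic series: the measured time grid at each heat-shock temperature,
# with the published region-averaged rate for the repressor region
rates <- c("35" = 0.0028, "37" = 0.0038, "39" = 0.011, "42" = 0.018)
tt <- c(10, 30, 60, 100, 300, 600, 1000)
for (i in seq_along(rates)) {
  sc <- exchange_scenario(peptide_id = "378-395",
                          condition_axis = "time_s", condition_values = tt,
                          fraction_law = exponential_law(
                            k_per_s = rates[[i]], f_start = 0, f_end = 1),
                          noise_rel = 0.02, seed = seed + i)
  ser <- simulate_series(sc)
  f <- file.path(out, sprintf("spectra_kinetic_%sC.csv", names(rates)[i]))
  write_spectra(ser, f)
  write_truth(ser, sub("spectra", "truth", sub("csv$", "json", f)))
  cat(sprintf("kinetic series at %s C: k_true = %.4f 1/s, %d time points\n",
              names(rates)[i], rates[[i]], length(tt)))
}
cat("done: synthetic spectra written under", out, "\n")
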