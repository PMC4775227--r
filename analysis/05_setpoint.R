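#!/usr/bin/env Rscript
# Stage 5: the concentration setpoint model. Fits the monomer-dimer
# mass-action model to synthetic (concentration, Tm) data, simulates the
# chaperone-like parameter variants, and computes the cellular concentration
# arithmetic that places the setpoint in the physiological range.

library(hdxtherm)

out <- "results"
seed <- 20160625L

truth <- dimer_model(kd_dim_nM = 330, tm_monomer_C = 53, tm_dimer_C = 33)
d <- simulate_tm_dataset(tm_scenario(truth, noise_sd_C = 0.3, seed = seed))
write.table(d, file.path(out, "tm_vs_concentration.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

fit <- fit_dimer_model(d$concentration_nM, d$Tm_C)
write_report(fit, file.path(out, "fit_dimer_model.json"))
cat(sprintf(paste0("monomer-dimer fit: Kd = %.0f +/- %.0f nM, ",
                   "Tm,M = %.1f C, Tm,D = %.1f C (true 330 / 53 / 33)\n"),
            fit$kd_dim_nM, fit$se_kd_dim_nM, fit$tm_monomer_C,
            fit$tm_dimer_C))
if (fit$low_conc_caveat)
  cat("  note: no data below Kd/3; the fit is sensitive to low concentrations\n")

# chaperone-like variants: lower dimerization Kd alone, or together with a
# destabilized dimer
curves <- simulate_variants(
  as_dimer_model(fit),
  variants = list(kd_100 = list(kd_dim_nM = 100),
                  kd_200_tmD_29 = list(kd_dim_nM = 200, tm_dimer_C = 29)))
write.table(curves, file.path(out, "setpoint_variant_curves.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("variant curves written for:", paste(unique(curves$variant),
                                         collapse = ", "), "\n")

# cellular arithmetic: cytosolic abundance bounds and nuclear enrichment
lo <- cellular_setpoint(4, cytosolic_nM = 10, model = truth)
hi <- cellular_setpoint(17, cytosolic_nM = 130, model = truth)
cat(sprintf(paste0("cytosolic 10-130 nM -> predicted Tm %.1f-%.1f C; ",
                   "nuclear enrichment gives local %g-%g nM ",
                   "(Tm %.1f-%.1f C)\n"),
            hi$predicted_Tm_cytosolic_C, lo$predicted_Tm_cytosolic_C,
            lo$local_nM, hi$local_nM,
            hi$predicted_Tm_local_C, lo$predicted_Tm_local_C))
write_report(list(cytosolic_low = lo, cytosolic_high = hi),
             file.path(out, "cellular_setpoint.json"))
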