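#!/usr/bin/env Rscript
# Stage 5: phenotype statistics. Host-range susceptibility counting from
# the published assay table, an EOP worked example, thermal-stability
# fold reduction, and latent period / burst size from the simulated
# one-step growth curve.

suppressMessages(library(phagekit))
dir.create("results", showWarnings = FALSE)

tab <- kpp105_host_range()
kp <- "Klebsiella pneumoniae"
n_kp <- sum(tab$species == kp)
n_susc <- count_susceptible(tab, kp)
message(sprintf("host range: %d of %d K. pneumoniae strains susceptible",
                n_susc, n_kp))
message(sprintf("non-Klebsiella susceptible: %d",
                count_susceptible(tab[tab$species != kp, ])))

e <- eop(c(50, 60, 70), c(100, 110, 90))
message(sprintf("worked EOP example: %.1f%% +/- %.1f", e["eop_percent"],
                e["sd_percent"]))

fold <- fold_reduction(8.5, 5.3)
message(sprintf("thermal stability 50 degC/60 min: %.0f-fold (~%s)",
                fold, format_fold(fold)))

curve_df <- utils::read.csv("results/simulated/growth_curve.csv")
gr <- growth_curve_analysis(growth_curve(curve_df$time_min,
                                         curve_df$pfu_per_ml))
message(sprintf(paste0("growth curve: latent %.0f min, burst period ",
                       "%.0f-%.0f min, burst size %.0f PFU/cell"),
                gr$latent_min, gr$burst_period["start"],
                gr$burst_period["end"], gr$burst_size))

jsonlite::write_json(
  list(susceptible_kpneumoniae = n_susc, total_kpneumoniae = n_kp,
       thermal_fold_reduction = fold,
       latent_min = gr$latent_min,
       burst_size = gr$burst_size,
       burst_period = unname(gr$burst_period)),
  "results/phenotype_summary.json", auto_unbox = TRUE, pretty = TRUE)
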