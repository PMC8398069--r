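#!/usr/bin/env Rscript

# Stage 2 -- per-plot curve fits.
#
# Fits the three-phase canopy development curve to every plot's weekly
# soil-cover series and the Gaussian size-distribution curve to every
# plot's tuber weight and number class tables, then checks parameter
# recovery against the simulation truth.

suppressPackageStartupMessages(library(cdvqtl))

canopy <- read_tsv("scratch/analysis/canopy_series.tsv")
tubers <- read_tsv("scratch/analysis/tuber_classes.tsv")
truth <- read_tsv("scratch/analysis/truth_canopy_params.tsv")

message("Fitting canopy curves for ", length(unique(canopy$plot_id)),
        " plots ...")
cf <- fit_canopy_plots(canopy)
write_tsv(cf, "scratch/analysis/canopy_fits.tsv")
message("  converged: ", sum(cf$converged), "/", nrow(cf))

m <- merge(truth, cf, by = "plot_id", suffixes = c(".true", ".fit"))
rec <- sapply(c("t2", "te", "Vx"), function(p) {
  median(abs(m[[paste0(p, ".true")]] - m[[paste0(p, ".fit")]]), na.rm = TRUE)
})
message("  median |error|: t2 ", round(rec["t2"], 2), " td, te ",
        round(rec["te"], 2), " td, Vx ", round(rec["Vx"], 2), " %SC")

message("Fitting tuber distribution curves ...")
tf <- fit_bell_plots(tubers)
write_tsv(tf, "scratch/analysis/tuber_fits.tsv")
message("  converged: ", sum(tf$converged), "/", nrow(tf))

write_tsv(data.frame(stat = c("canopy_converged", "median_abs_err_t2",
                              "median_abs_err_te", "median_abs_err_Vx",
                              "tuber_converged"),
                     value = c(mean(cf$converged), rec, mean(tf$converged))),
          "results/02_fit_quality.tsv")
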