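#!/usr/bin/env Rscript

# Stage 3 -- standardised plot-level traits.
#
# Combines the curve parameters with the harvest data into the full
# plot-level trait table: canopy parameters and areas, tuber
# distribution parameters, dry-matter yield and the nitrogen-efficiency
# ratios (NUE, NUtE, NUptE), and the soil-coverage yield index.

suppressPackageStartupMessages(library(cdvqtl))

plots <- read_tsv("scratch/analysis/plots.tsv")
cf <- read_tsv("scratch/analysis/canopy_fits.tsv")
tf <- read_tsv("scratch/analysis/tuber_fits.tsv")
harvest <- read_tsv("scratch/analysis/harvest.tsv")

agro <- with(harvest, compute_agronomic(
  fresh_yield_kg_m2, dm_pct, n_conc_g_kg, n_input_g_m2(n_input_kg_ha),
  cf$AUC[match(plot_id, cf$plot_id)]))
agro$plot_id <- harvest$plot_id

pt <- merge(plots, cf, by = "plot_id")
pt <- merge(pt, tf[, c("plot_id", "TbwA", "TbwB", "TbwMX", "TbnA", "TbnB",
                       "TbnMX")], by = "plot_id")
pt <- merge(pt, agro, by = "plot_id")
write_tsv(pt, "scratch/analysis/plot_traits.tsv")

message("Plot trait table: ", nrow(pt), " plots x ",
        ncol(pt) - 8, " trait columns")
by_lev <- aggregate(cbind(Y_DM, NUE, AUC) ~ n_level, pt, mean)
print(by_lev)
write_tsv(by_lev, "results/03_trait_means_by_N.tsv")
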