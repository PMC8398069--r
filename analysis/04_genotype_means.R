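#!/usr/bin/env Rscript

# Stage 4 -- genotype values from the split-plot mixed model.
#
# Fits, per nitrogen level and trait, the two-year model
# Y = yr + Mt + yr.Mt + Mt.G + yr.row + yr.col + E, exports the four
# year x N genotype datasets (BLUP-based per-year predictions) plus
# maturity-corrected variants, and summarises the genetic correlation
# structure (per-level matrices, cross-N diagonal, Ward dendrograms and
# a Mantel comparison of the two matrices).

suppressPackageStartupMessages(library(cdvqtl))

pt <- read_tsv("scratch/analysis/plot_traits.tsv")

use_traits <- c("tm1", "t1", "t2", "te", "Vx", "t2_t1", "te_t2", "Cm",
                "AP1", "AP2", "AP3", "AUC", "TbwA", "TbwB", "TbwMX",
                "TbnA", "TbnB", "TbnMX", "Y_DM", "NUpt", "NUE", "NUtE",
                "NUptE", "SCYi", "mt_as")

groups <- NULL
blues <- list()
for (lev in c("HN", "LN")) {
  per_year <- NULL
  blue_tab <- NULL
  for (tr in use_traits) {
    fit <- tryCatch(fit_eq2(pt, tr, lev), error = function(e) NULL)
    if (is.null(fit)) { message("  skipped ", tr, " at ", lev); next }
    groups <- fit$groups
    py <- fit$per_year; names(py)[3] <- tr
    per_year <- if (is.null(per_year)) py else
      merge(per_year, py, by = c("genotype", "year"))
    bl <- data.frame(genotype = names(fit$blue), v = unname(fit$blue))
    names(bl)[2] <- tr
    blue_tab <- if (is.null(blue_tab)) bl else merge(blue_tab, bl,
                                                     by = "genotype")
  }
  blues[[lev]] <- blue_tab
  for (yr in unique(per_year$year)) {
    d <- per_year[per_year$year == yr, names(per_year) != "year"]
    write_tsv(d, sprintf("scratch/analysis/dataset_%s_%s.tsv", yr, lev))
    dc <- maturity_correct(d, groups)
    write_tsv(dc, sprintf("scratch/analysis/dataset_%s_%s_corrected.tsv",
                          yr, lev))
  }
}
write_tsv(data.frame(genotype = names(groups), maturity_group = groups),
          "scratch/analysis/maturity_groups.tsv")

message("Genetic correlation structure over BLUEs ...")
gc <- genetic_correlations(blues$HN, blues$LN)
cross <- data.frame(trait = names(gc$cross_N), r_HN_LN = unname(gc$cross_N))
write_tsv(cross, "results/04_cross_N_correlations.tsv")

hc_hn <- cluster_traits(gc$corr_HN)
hc_ln <- cluster_traits(gc$corr_LN)
message("  HN dendrogram first merges: ",
        paste(head(hc_hn$labels[-hc_hn$merge[1, ]], 2), collapse = " + "))

keep <- setdiff(colnames(gc$corr_HN), c("NUE", "NUtE", "NUptE"))
mt <- mantel_test(gc$corr_HN[keep, keep], gc$corr_LN[keep, keep],
                  n_perm = 999, seed = 2021)
message(sprintf("  Mantel r = %.4f (p = %.3f) between HN and LN matrices",
                mt$r, mt$p))
write_tsv(data.frame(stat = c("mantel_r", "mantel_p"),
                     value = c(mt$r, mt$p)),
          "results/04_mantel.tsv")
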