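#!/usr/bin/env Rscript

# Stage 1 -- generate the synthetic trial.
#
# Builds the "full" scenario: 169 tetraploid cultivars genotyped at 2000
# SNPs on 12 chromosomes with 3 subpopulations (Fst 0.1), a large-effect
# maturity locus on chromosome 5 mediating the canopy and agronomic
# traits, six scattered nitrogen-dependent tuber/dry-matter QTLs, and a
# two-year split-plot experiment at 180 (HN) and 75 (LN) kg available
# N/ha. Bulky raw observations go to scratch/analysis/; small summaries
# to results/.

suppressPackageStartupMessages(library(cdvqtl))

seed <- 2021
dir.create("scratch/analysis", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

message("Simulating the full scenario (seed ", seed, ") ...")
sc <- scenario("full", seed = seed, experiment = TRUE)

ex <- sc$experiment
write_tsv(ex$plots, "scratch/analysis/plots.tsv")
write_tsv(ex$canopy, "scratch/analysis/canopy_series.tsv")
write_tsv(ex$tubers, "scratch/analysis/tuber_classes.tsv")
write_tsv(ex$harvest, "scratch/analysis/harvest.tsv")
write_tsv(ex$truth_params, "scratch/analysis/truth_canopy_params.tsv")

# dosage matrix in marker-rows orientation plus the marker map
panel <- sc$genotypes$panel
dos <- data.frame(marker = colnames(panel$dosages),
                  t(panel$dosages), check.names = FALSE)
write_tsv(dos, "scratch/analysis/dosages.tsv")
write_tsv(panel$map, "scratch/analysis/marker_map.tsv")

truth <- data.frame(genotype = names(sc$arch$groups),
                    maturity_group = sc$arch$groups,
                    maturity_score = sc$arch$score)
write_tsv(truth, "scratch/analysis/truth_genotypes.tsv")
planted <- do.call(rbind, lapply(seq_along(sc$config$qtls), function(i) {
  q <- sc$config$qtls[[i]]
  data.frame(trait = q$trait, chrom = q$chrom, pos_bp = q$pos_bp,
             var_frac = q$var_frac, n_dependence = q$n_dependence,
             marker = sc$arch$qtl_markers[i])
}))
write_tsv(planted, "results/01_planted_qtls.tsv")

message("Plots: ", nrow(ex$plots), " (", sum(ex$plots$is_reference),
        " reference) over ", length(unique(ex$plots$year)), " years")
message("Markers: ", ncol(panel$dosages), "; planted trait QTLs: ",
        nrow(planted), "; maturity locus at ", sc$arch$locus_marker)
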