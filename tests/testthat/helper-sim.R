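# Shared generators for small synthetic inputs used across test files.

small_panel <- function(seed = 1, n_genotypes = 60, n_markers = 240) {
  cfg <- sim_config(n_genotypes = n_genotypes, n_markers = n_markers,
                    traits = list())
  simulate_genotypes(cfg, seed)$panel
}

# balanced two-year field table with known genotype means and no noise
balanced_plots <- function(genotype_means, groups, year_effects = c(0.5, -0.5),
                           n_level = "HN", noise_sd = 0) {
  genos <- names(genotype_means)
  grid <- expand.grid(genotype = genos, year = c(2009, 2010),
                      stringsAsFactors = FALSE)
  grid$maturity_group <- groups[grid$genotype]
  grid$n_level <- n_level
  grid$row <- rep(seq_along(genos), 2) %% 6 + 1
  grid$col <- rep(seq_along(genos), 2) %% 5 + 1
  grid$is_reference <- FALSE
  grid$plot_id <- sprintf("P%03d", seq_len(nrow(grid)))
  ye <- ifelse(grid$year == 2009, year_effects[1], year_effects[2])
  grid$y <- genotype_means[grid$genotype] + ye +
    stats::rnorm(nrow(grid), 0, noise_sd)
  grid
}

# dosage panel built from an explicit dosage matrix with a uniform map
panel_from_matrix <- function(dos, chrom = NULL, pos = NULL) {
  p <- ncol(dos)
  if (is.null(colnames(dos))) colnames(dos) <- sprintf("m%03d", seq_len(p))
  if (is.null(rownames(dos))) rownames(dos) <- sprintf("G%03d", seq_len(nrow(dos)))
  map <- data.frame(marker = colnames(dos),
                    chrom = if (is.null(chrom)) rep(1L, p) else chrom,
                    pos_bp = if (is.null(pos)) seq_len(p) * 1e5 else pos)
  dosage_panel(dos, map)
}
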