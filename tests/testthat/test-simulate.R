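test_that("genotype simulation is reproducible and well-formed", {
  cfg <- sim_config(n_genotypes = 40, n_markers = 120, traits = list())
  a <- simulate_genotypes(cfg, 99)
  b <- simulate_genotypes(cfg, 99)
  expect_identical(a$panel$dosages, b$panel$dosages)
  expect_identical(a$panel$map, b$panel$map)
  vals <- a$panel$dosages[!is.na(a$panel$dosages)]
  expect_true(all(vals %in% 0:4))
  expect_equal(length(unique(a$panel$map$chrom)), 12)
  for (ch in 1:12) {
    expect_false(is.unsorted(a$panel$map$pos_bp[a$panel$map$chrom == ch]))
  }
})

test_that("simulated differentiation matches the configured Fst", {
  cfg <- sim_config(n_genotypes = 150, n_markers = 600, fst = 0.1,
                    missing_rate = 0, traits = list())
  sim <- simulate_genotypes(cfg, 77)
  dos <- sim$panel$dosages
  sp <- sim$truth$subpop
  # method-of-moments estimate over markers: between-subpop variance of
  # allele frequencies relative to p(1-p)
  num <- 0; den <- 0
  for (j in seq_len(ncol(dos))) {
    ps <- tapply(dos[, j], sp, mean) / 4
    pbar <- mean(ps)
    if (pbar <= 0.02 || pbar >= 0.98) next
    num <- num + var(ps)
    den <- den + pbar * (1 - pbar)
  }
  fst_hat <- num / den
  expect_gt(fst_hat, 0.05)
  expect_lt(fst_hat, 0.15)
})

test_that("a vanishing Fst removes the subpopulation signal", {
  cfg <- sim_config(n_genotypes = 90, n_markers = 300, fst = 0.005,
                    missing_rate = 0, traits = list())
  sim <- simulate_genotypes(cfg, 78)
  # the moment estimator should collapse towards its sampling floor
  dos <- sim$panel$dosages
  sp <- sim$truth$subpop
  num <- 0; den <- 0
  for (j in seq_len(ncol(dos))) {
    ps <- tapply(dos[, j], sp, mean) / 4
    pbar <- mean(ps)
    if (pbar <= 0.02 || pbar >= 0.98) next
    num <- num + var(ps)
    den <- den + pbar * (1 - pbar)
  }
  expect_lt(num / den, 0.05)
})

test_that("the maturity locus drives the score and the group binning", {
  cfg <- sim_config(n_genotypes = 169, n_markers = 400, traits = list(),
                    maturity_locus = list(chrom = 5, pos_bp = 40e6, h2 = 0.5))
  sim <- simulate_genotypes(cfg, 61)
  arch <- simulate_architecture(sim, cfg, 62)
  i <- match(arch$locus_marker, sim$panel$map$marker)
  expect_equal(sim$panel$map$chrom[i], 5)
  dos <- sim$panel$dosages[, i]
  dos[is.na(dos)] <- mean(dos, na.rm = TRUE)
  expect_gt(abs(cor(arch$score, dos)), 0.5)
  expect_setequal(unique(arch$groups), c("E", "M", "L"))
  expect_equal(max(table(arch$groups)) - min(table(arch$groups)) <= 1, TRUE)
})

test_that("a silent maturity locus leaves groups independent of chromosome 5", {
  cfg <- sim_config(n_genotypes = 169, n_markers = 400, traits = list(),
                    maturity_locus = list(chrom = 5, pos_bp = 40e6, h2 = 0))
  sim <- simulate_genotypes(cfg, 63)
  arch <- simulate_architecture(sim, cfg, 64)
  i <- match(arch$locus_marker, sim$panel$map$marker)
  dos <- sim$panel$dosages[, i]
  dos[is.na(dos)] <- mean(dos, na.rm = TRUE)
  expect_lt(abs(cor(arch$score, dos)), 0.25)
})

test_that("a pure polygenic trait is shared across N levels at heritability one", {
  cfg <- sim_config(n_genotypes = 100, n_markers = 300,
                    traits = list(pg = list(maturity_frac = 0,
                                            polygenic_h2 = 1)))
  sim <- simulate_genotypes(cfg, 65)
  arch <- simulate_architecture(sim, cfg, 66)
  expect_equal(arch$values$HN$pg, arch$values$LN$pg)
  expect_equal(sd(arch$values$HN$pg), 1, tolerance = 1e-6)
})

test_that("a planted N-dependent QTL appears only at its nitrogen level", {
  cfg <- sim_config(
    n_genotypes = 169, n_markers = 400,
    traits = list(tr = list(maturity_frac = 0, polygenic_h2 = 0.2)),
    qtls = list(list(chrom = 3, pos_bp = 30e6, trait = "tr",
                     var_frac = 0.25, n_dependence = "HN")))
  sim <- simulate_genotypes(cfg, 67)
  arch <- simulate_architecture(sim, cfg, 68)
  i <- match(arch$qtl_markers[1], sim$panel$map$marker)
  dos <- sim$panel$dosages[, i]
  dos[is.na(dos)] <- mean(dos, na.rm = TRUE)
  r2_hn <- summary(lm(arch$values$HN$tr ~ dos))$r.squared
  r2_ln <- summary(lm(arch$values$LN$tr ~ dos))$r.squared
  expect_gt(r2_hn, 0.12)
  expect_lt(r2_ln, 0.08)
  expect_error(
    simulate_architecture(sim, sim_config(
      n_genotypes = 169, n_markers = 400,
      traits = list(tr = list()),
      qtls = list(list(chrom = 14, pos_bp = 1e6, trait = "tr",
                       var_frac = 0.1))), 68),
    "off the map")
})

test_that("the field experiment honours the design and value bounds", {
  sc <- scenario("full", seed = 31, n_genotypes = 24, n_markers = 120,
                 experiment = TRUE)
  ex <- sc$experiment
  expect_true(all(ex$canopy$cover >= 0 & ex$canopy$cover <= 100))
  real <- ex$plots[!ex$plots$is_reference, ]
  combos <- table(real$genotype, paste(real$year, real$n_level))
  expect_true(all(combos == 1))          # every genotype in every year x N
  expect_equal(sum(ex$plots$is_reference),
               sum(sc$config$n_reference_plots))
  expect_true(all(ex$tubers$weight_kg >= 0))
  expect_true(all(ex$harvest$fresh_yield_kg_m2 > 0))
  expect_true(all(ex$plots$mt_as >= 1 & ex$plots$mt_as <= 8))
})

test_that("noise-free observations round-trip through the canopy fit", {
  cfg <- sim_config(n_genotypes = 9, n_markers = 60,
                    traits = list(t2 = list(polygenic_h2 = 0.5)),
                    canopy_sd = 0, tuber_cv = 0, harvest_cv = 0,
                    row_sd = 0, col_sd = 0, plot_sd = 0,
                    n_reference_plots = c(1, 1))
  sim <- simulate_genotypes(cfg, 81)
  arch <- simulate_architecture(sim, cfg, 82)
  ex <- simulate_experiment(arch, cfg, 83)
  fits <- fit_canopy_plots(ex$canopy)
  m <- merge(ex$truth_params, fits, by = "plot_id",
             suffixes = c(".true", ".fit"))
  expect_true(all(m$converged))
  expect_lt(max(abs(m$t2.true - m$t2.fit)), 0.05)
  expect_lt(max(abs(m$te.true - m$te.fit)), 0.05)
  expect_lt(max(abs(m$Vx.true - m$Vx.fit)), 0.05)
})

test_that("plot parameters are recovered within field accuracy at default noise", {
  sc <- scenario("full", seed = 32, n_genotypes = 20, n_markers = 120,
                 experiment = TRUE)
  fits <- fit_canopy_plots(sc$experiment$canopy)
  m <- merge(sc$experiment$truth_params, fits, by = "plot_id",
             suffixes = c(".true", ".fit"))
  expect_lt(median(abs(m$t2.true - m$t2.fit), na.rm = TRUE), 2)
  expect_lt(median(abs(m$te.true - m$te.fit), na.rm = TRUE), 2)
  expect_lt(median(abs(m$Vx.true - m$Vx.fit), na.rm = TRUE), 3)
})

test_that("unknown scenario names are rejected", {
  expect_error(scenario("banana"), "arg")
})
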