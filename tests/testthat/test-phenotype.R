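test_that("BLUEs recover true genotype means on balanced noiseless data", {
  mu <- setNames(seq(4, 9.5, by = 0.5), sprintf("g%02d", 1:12))
  groups <- setNames(rep(c("E", "M", "L"), each = 4), names(mu))
  plots <- balanced_plots(mu, groups, year_effects = c(0.5, -0.5))
  fit <- fit_eq2(plots, "y", "HN")
  # year effects average out across the two balanced years
  expect_equal(unname(fit$blue[names(mu)]), unname(mu), tolerance = 1e-8)
  expect_equal(fit$groups[names(mu)], groups)
})

test_that("per-year predictions carry the year main effect", {
  mu <- setNames(rnorm(12, 6), sprintf("g%02d", 1:12))
  groups <- setNames(rep(c("E", "M", "L"), each = 4), names(mu))
  set.seed(2)
  plots <- balanced_plots(mu, groups, year_effects = c(1, -1), noise_sd = 0.1)
  fit <- fit_eq2(plots, "y", "HN")
  py <- fit$per_year
  expect_equal(sort(unique(py$year)), c("2009", "2010"))
  gap <- mean(py$value[py$year == "2009"]) - mean(py$value[py$year == "2010"])
  expect_equal(gap, 2, tolerance = 0.2)
})

test_that("REML recovers spatial and residual variance components", {
  set.seed(9)
  mu <- setNames(rnorm(30, 10, 1), sprintf("g%02d", 1:30))
  groups <- setNames(rep(c("E", "M", "L"), each = 10), names(mu))
  est <- replicate(60, {
    plots <- balanced_plots(mu, groups, noise_sd = 0)
    re <- rnorm(max(plots$row), 0, 1)
    plots$y <- plots$y + re[plots$row] + rnorm(nrow(plots), 0, 1)
    fit_eq2(plots, "y", "HN")$varcomp[c("yr_row", "residual")]
  })
  m <- rowMeans(est)
  se <- apply(est, 1, sd) / sqrt(ncol(est))
  # Monte-Carlo confidence intervals cover the simulated variances (1, 1)
  expect_lt(abs(m["yr_row"] - 1), 3 * se["yr_row"] + 0.15)
  expect_lt(abs(m["residual"] - 1), 3 * se["residual"] + 0.15)
})

test_that("a constant trait yields zero genetic variance", {
  mu <- setNames(rep(5, 12), sprintf("g%02d", 1:12))
  groups <- setNames(rep(c("E", "M", "L"), each = 4), names(mu))
  plots <- balanced_plots(mu, groups, year_effects = c(0, 0))
  fit <- fit_eq2(plots, "y", "HN")
  expect_true(all(fit$blue == 5))
  expect_true(all(fit$blup == 5))
  expect_equal(unname(fit$varcomp["genotype"]), 0)
})

test_that("a genotype in two maturity groups is rejected", {
  mu <- setNames(rnorm(12, 6), sprintf("g%02d", 1:12))
  groups <- setNames(rep(c("E", "M", "L"), each = 4), names(mu))
  plots <- balanced_plots(mu, groups)
  plots$maturity_group[plots$genotype == "g01" & plots$year == 2010] <- "L"
  expect_error(fit_eq2(plots, "y", "HN"), "more than one maturity group")
})

test_that("maturity correction equalises group means and keeps within-group structure", {
  genos <- sprintf("g%02d", 1:9)
  groups <- setNames(rep(c("E", "M", "L"), each = 3), genos)
  vals <- setNames(c(4, 5, 6, 6, 7, 8, 8, 9, 10), genos)  # group means 5/7/9
  cor_ <- maturity_correct(vals, groups)
  gm <- tapply(cor_, groups[names(cor_)], mean)
  expect_equal(as.numeric(gm), rep(7, 3))
  # within-group differences preserved exactly
  expect_equal(cor_["g02"] - cor_["g01"], vals["g02"] - vals["g01"])
  expect_equal(unname(rank(cor_[1:3])), unname(rank(vals[1:3])))
  # idempotence
  expect_equal(maturity_correct(cor_, groups), cor_, tolerance = 1e-12)
  # single group: identity
  one <- setNames(rep("M", 9), genos)
  expect_equal(maturity_correct(vals, one), vals)
  expect_error(maturity_correct(vals, groups[-1]), "without a maturity group")
})

test_that("maturity correction on a trait table corrects every trait column", {
  genos <- sprintf("g%02d", 1:6)
  groups <- setNames(rep(c("E", "L"), each = 3), genos)
  tab <- data.frame(genotype = genos, a = c(1, 2, 3, 11, 12, 13),
                    b = c(10, 10, 10, 30, 30, 30))
  out <- maturity_correct(tab, groups)
  expect_equal(as.numeric(tapply(out$a, groups, mean)), rep(7, 2))
  expect_equal(as.numeric(tapply(out$b, groups, mean)), rep(20, 2))
})

test_that("genetic correlations behave on constructed inputs", {
  set.seed(4)
  genos <- sprintf("g%02d", 1:30)
  hn <- data.frame(genotype = genos, a = rnorm(30), b = rnorm(30))
  hn$c <- 2 * hn$a + 3        # affine transform of a
  ln <- hn
  out <- genetic_correlations(hn, ln)
  expect_equal(unname(out$cross_N), rep(1, 3))
  expect_equal(out$corr_HN["a", "c"], 1)
  expect_true(isSymmetric(out$corr_HN))
  # zero-variance trait flagged missing
  hn$d <- 1
  ln$d <- 1
  out2 <- genetic_correlations(hn, ln)
  expect_true(is.na(out2$corr_HN["a", "d"]))
  expect_error(genetic_correlations(hn[1:2, ], ln[1:2, ]), ">= 3")
})

test_that("independent traits show only null-scale correlations", {
  set.seed(12)
  genos <- sprintf("g%03d", 1:169)
  mk <- function() {
    d <- data.frame(genotype = genos)
    for (i in 1:6) d[[paste0("t", i)]] <- rnorm(169)
    d
  }
  out <- genetic_correlations(mk(), mk())
  off <- out$corr_HN[upper.tri(out$corr_HN)]
  # |r| < 0.3 has probability ~1 per pair at n = 169 under the null
  expect_true(all(abs(off) < 0.3))
})

test_that("Ward clustering on 1-|r| groups correlated traits", {
  # two perfectly correlated traits merge first at height 0
  set.seed(6)
  x <- rnorm(40)
  m <- cor(cbind(a = x, b = x, c = rnorm(40), d = rnorm(40)))
  hc <- cluster_traits(m)
  expect_equal(hc$height[1], 0, tolerance = 1e-10)
  first <- rownames(m)[-hc$merge[1, ]]
  expect_setequal(first, c("a", "b"))
  # block-diagonal structure: top split separates the blocks
  blocks <- diag(8)
  blocks[1:4, 1:4] <- 0.9; blocks[5:8, 5:8] <- 0.9; diag(blocks) <- 1
  dimnames(blocks) <- list(letters[1:8], letters[1:8])
  hc2 <- cluster_traits(blocks)
  top <- cutree(hc2, 2)
  expect_equal(length(unique(top[1:4])), 1)
  expect_equal(length(unique(top[5:8])), 1)
  expect_false(top[1] == top[5])
  # permutation invariance of merge heights
  perm <- sample(8)
  hc3 <- cluster_traits(blocks[perm, perm])
  expect_equal(sort(hc3$height), sort(hc2$height), tolerance = 1e-12)
  # N-input-derived traits are excluded upstream
  nm <- c("a", "b", "NUE", "NUtE", "NUptE")
  m2 <- diag(5); dimnames(m2) <- list(nm, nm)
  hc4 <- cluster_traits(m2)
  expect_setequal(hc4$labels, c("a", "b"))
  expect_error(cluster_traits(matrix(c(1, 0.2, 0.5, 1), 2)), "symmetric")
})

test_that("Mantel statistic and permutation p behave on identities", {
  set.seed(8)
  m <- cor(matrix(rnorm(200), 20, 10))
  out <- mantel_test(m, m, n_perm = 199, seed = 1)
  expect_equal(out$r, 1)
  expect_equal(out$p, 1 / 200)
  neg <- mantel_test(m, -m, n_perm = 199, seed = 1)
  expect_equal(neg$r, -1)
  expect_error(mantel_test(m, m[1:5, 1:5]), "dimensions differ")
  expect_warning(mantel_test(m, m, n_perm = 50), "coarse")
})

test_that("Mantel statistic agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(13)
  a <- cor(matrix(rnorm(300), 30, 10))
  b <- cor(matrix(rnorm(300), 30, 10))
  ours <- mantel_test(a, b, n_perm = 999, seed = 3)
  ref <- vegan::mantel(as.dist(1 - a), as.dist(1 - b), permutations = 999)
  # the 1-r dissimilarity transform on both sides leaves the statistic
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-10)
})

test_that("Mantel p-values are uniform under the null", {
  set.seed(14)
  pvals <- replicate(200, {
    a <- cor(matrix(rnorm(160), 20, 8))
    b <- cor(matrix(rnorm(160), 20, 8))
    mantel_test(a, b, n_perm = 199)$p
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
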