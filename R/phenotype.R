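#' Genotype values from the split-plot mixed model
#'
#' Fits, for one trait at one nitrogen level, the two-year split-plot
#' model `Y = yr + Mt + yr.Mt + Mt.G + yr.row + yr.col + E`, where year,
#' maturity group and genotype-within-maturity-group are fixed and the
#' year-specific row and column corrections are random (restricted maximum
#' likelihood via lme4). Genotype BLUEs come from the fixed-genotype fit;
#' genotype BLUPs and per-year genotype predictions (year main effect plus
#' genotype effect) come from a refit with the genotype term random.
#' Reference-cultivar plots (flagged `is_reference`) carry their own
#' maturity level so that they inform only the spatial variance
#' components; they are dropped from the returned genotype values.
#'
#' @param plots Data frame with columns `plot_id`, `year`, `n_level`,
#'   `maturity_group`, `genotype`, `row`, `col`, `is_reference` and one
#'   column per trait.
#' @param trait Name of the trait column to analyse.
#' @param n_level Which nitrogen level to analyse (a value of
#'   `plots$n_level`, e.g. `"HN"` or `"LN"`).
#' @return A list with elements `blue` and `blup` (named numeric vectors
#'   over genotypes, averaged over years), `per_year` (data frame
#'   `genotype`, `year`, `value` of per-year BLUP-based predictions),
#'   `groups` (named genotype-to-maturity-group map) and `varcomp`.
#' @export
fit_eq2 <- function(plots, trait, n_level) {
  stopifnot(trait %in% names(plots))
  d <- plots[plots$n_level == n_level & !is.na(plots[[trait]]), , drop = FALSE]
  if (nrow(d) == 0) stop("no data for n_level '", n_level, "'")
  d$y <- d[[trait]]
  if (!"is_reference" %in% names(d)) d$is_reference <- FALSE
  d$maturity_group <- as.character(d$maturity_group)
  d$genotype <- as.character(d$genotype)
  d$maturity_group[d$is_reference] <- ".ref"
  gmap <- unique(d[!d$is_reference, c("genotype", "maturity_group")])
  if (anyDuplicated(gmap$genotype)) {
    bad <- gmap$genotype[duplicated(gmap$genotype)]
    stop("genotype(s) assigned to more than one maturity group: ",
         paste(unique(bad), collapse = ", "))
  }
  if (any(table(gmap$maturity_group) < 2)) {
    stop("each maturity group needs at least 2 genotypes")
  }
  d$year <- factor(d$year)
  d$maturity_group <- factor(d$maturity_group)
  d$genotype <- factor(d$genotype)
  d$yr_row <- interaction(d$year, d$row, drop = TRUE)
  d$yr_col <- interaction(d$year, d$col, drop = TRUE)
  groups <- stats::setNames(gmap$maturity_group, gmap$genotype)
  genos <- sort(unique(gmap$genotype))

  if (stats::var(d$y) == 0) {
    flat <- stats::setNames(rep(d$y[1], length(genos)), genos)
    per_year <- expand.grid(genotype = genos, year = levels(d$year),
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    per_year$value <- d$y[1]
    return(list(blue = flat, blup = flat, per_year = per_year,
                groups = groups,
                varcomp = c(genotype = 0, yr_row = 0, yr_col = 0,
                            residual = 0)))
  }

  grid <- expand.grid(genotype = genos, year = levels(d$year),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$maturity_group <- as.character(groups[grid$genotype])
  grid_f <- data.frame(
    genotype = factor(grid$genotype, levels = levels(d$genotype)),
    year = factor(grid$year, levels = levels(d$year)),
    maturity_group = factor(grid$maturity_group,
                            levels = levels(d$maturity_group)))

  ## BLUE fit: genotype fixed. The genotype factor absorbs the maturity
  ## main effect (genotypes are nested in maturity groups); year-by-
  ## maturity cells carry the yr and yr.Mt terms. The resulting fixed
  ## model matrix is rank deficient by construction; predictions on
  ## observed cells are still unique.
  blue_fit <- tryCatch(
    suppressWarnings(suppressMessages(lme4::lmer(
      y ~ 0 + year:maturity_group + genotype + (1 | yr_row) + (1 | yr_col),
      data = d, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE)))),
    error = function(e) NULL)
  pred_blue <- if (is.null(blue_fit)) {
    lm_fit <- stats::lm(y ~ 0 + year:maturity_group + genotype, data = d)
    suppressWarnings(stats::predict(lm_fit, newdata = grid_f))
  } else {
    stats::predict(blue_fit, newdata = grid_f, re.form = NA,
                   allow.new.levels = FALSE)
  }
  blue <- tapply(pred_blue, grid$genotype, mean)[genos]

  ## BLUP fit: genotype random (equivalent to Mt.G random given nesting).
  blup_fit <- suppressWarnings(suppressMessages(lme4::lmer(
    y ~ 0 + year:maturity_group + (1 | genotype) + (1 | yr_row) +
      (1 | yr_col),
    data = d, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE))))
  pred_blup <- stats::predict(blup_fit, newdata = grid_f,
                              re.form = ~ (1 | genotype),
                              allow.new.levels = FALSE)
  blup <- tapply(pred_blup, grid$genotype, mean)[genos]
  per_year <- data.frame(genotype = grid$genotype, year = grid$year,
                         value = as.numeric(pred_blup))

  vc <- as.data.frame(lme4::VarCorr(blup_fit))
  getvc <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v else 0
  }
  list(blue = stats::setNames(as.numeric(blue), genos),
       blup = stats::setNames(as.numeric(blup), genos),
       per_year = per_year, groups = groups,
       varcomp = c(genotype = getvc("genotype"), yr_row = getvc("yr_row"),
                   yr_col = getvc("yr_col"), residual = getvc("Residual")))
}

#' Remove maturity-class means from genotype trait values
#'
#' Subtracts, per trait, the maturity-group mean minus the grand mean from
#' each genotype's value, equalising trait means across maturity classes
#' while preserving within-group differences exactly. Applying the
#' correction twice equals applying it once.
#'
#' @param traits Data frame with a `genotype` column and one column per
#'   trait, or a named numeric vector (single trait).
#' @param groups Named character vector mapping every genotype to its
#'   maturity group.
#' @return Object of the same shape with corrected values.
#' @export
maturity_correct <- function(traits, groups) {
  correct_one <- function(values, genos) {
    g <- as.character(groups[genos])
    if (anyNA(g)) {
      stop("genotype(s) without a maturity group: ",
           paste(genos[is.na(g)], collapse = ", "))
    }
    ok <- !is.na(values)
    grand <- mean(values[ok])
    grp_mean <- tapply(values[ok], g[ok], mean)
    values - (grp_mean[g] - grand)
  }
  if (is.numeric(traits) && !is.null(names(traits))) {
    return(stats::setNames(as.numeric(correct_one(traits, names(traits))),
                           names(traits)))
  }
  stopifnot(is.data.frame(traits), "genotype" %in% names(traits))
  out <- traits
  for (cn in setdiff(names(traits), c("genotype", "maturity_group"))) {
    out[[cn]] <- as.numeric(correct_one(traits[[cn]], traits$genotype))
  }
  out
}

#' Genetic correlation summary across nitrogen levels
#'
#' Pairwise Pearson correlations between traits over genotype values,
#' within each N level, plus the per-trait correlation between N levels
#' (the diagonal of the published heatmaps). Missing values are handled
#' pairwise-complete; zero-variance traits yield `NA` correlations.
#'
#' @param blues_HN,blues_LN Data frames with a `genotype` column and the
#'   same trait columns, one row per genotype.
#' @return A list with `corr_HN`, `corr_LN` (trait x trait matrices) and
#'   `cross_N` (named per-trait correlation between levels).
#' @export
genetic_correlations <- function(blues_HN, blues_LN) {
  common <- intersect(blues_HN$genotype, blues_LN$genotype)
  if (length(common) < 3) stop("need >= 3 shared genotypes")
  traits <- setdiff(intersect(names(blues_HN), names(blues_LN)),
                    c("genotype", "maturity_group"))
  hn <- as.matrix(blues_HN[match(common, blues_HN$genotype), traits,
                           drop = FALSE])
  ln <- as.matrix(blues_LN[match(common, blues_LN$genotype), traits,
                           drop = FALSE])
  corr_hn <- suppressWarnings(stats::cor(hn, use = "pairwise.complete.obs"))
  corr_ln <- suppressWarnings(stats::cor(ln, use = "pairwise.complete.obs"))
  cross <- vapply(traits, function(tr) {
    suppressWarnings(stats::cor(hn[, tr], ln[, tr],
                                use = "pairwise.complete.obs"))
  }, numeric(1))
  list(corr_HN = corr_hn, corr_LN = corr_ln, cross_N = cross)
}

#' Ward clustering of traits on absolute genetic correlations
#'
#' Agglomerative Ward minimum-variance clustering with dissimilarity
#' `1 - |r|`. Traits whose definition involves the N input level (NUE,
#' NUtE, NUptE) should be excluded by the caller before clustering.
#'
#' @param corr Symmetric trait-by-trait correlation matrix.
#' @param exclude Trait names to drop before clustering (default the
#'   N-input-derived efficiencies).
#' @return An [stats::hclust] dendrogram.
#' @export
cluster_traits <- function(corr, exclude = c("NUE", "NUtE", "NUptE")) {
  if (!isSymmetric(unname(corr), tol = 1e-8)) {
    stop("correlation matrix must be symmetric")
  }
  keep <- setdiff(colnames(corr), exclude)
  corr <- corr[keep, keep, drop = FALSE]
  d <- stats::as.dist(1 - abs(corr))
  stats::hclust(d, method = "ward.D2")
}

#' Mantel test between two trait correlation matrices
#'
#' Pearson correlation of the upper-triangle entries, with a permutation
#' p-value over simultaneous row/column permutations of the second
#' matrix: `p = (#(r_perm >= r_obs) + 1) / (n_perm + 1)`.
#'
#' @param matA,matB Symmetric matrices of equal dimension.
#' @param n_perm Number of permutations (>= 99 recommended).
#' @param seed Optional integer seed for the permutations.
#' @return A list with elements `r` and `p`.
#' @export
mantel_test <- function(matA, matB, n_perm = 999, seed = NULL) {
  if (!all(dim(matA) == dim(matB))) stop("matrix dimensions differ")
  if (!isSymmetric(unname(matA), tol = 1e-8) ||
      !isSymmetric(unname(matB), tol = 1e-8)) {
    stop("matrices must be symmetric")
  }
  if (n_perm < 99) warning("fewer than 99 permutations; p-value is coarse")
  if (!is.null(seed)) set.seed(seed)
  ut <- upper.tri(matA)
  r_obs <- stats::cor(matA[ut], matB[ut])
  n <- nrow(matA)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n)
    stats::cor(matA[ut], matB[idx, idx][ut])
  }, numeric(1))
  list(r = r_obs, p = (sum(r_perm >= r_obs) + 1) / (n_perm + 1))
}
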