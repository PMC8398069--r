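#' Configuration for the synthetic potato trial generator
#'
#' Bundles the population, architecture and observation-noise settings
#' used by the simulators. The defaults emulate the study conditions the
#' pipeline is built for: 169 tetraploid cultivars in 3 maturity groups,
#' 12 chromosomes, 2 years, nitrogen whole plots at 180 (HN) and 75 (LN)
#' kg available N/ha, and a large-effect maturity locus on chromosome 5.
#'
#' @param n_genotypes Number of cultivars (default 169).
#' @param n_chromosomes Number of chromosomes (potato: 12).
#' @param chromosome_length_bp Chromosome length in bp (default 75 Mb).
#' @param n_markers Total SNP count across the genome (default 2000).
#' @param n_subpops Number of subpopulations (default 3).
#' @param fst Balding-Nichols differentiation among subpopulations
#'   (default 0.1).
#' @param ld_block_size Markers per correlated-frequency block; blocks
#'   create local linkage disequilibrium (default 10).
#' @param missing_rate Fraction of dosage calls set missing (default 0.02).
#' @param maturity_locus List `chrom`, `pos_bp`, `h2` (fraction of the
#'   maturity-score variance explained by the locus dosage).
#' @param qtls List of planted QTLs, each a list with `chrom`, `pos_bp`,
#'   `trait`, `var_frac` (fraction of the genotype-level trait variance)
#'   and `n_dependence` (`"both"`, `"HN"` or `"LN"`).
#' @param traits Named list of trait architectures, each a list
#'   `maturity_frac` (variance from the maturity-group effect),
#'   `polygenic_h2` (variance from the kinship-structured polygenic
#'   term); the remainder is genotype-level residual.
#' @param years Two trial years.
#' @param n_levels Named available-N vector in kg/ha
#'   (default `c(HN = 180, LN = 75)`).
#' @param year_noise_frac Standard deviation of year-by-genotype noise in
#'   the genotype-level datasets, as a fraction of the trait SD
#'   (default 0.3).
#' @param canopy_sd Gaussian noise SD on weekly soil-cover observations
#'   (%SC, default 3).
#' @param tuber_cv Multiplicative (lognormal) noise CV on tuber class
#'   values (default 0.1).
#' @param harvest_cv Multiplicative noise CV on harvest variables
#'   (default 0.08).
#' @param row_sd,col_sd Spatial row/column effect SDs on plot traits, in
#'   trait-SD units (default 0.3 each).
#' @param n_reference_plots Reference-cultivar plots per year
#'   (default `c(16, 20)`).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genotypes = 169, n_chromosomes = 12,
                       chromosome_length_bp = 75e6, n_markers = 2000,
                       n_subpops = 3, fst = 0.1, ld_block_size = 10,
                       missing_rate = 0.02,
                       maturity_locus = list(chrom = 5, pos_bp = 50e6,
                                             h2 = 0.5),
                       qtls = list(),
                       traits = list(),
                       years = c(2009, 2010),
                       n_levels = c(HN = 180, LN = 75),
                       year_noise_frac = 0.3,
                       canopy_sd = 3, tuber_cv = 0.1, harvest_cv = 0.08,
                       row_sd = 0.3, col_sd = 0.3, plot_sd = 0.25,
                       n_reference_plots = c(16, 20)) {
  stopifnot(n_genotypes > 0, n_markers > 0, fst > 0, fst < 1,
            length(years) == 2, all(n_levels > 0))
  structure(as.list(environment()), class = "sim_config")
}

## rescale a component to a target variance fraction (population sd = 1)
scale_to <- function(x, var_frac) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s * sqrt(var_frac)
}

#' Simulate a structured tetraploid dosage panel
#'
#' Ancestral allele frequencies are Uniform(0.1, 0.9) per linkage block;
#' subpopulation frequencies follow the Balding-Nichols construction
#' `Beta(p(1-Fst)/Fst, (1-p)(1-Fst)/Fst)`; markers within a block share
#' the subpopulation frequency draw (plus per-marker jitter), which
#' creates block-wise linkage disequilibrium through the population
#' structure; tetraploid dosages are Binomial(4, p).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list with `panel` (a [dosage_panel()]) and `truth` (list:
#'   `subpop` assignment, per-subpop allele frequencies).
#' @export
simulate_genotypes <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_genotypes
  p_tot <- config$n_markers
  per_chr <- diff(round(seq(0, p_tot, length.out = config$n_chromosomes + 1)))
  map <- do.call(rbind, lapply(seq_len(config$n_chromosomes), function(ch) {
    k <- per_chr[ch]
    data.frame(marker = sprintf("chr%02d_m%04d", ch, seq_len(k)),
               chrom = ch,
               pos_bp = sort(round(stats::runif(k, 1,
                                                config$chromosome_length_bp))))
  }))
  n_blocks <- ceiling(p_tot / config$ld_block_size)
  block <- rep(seq_len(n_blocks), each = config$ld_block_size)[seq_len(p_tot)]
  p_anc <- stats::runif(n_blocks, 0.1, 0.9)[block]
  a <- config$fst
  freqs <- sapply(seq_len(config$n_subpops), function(s) {
    p_block <- stats::rbeta(n_blocks, p_anc[!duplicated(block)] * (1 - a) / a,
                            (1 - p_anc[!duplicated(block)]) * (1 - a) / a)
    pmin(pmax(p_block[block] + stats::rnorm(p_tot, 0, 0.03), 0.02), 0.98)
  })
  subpop <- rep(seq_len(config$n_subpops), length.out = n)
  dos <- t(sapply(seq_len(n), function(i) {
    stats::rbinom(p_tot, 4, freqs[, subpop[i]])
  }))
  if (config$missing_rate > 0) {
    miss <- stats::runif(length(dos)) < config$missing_rate
    dos[miss] <- NA
  }
  dimnames(dos) <- list(sprintf("G%03d", seq_len(n)), map$marker)
  list(panel = dosage_panel(dos, map),
       truth = list(subpop = subpop, freqs = freqs, block = block))
}

nearest_marker <- function(panel, chrom, pos_bp) {
  on_chr <- which(panel$map$chrom == chrom)
  if (!length(on_chr)) stop("requested QTL position off the map (chromosome ",
                            chrom, ")")
  on_chr[which.min(abs(panel$map$pos_bp[on_chr] - pos_bp))]
}

#' Simulate trait architecture on top of a dosage panel
#'
#' Builds a maturity score as a large-effect additive function of the
#' chromosome-5 locus dosage plus noise, bins genotypes into E/M/L
#' maturity groups by score terciles, and constructs genotype-level trait
#' values per nitrogen level as the sum of a maturity-group-mediated
#' component, planted QTL effects (honouring each QTL's nitrogen
#' dependence), a polygenic term with kinship-structured covariance, and
#' a residual, with each component rescaled to its configured variance
#' fraction.
#'
#' @param sim Output of [simulate_genotypes()].
#' @param config The same [sim_config()].
#' @param seed Integer seed.
#' @return A truth record: list with `groups` (named genotype-to-E/M/L
#'   map), `score` (continuous maturity score), `locus_marker`,
#'   `qtl_markers`, and `values` (named list per N level of genotype x
#'   trait data frames, first column `genotype`).
#' @export
simulate_architecture <- function(sim, config, seed = 1) {
  set.seed(seed)
  panel <- sim$panel
  n <- nrow(panel$dosages)
  ids <- rownames(panel$dosages)
  Z <- panel$dosages
  Z <- apply(Z, 2, function(x) {
    m <- mean(x, na.rm = TRUE); x[is.na(x)] <- m; x - m
  })

  loc <- config$maturity_locus
  locus_idx <- nearest_marker(panel, loc$chrom, loc$pos_bp)
  locus_dos <- Z[, locus_idx]
  h2_loc <- loc$h2
  score <- scale_to(locus_dos, h2_loc) + scale_to(stats::rnorm(n), 1 - h2_loc)
  ## high score = late maturity; terciles define the E/M/L blocking factor
  tert <- cut(rank(score, ties.method = "first"),
              breaks = 3, labels = c("E", "M", "L"))
  groups <- stats::setNames(as.character(tert), ids)
  grp_eff <- c(E = -1, M = 0, L = 1)[groups]

  polygenic <- as.numeric(Z %*% stats::rnorm(ncol(Z))) / sqrt(ncol(Z))

  qtl_markers <- lapply(config$qtls, function(q) {
    nearest_marker(panel, q$chrom, q$pos_bp)
  })

  values <- lapply(names(config$n_levels), function(lev) {
    df <- data.frame(genotype = ids)
    for (tn in names(config$traits)) {
      arch <- config$traits[[tn]]
      mat_f <- if (is.null(arch$maturity_frac)) 0 else arch$maturity_frac
      pol_f <- if (is.null(arch$polygenic_h2)) 0 else arch$polygenic_h2
      comp <- scale_to(grp_eff, mat_f) + scale_to(polygenic, pol_f)
      used <- mat_f + pol_f
      for (qi in seq_along(config$qtls)) {
        q <- config$qtls[[qi]]
        if (!identical(q$trait, tn)) next
        dep <- if (is.null(q$n_dependence)) "both" else q$n_dependence
        if (dep != "both" && dep != lev) next
        comp <- comp + scale_to(Z[, qtl_markers[[qi]]], q$var_frac)
        used <- used + q$var_frac
      }
      resid_f <- max(1 - used, 0)
      df[[tn]] <- comp + scale_to(stats::rnorm(n), resid_f)
    }
    ## the maturity assessment itself tracks the continuous score
    df$mt_as <- scale_to(score, 0.9) + scale_to(stats::rnorm(n), 0.1)
    df
  })
  names(values) <- names(config$n_levels)

  list(groups = groups, score = score,
       locus_marker = panel$map$marker[locus_idx],
       qtl_markers = vapply(qtl_markers, function(i) panel$map$marker[i], ""),
       values = values)
}

#' Genotype-level year-by-nitrogen datasets from a truth record
#'
#' Adds a year main effect and genotype-by-year noise to the genotype
#' trait values, producing the four datasets (year x N level) that feed
#' the association scan when the plot-level stages are not exercised.
#'
#' @param arch Output of [simulate_architecture()].
#' @param config The [sim_config()].
#' @param seed Integer seed.
#' @return A list of data frames (one per year x N level) with attributes
#'   `year` and `n_level`.
#' @export
simulate_genotype_datasets <- function(arch, config, seed = 1) {
  set.seed(seed)
  out <- list()
  for (yr in config$years) {
    for (lev in names(config$n_levels)) {
      df <- arch$values[[lev]]
      traits <- setdiff(names(df), "genotype")
      year_eff <- stats::rnorm(length(traits), 0, 0.2)
      names(year_eff) <- traits
      for (tn in traits) {
        noise <- stats::rnorm(nrow(df), 0, config$year_noise_frac *
                                max(stats::sd(df[[tn]]), 1e-12))
        df[[tn]] <- df[[tn]] + year_eff[tn] + noise
      }
      out[[paste(yr, lev, sep = ".")]] <-
        structure(df, year = yr, n_level = lev)
    }
  }
  out
}

## baseline canopy/tuber/harvest parameter surfaces per N level; genotype
## deviations (in SD units) come from the architecture trait values
observation_bases <- function() {
  list(
    HN = list(tm1 = c(12, 1.5), t1 = c(22, 2), t2 = c(48, 3), te = c(72, 3.5),
              Vx = c(92, 3), TbwA = c(210, 25), TbwB = c(54, 3),
              TbwMX = c(5.5, 0.8), TbnA = c(260, 30), TbnB = c(48, 3),
              TbnMX = c(26, 4), yield = c(6.2, 0.8), DM_pct = c(21.5, 1.4),
              N_conc = c(12.5, 1.3), mt_as = c(4.5, 1.2)),
    LN = list(tm1 = c(11, 1.5), t1 = c(20, 2), t2 = c(42, 3), te = c(64, 3.5),
              Vx = c(84, 4), TbwA = c(190, 25), TbwB = c(51, 3),
              TbwMX = c(4.2, 0.7), TbnA = c(240, 30), TbnB = c(46, 3),
              TbnMX = c(24, 4), yield = c(4.8, 0.7), DM_pct = c(21.9, 1.4),
              N_conc = c(10.5, 1.2), mt_as = c(5.0, 1.2)))
}

#' Simulate the two-year split-plot field experiment
#'
#' Lays out, per year, nitrogen whole plots with maturity-group subplots
#' and genotypes randomised within subplot, plus randomly placed
#' reference-cultivar plots; perturbs the genotype-level latent traits by
#' year, row, column and plot effects; and generates the raw observation
#' tables: weekly canopy cover series (via [evaluate_canopy()] with
#' truncated Gaussian noise), tuber size-class tables (via
#' [evaluate_bell()] with multiplicative noise) and harvest variables.
#'
#' @param arch Output of [simulate_architecture()]; trait values in SD
#'   units are mapped onto observation scales by fixed per-N baselines.
#' @param config The [sim_config()].
#' @param seed Integer seed.
#' @return A list with `plots` (field plot table incl. `mt_as` scores),
#'   `canopy` (stacked [canopy_series()] rows), `tubers` (stacked size
#'   class tables), `harvest` (plot harvest table) and `truth_params`
#'   (per-plot latent canopy parameters, for recovery checks).
#' @export
simulate_experiment <- function(arch, config, seed = 1) {
  set.seed(seed)
  bases <- observation_bases()
  ids <- names(arch$groups)
  midpts <- c(15, 35, 45, 55, 65, 75)
  class_lo <- c(0, 30, 40, 50, 60, 70)
  class_hi <- c(30, 40, 50, 60, 70, Inf)
  n_col_field <- 24

  plots <- list(); canopy <- list(); tubers <- list(); harvest <- list()
  truth_params <- list()
  plot_counter <- 0

  for (yi in seq_along(config$years)) {
    yr <- config$years[yi]
    year_shift <- stats::rnorm(1, 0, 0.25)
    order_all <- list()
    for (lev in names(config$n_levels)) {
      for (mg in sample(c("E", "M", "L"))) {
        gs <- sample(ids[arch$groups == mg])
        order_all[[length(order_all) + 1L]] <-
          data.frame(genotype = gs, n_level = lev, maturity_group = mg,
                     is_reference = FALSE)
      }
    }
    layout <- do.call(rbind, order_all)
    n_ref <- config$n_reference_plots[yi]
    ref <- data.frame(genotype = "REFCV", n_level = sample(
                        names(config$n_levels), n_ref, replace = TRUE),
                      maturity_group = "M", is_reference = TRUE)
    ins <- sort(sample(nrow(layout) + n_ref, n_ref))
    idx_ref <- logical(nrow(layout) + n_ref)
    idx_ref[ins] <- TRUE
    full <- rbind(layout, ref)
    ord <- integer(nrow(full))
    ord[idx_ref] <- nrow(layout) + seq_len(n_ref)
    ord[!idx_ref] <- seq_len(nrow(layout))
    full <- full[ord, , drop = FALSE]
    full$row <- (seq_len(nrow(full)) - 1) %/% n_col_field + 1
    full$col <- (seq_len(nrow(full)) - 1) %% n_col_field + 1
    row_eff <- stats::rnorm(max(full$row), 0, config$row_sd)
    col_eff <- stats::rnorm(max(full$col), 0, config$col_sd)

    for (k in seq_len(nrow(full))) {
      plot_counter <- plot_counter + 1
      pid <- sprintf("P%04d", plot_counter)
      g <- full$genotype[k]
      lev <- full$n_level[k]
      base <- bases[[lev]]
      gv <- function(tn) {
        if (full$is_reference[k] || !tn %in% names(arch$values[[lev]])) {
          return(0)
        }
        arch$values[[lev]][[tn]][match(g, arch$values[[lev]]$genotype)]
      }
      spatial <- row_eff[full$row[k]] + col_eff[full$col[k]]
      latent <- function(tn, plot_sd = config$plot_sd) {
        b <- base[[tn]]
        b[1] + b[2] * (gv(tn) + year_shift + spatial +
                         stats::rnorm(1, 0, plot_sd))
      }
      tm1 <- max(latent("tm1"), 2)
      t1 <- max(latent("t1"), tm1 + 2)
      t2 <- max(latent("t2"), t1 + 1)
      te <- max(latent("te"), t2 + 5)
      Vx <- min(max(latent("Vx"), 20), 99.5)
      cp <- canopy_params(tm1, t1, t2, te, Vx)
      td <- seq(0, te * 1.08, by = 5)
      cover <- pmin(pmax(evaluate_canopy(cp, td) +
                           stats::rnorm(length(td), 0, config$canopy_sd),
                         0), 100)
      canopy[[pid]] <- data.frame(plot_id = pid, thermal_day = td,
                                  cover = cover)
      truth_params[[pid]] <- data.frame(plot_id = pid, tm1 = tm1, t1 = t1,
                                        t2 = t2, te = te, Vx = Vx)

      sdlog <- sqrt(log(1 + config$tuber_cv^2))
      tw <- tuber_curve_params(max(latent("TbwA"), 40), latent("TbwB"),
                               max(latent("TbwMX"), 0.3), "weight")
      tn_ <- tuber_curve_params(max(latent("TbnA"), 40), latent("TbnB"),
                                max(latent("TbnMX"), 2), "number")
      tubers[[pid]] <- data.frame(
        plot_id = pid, class_low_mm = class_lo, class_high_mm = class_hi,
        weight_kg = evaluate_bell(tw, midpts) *
          stats::rlnorm(6, -sdlog^2 / 2, sdlog),
        number = round(evaluate_bell(tn_, midpts) *
                         stats::rlnorm(6, -sdlog^2 / 2, sdlog)))

      hcv <- sqrt(log(1 + config$harvest_cv^2))
      harvest[[pid]] <- data.frame(
        plot_id = pid,
        fresh_yield_kg_m2 = max(latent("yield"), 0.3) *
          stats::rlnorm(1, -hcv^2 / 2, hcv),
        dm_pct = min(max(latent("DM_pct"), 12), 32),
        n_conc_g_kg = max(latent("N_conc"), 4),
        n_input_kg_ha = unname(config$n_levels[lev]))

      plots[[pid]] <- data.frame(
        plot_id = pid, year = yr, n_level = lev,
        maturity_group = full$maturity_group[k], genotype = g,
        row = full$row[k], col = full$col[k],
        is_reference = full$is_reference[k],
        mt_as = min(max(latent("mt_as", 0.15), 1), 8))
    }
  }
  rb <- function(l) { x <- do.call(rbind, l); rownames(x) <- NULL; x }
  list(plots = rb(plots), canopy = rb(canopy), tubers = rb(tubers),
       harvest = rb(harvest), truth_params = rb(truth_params))
}

#' Canned simulation scenarios
#'
#' `"null"`: population structure only, no planted QTLs and no
#' maturity-mediated traits (for calibration). `"maturity_only"`: the
#' chromosome-5 locus drives the maturity groups, and all traits are
#' mediated by the maturity group (for hotspot reproduction and the
#' maturity-correction check). `"n_dependent"`: one common, one HN-only
#' and one LN-only QTL on separate chromosomes (for N-classification
#' recovery). `"full"`: the maturity hotspot plus six scattered QTLs.
#'
#' @param name Scenario name.
#' @param seed Integer seed used for genotypes, architecture and the
#'   genotype-level datasets.
#' @param n_genotypes,n_markers Population dimensions (defaults are the
#'   study conditions).
#' @param experiment Also generate the plot-level field experiment
#'   (slower; default `FALSE`).
#' @return A list with `config`, `genotypes` (panel + truth), `arch`,
#'   `datasets` (genotype-level year x N datasets) and, when requested,
#'   `experiment`.
#' @export
scenario <- function(name = c("null", "maturity_only", "n_dependent", "full"),
                     seed = 1, n_genotypes = 169, n_markers = 2000,
                     experiment = FALSE) {
  name <- match.arg(name)
  generic <- function(k, maturity_frac = 0, polygenic_h2 = 0.4) {
    stats::setNames(rep(list(list(maturity_frac = maturity_frac,
                                  polygenic_h2 = polygenic_h2)), k),
                    sprintf("trait%02d", seq_len(k)))
  }
  cfg <- switch(
    name,
    null = sim_config(n_genotypes = n_genotypes, n_markers = n_markers,
                      traits = generic(8), qtls = list(),
                      maturity_locus = list(chrom = 5, pos_bp = 50e6,
                                            h2 = 0)),
    maturity_only = sim_config(
      n_genotypes = n_genotypes, n_markers = n_markers,
      traits = generic(4, maturity_frac = 0.5, polygenic_h2 = 0.2),
      qtls = list()),
    n_dependent = sim_config(
      n_genotypes = n_genotypes, n_markers = n_markers,
      traits = list(
        trait_cm = list(maturity_frac = 0, polygenic_h2 = 0.3),
        trait_hn = list(maturity_frac = 0, polygenic_h2 = 0.3),
        trait_ln = list(maturity_frac = 0, polygenic_h2 = 0.3)),
      qtls = list(
        list(chrom = 1, pos_bp = 30e6, trait = "trait_cm",
             var_frac = 0.25, n_dependence = "both"),
        list(chrom = 3, pos_bp = 40e6, trait = "trait_hn",
             var_frac = 0.25, n_dependence = "HN"),
        list(chrom = 7, pos_bp = 55e6, trait = "trait_ln",
             var_frac = 0.25, n_dependence = "LN"))),
    full = sim_config(
      n_genotypes = n_genotypes, n_markers = n_markers,
      traits = list(
        tm1 = list(maturity_frac = 0.1, polygenic_h2 = 0.3),
        t1 = list(maturity_frac = 0.2, polygenic_h2 = 0.3),
        t2 = list(maturity_frac = 0.5, polygenic_h2 = 0.2),
        te = list(maturity_frac = 0.5, polygenic_h2 = 0.2),
        Vx = list(maturity_frac = 0.2, polygenic_h2 = 0.3),
        yield = list(maturity_frac = 0.3, polygenic_h2 = 0.3),
        DM_pct = list(maturity_frac = 0.1, polygenic_h2 = 0.4),
        N_conc = list(maturity_frac = 0.4, polygenic_h2 = 0.2),
        TbwB = list(maturity_frac = 0, polygenic_h2 = 0.4),
        TbnB = list(maturity_frac = 0, polygenic_h2 = 0.4),
        TbwA = list(maturity_frac = 0, polygenic_h2 = 0.4),
        TbnA = list(maturity_frac = 0, polygenic_h2 = 0.4),
        TbwMX = list(maturity_frac = 0.2, polygenic_h2 = 0.3),
        TbnMX = list(maturity_frac = 0.1, polygenic_h2 = 0.3)),
      qtls = list(
        list(chrom = 2, pos_bp = 20e6, trait = "TbwA", var_frac = 0.25,
             n_dependence = "HN"),
        list(chrom = 2, pos_bp = 22e6, trait = "TbnA", var_frac = 0.22,
             n_dependence = "HN"),
        list(chrom = 3, pos_bp = 60e6, trait = "TbnB", var_frac = 0.25,
             n_dependence = "both"),
        list(chrom = 6, pos_bp = 35e6, trait = "TbwB", var_frac = 0.25,
             n_dependence = "LN"),
        list(chrom = 1, pos_bp = 10e6, trait = "DM_pct", var_frac = 0.25,
             n_dependence = "both"),
        list(chrom = 12, pos_bp = 65e6, trait = "TbnMX", var_frac = 0.25,
             n_dependence = "HN"))))
  sim <- simulate_genotypes(cfg, seed)
  arch <- simulate_architecture(sim, cfg, seed + 1000L)
  datasets <- simulate_genotype_datasets(arch, cfg, seed + 2000L)
  out <- list(name = name, config = cfg, genotypes = sim, arch = arch,
              datasets = datasets)
  if (experiment) out$experiment <- simulate_experiment(arch, cfg,
                                                        seed + 3000L)
  out
}
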