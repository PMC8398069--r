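#' Read / write tab-separated pipeline tables
#'
#' Thin wrappers fixing the conventions used throughout (UTF-8, header
#' row, `NA` for missing, no quoting, no row names).
#'
#' @param path File path.
#' @param x Data frame to write.
#' @return `read_tsv()` returns a data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' @rdname read_tsv
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Published peak-marker tables bundled with the package
#'
#' Two peak-marker association tables from a two-year potato cultivar
#' trial at contrasting nitrogen inputs, shipped as plain TSV and used to
#' demonstrate and test the QTL consolidation rules. `"uncorrected"`
#' holds the year-consistent peak markers by nitrogen class from the
#' maturity-uncorrected analysis; `"comparison"` holds peak markers with
#' statistics from the maturity-corrected analysis side by side with the
#' uncorrected one (rows without uncorrected statistics were detected
#' only after correction). Genome positions are cumulative across
#' chromosomes; all merging happens within chromosomes, where cumulative
#' and per-chromosome distances agree.
#'
#' @param table Which table to load.
#' @return A data frame; for `"uncorrected"` in association-record format
#'   (`trait`, `marker`, `chrom`, `pos_bp`, `n_class`, `minus_log10_p`,
#'   `explained_var_pct`).
#' @export
load_peak_table <- function(table = c("uncorrected", "comparison")) {
  table <- match.arg(table)
  file <- c(uncorrected = "table2.tsv", comparison = "table3.tsv")[table]
  path <- system.file("extdata", "tables", file, package = "cdvqtl",
                      mustWork = TRUE)
  x <- read_tsv(path)
  if (table == "uncorrected") {
    data.frame(trait = x$trait, marker = x$marker, chrom = x$chrom,
               pos_bp = x$cum_pos, n_class = x$n_class,
               minus_log10_p = x$minus_log10_p,
               explained_var_pct = x$explained_var_pct)
  } else {
    x
  }
}

#' Split the corrected/uncorrected comparison table into analysis subsets
#'
#' Rows carrying statistics under both analyses form the
#' `both`-detected subset; rows without uncorrected statistics form the
#' `corrected_only` subset. Both are returned in association-record
#' format ready for [consolidate_qtls()], carrying the corrected
#' statistics.
#'
#' @param comparison Output of `load_peak_table("comparison")`.
#' @return A list of data frames `both` and `corrected_only`.
#' @export
comparison_subsets <- function(comparison) {
  as_assoc <- function(x) {
    data.frame(trait = x$trait, marker = x$marker, chrom = x$chrom,
               pos_bp = x$cum_pos, n_class = x$n_class,
               minus_log10_p = x$logp_corrected,
               explained_var_pct = x$ev_corrected)
  }
  in_both <- !is.na(comparison$logp_uncorrected)
  list(both = as_assoc(comparison[in_both, , drop = FALSE]),
       corrected_only = as_assoc(comparison[!in_both, , drop = FALSE]))
}

#' Add cumulative genome positions to a marker map
#'
#' @param map Data frame with `chrom` and `pos_bp`.
#' @param chrom_lengths Named or ordered vector of chromosome lengths in
#'   bp; defaults to the maximum observed position per chromosome.
#' @return `map` with a `cum_pos_bp` column (for Manhattan-style plots).
#' @export
cumulative_positions <- function(map, chrom_lengths = NULL) {
  chroms <- sort(unique(map$chrom))
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(ch) {
      max(map$pos_bp[map$chrom == ch])
    }, numeric(1))
  }
  offsets <- c(0, cumsum(chrom_lengths))[seq_along(chroms)]
  names(offsets) <- chroms
  map$cum_pos_bp <- map$pos_bp + offsets[as.character(map$chrom)]
  map
}

#' Association-to-QTL pipeline over genotype-level datasets
#'
#' Runs the downstream half of the pipeline: per-dataset kinship-corrected
#' scans, reporting thresholds, year-consistency, nitrogen classification,
#' LD-window consolidation and maturity colocalization.
#'
#' @param datasets List of genotype-level data frames (one per year x N
#'   level, as from [simulate_genotype_datasets()] or [fit_eq2()]
#'   per-year predictions), each with attributes `year` and `n_level`.
#' @param panel A filtered [dosage_panel()].
#' @param K Kinship matrix.
#' @param min_logp,min_ev Reporting thresholds (defaults 4 and 10).
#' @param merge_dist_bp LD merge distance in bp (default 4 Mb).
#' @param mt_trait Maturity-assessment trait name used for
#'   colocalization (default `"mt_as"`; set `NULL` to skip).
#' @param correct_maturity Subtract maturity-class means from every trait
#'   before scanning (requires `groups`).
#' @param groups Named genotype-to-maturity-group map (needed when
#'   `correct_maturity = TRUE`).
#' @return A list with `records` (all scan records), `kept` (thresholded),
#'   `consistent` (year-consistent), `classified` (with `n_class`) and
#'   `qtls` (consolidated, with `maturity_colocalized` when `mt_trait`
#'   is present).
#' @export
run_gwas_pipeline <- function(datasets, panel, K, min_logp = 4, min_ev = 10,
                              merge_dist_bp = 4e6, mt_trait = "mt_as",
                              correct_maturity = FALSE, groups = NULL) {
  records <- do.call(rbind, lapply(datasets, function(d) {
    yr <- attr(d, "year"); lev <- attr(d, "n_level")
    if (correct_maturity) {
      if (is.null(groups)) stop("groups required for maturity correction")
      d <- maturity_correct(d, groups)
    }
    r <- association_scan(d, panel, K,
                          dataset = paste(yr, lev, sep = "."))
    r$year <- yr
    r$n_level <- lev
    r
  }))
  rownames(records) <- NULL
  kept <- threshold_associations(records, min_logp, min_ev)
  consistent <- if (nrow(kept)) {
    ## an association absent from one year is simply dropped, so a kept
    ## set that happens to touch one year only is valid input here
    yk <- kept
    if (length(unique(yk$year)) < 2) {
      yk[0, setdiff(names(yk), "year"), drop = FALSE]
    } else {
      year_consistent(yk)
    }
  } else {
    kept[0, setdiff(names(kept), "year"), drop = FALSE]
  }
  classified <- classify_n(consistent)
  qtls <- consolidate_qtls(classified, merge_dist_bp)
  if (!is.null(mt_trait) && nrow(qtls)) {
    mt_markers <- classified[classified$trait == mt_trait,
                             c("chrom", "pos_bp"), drop = FALSE]
    qtls <- colocalize_maturity(qtls, mt_markers, merge_dist_bp)
  }
  list(records = records, kept = kept, consistent = consistent,
       classified = classified, qtls = qtls)
}

#' Full plot-level analysis pipeline
#'
#' Sequences every stage on a simulated (or equivalently formatted)
#' experiment: canopy curve fits per plot, tuber distribution fits per
#' plot, agronomic trait calculation, split-plot mixed-model genotype
#' estimation per nitrogen level (with per-year genotype predictions
#' forming the four year x N datasets), optional maturity correction, and
#' the association-to-QTL pipeline.
#'
#' @param experiment Output of [simulate_experiment()] (lists `plots`,
#'   `canopy`, `tubers`, `harvest`).
#' @param panel A filtered [dosage_panel()].
#' @param K Kinship matrix.
#' @param traits Optional character vector restricting which plot-level
#'   traits are carried into the mixed model (default: all).
#' @param correct_maturity Run the scan on maturity-corrected genotype
#'   values.
#' @param ... Passed to [run_gwas_pipeline()] (thresholds, distances).
#' @return A list with `plot_traits` (per-plot fitted parameters and
#'   derived traits), `datasets` (per year x N genotype values), `groups`
#'   and the [run_gwas_pipeline()] outputs under `gwas`.
#' @export
run_pipeline <- function(experiment, panel, K, traits = NULL,
                         correct_maturity = FALSE, ...) {
  canopy_fits <- fit_canopy_plots(experiment$canopy)
  tuber_fits <- fit_bell_plots(experiment$tubers)
  agro <- with(experiment$harvest, compute_agronomic(
    fresh_yield_kg_m2, dm_pct, n_conc_g_kg, n_input_g_m2(n_input_kg_ha),
    canopy_fits$AUC[match(plot_id, canopy_fits$plot_id)]))
  agro$plot_id <- experiment$harvest$plot_id

  pt <- experiment$plots
  pt <- merge(pt, canopy_fits, by = "plot_id")
  pt <- merge(pt, tuber_fits[, setdiff(names(tuber_fits),
                                       c("rss_w", "rss_n", "converged"))],
              by = "plot_id")
  pt <- merge(pt, agro, by = "plot_id")

  all_traits <- c("tm1", "t1", "t2", "te", "Vx", "t2_t1", "te_t2", "Cm",
                  "AP1", "AP2", "AP3", "AUC", "TbwA", "TbwB", "TbwMX",
                  "TbnA", "TbnB", "TbnMX", "Y_DM", "NUpt", "NUE", "NUtE",
                  "NUptE", "SCYi", "mt_as")
  use_traits <- if (is.null(traits)) all_traits else intersect(traits,
                                                               all_traits)
  datasets <- list()
  groups <- NULL
  for (lev in unique(pt$n_level)) {
    per_year <- NULL
    for (tr in use_traits) {
      fit <- tryCatch(fit_eq2(pt, tr, lev), error = function(e) NULL)
      if (is.null(fit)) next
      groups <- fit$groups
      py <- fit$per_year
      names(py)[names(py) == "value"] <- tr
      per_year <- if (is.null(per_year)) py else merge(per_year, py,
                                                       by = c("genotype",
                                                              "year"))
    }
    for (yr in unique(per_year$year)) {
      d <- per_year[per_year$year == yr,
                    setdiff(names(per_year), "year"), drop = FALSE]
      datasets[[paste(yr, lev, sep = ".")]] <-
        structure(d, year = yr, n_level = lev)
    }
  }
  gwas <- run_gwas_pipeline(datasets, panel, K,
                            correct_maturity = correct_maturity,
                            groups = groups, ...)
  list(plot_traits = pt, datasets = datasets, groups = groups, gwas = gwas)
}
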