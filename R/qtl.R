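#' Keep marker-trait associations detected in both years
#'
#' Per nitrogen level, keeps the (trait, marker) pairs whose association
#' passes the thresholds in both years, and collapses them to one record
#' per (trait, marker, n_level) carrying the stronger year's statistics.
#'
#' @param records Thresholded association records with columns `trait`,
#'   `marker`, `chrom`, `pos_bp`, `year`, `n_level`, `minus_log10_p`,
#'   `explained_var_pct`.
#' @return Collapsed year-consistent records (columns as input minus
#'   `year`).
#' @export
year_consistent <- function(records) {
  if (length(unique(records$year)) < 2) {
    stop("records from both years are required")
  }
  key <- interaction(records$trait, records$marker, records$n_level,
                     drop = TRUE)
  both <- tapply(records$year, key, function(y) length(unique(y)) >= 2)
  keep <- records[both[key], , drop = FALSE]
  if (nrow(keep) == 0) {
    return(keep[, setdiff(names(keep), "year"), drop = FALSE])
  }
  parts <- split(keep, interaction(keep$trait, keep$marker, keep$n_level,
                                   drop = TRUE))
  out <- do.call(rbind, lapply(parts, function(g) {
    g <- g[order(-g$minus_log10_p, -g$explained_var_pct), , drop = FALSE]
    g[1, setdiff(names(g), "year"), drop = FALSE]
  }))
  rownames(out) <- NULL
  out
}

#' Classify year-consistent associations by nitrogen dependence
#'
#' Each (trait, marker) pair becomes `cm` (common) when detected at both
#' nitrogen levels, otherwise `HN` or `LN`.
#'
#' @param assoc Year-consistent records with an `n_level` column
#'   (`"HN"`/`"LN"`).
#' @return One record per (trait, marker) with an `n_class` column; for
#'   `cm` pairs the stronger level's statistics are carried.
#' @export
classify_n <- function(assoc) {
  if (nrow(assoc) == 0) {
    out <- assoc[, setdiff(names(assoc), "n_level"), drop = FALSE]
    out$n_class <- character(0)
    return(out)
  }
  parts <- split(assoc, interaction(assoc$trait, assoc$marker, drop = TRUE))
  out <- do.call(rbind, lapply(parts, function(g) {
    lv <- unique(g$n_level)
    g <- g[order(-g$minus_log10_p, -g$explained_var_pct), , drop = FALSE]
    r <- g[1, setdiff(names(g), "n_level"), drop = FALSE]
    r$n_class <- if (all(c("HN", "LN") %in% lv)) "cm" else lv[1]
    r
  }))
  rownames(out) <- NULL
  out
}

#' Consolidate classified associations into QTLs by LD windows
#'
#' Within each trait and chromosome, markers are merged by single linkage:
#' positions whose gaps are at most `merge_dist_bp` (linkage
#' disequilibrium taken as 4 Mb, i.e. a marker's +/-4 Mb window spans
#' 8 Mb) join one QTL. Markers of the same trait merge across nitrogen
#' levels; the merged QTL is `cm` when its member associations include
#' both levels. The peak member has the largest `-log10(p)` (ties broken
#' by larger explained variance, then lower position).
#'
#' @param assoc Classified associations with columns `trait`, `marker`,
#'   `chrom`, `pos_bp`, `n_class`, `minus_log10_p`, `explained_var_pct`.
#' @param merge_dist_bp Single-linkage merge distance in bp (default
#'   4,000,000).
#' @return Data frame of QTLs: `trait`, `chrom`, `n_class`, `peak_marker`,
#'   `peak_pos_bp`, `minus_log10_p`, `explained_var_pct`, `n_markers`,
#'   `start_bp`, `end_bp`, and a list column `members` of member
#'   positions.
#' @export
consolidate_qtls <- function(assoc, merge_dist_bp = 4e6) {
  need <- c("trait", "marker", "chrom", "pos_bp", "n_class",
            "minus_log10_p", "explained_var_pct")
  stopifnot(all(need %in% names(assoc)))
  if (anyNA(assoc$pos_bp)) stop("marker(s) missing from the map")
  if (nrow(assoc) == 0) {
    return(data.frame(trait = character(0), chrom = integer(0),
                      n_class = character(0), peak_marker = character(0),
                      peak_pos_bp = numeric(0), minus_log10_p = numeric(0),
                      explained_var_pct = numeric(0), n_markers = integer(0),
                      start_bp = numeric(0), end_bp = numeric(0)))
  }
  parts <- split(assoc, interaction(assoc$trait, assoc$chrom, drop = TRUE))
  qtls <- lapply(parts, function(g) {
    g <- g[order(g$pos_bp), , drop = FALSE]
    gap <- c(0, diff(g$pos_bp))
    cluster <- cumsum(gap > merge_dist_bp)
    lapply(split(g, cluster), function(m) {
      levels_present <- unique(m$n_class)
      n_class <- if ("cm" %in% levels_present ||
                     all(c("HN", "LN") %in% levels_present)) "cm"
                 else levels_present[1]
      peak <- m[order(-m$minus_log10_p, -m$explained_var_pct, m$pos_bp),
                , drop = FALSE][1, ]
      out <- data.frame(trait = m$trait[1], chrom = m$chrom[1],
                        n_class = n_class, peak_marker = peak$marker,
                        peak_pos_bp = peak$pos_bp,
                        minus_log10_p = peak$minus_log10_p,
                        explained_var_pct = peak$explained_var_pct,
                        n_markers = nrow(m), start_bp = min(m$pos_bp),
                        end_bp = max(m$pos_bp))
      out$members <- list(m$pos_bp)
      out
    })
  })
  out <- do.call(rbind, unlist(qtls, recursive = FALSE))
  rownames(out) <- NULL
  out[order(out$chrom, out$start_bp, out$trait), , drop = FALSE]
}

#' Flag QTLs colocalizing with maturity-associated markers
#'
#' A QTL is maturity-colocalized when any of its member markers lies
#' within `window_bp` of any maturity-assessment-associated marker on the
#' same chromosome.
#'
#' @param qtls Output of [consolidate_qtls()].
#' @param mt_markers Data frame with columns `chrom` and `pos_bp` of
#'   markers associated with the maturity assessment.
#' @param window_bp Colocalization distance in bp (default 4,000,000, a
#'   marker's +/-4 Mb window).
#' @return `qtls` with a logical `maturity_colocalized` column.
#' @export
colocalize_maturity <- function(qtls, mt_markers, window_bp = 4e6) {
  qtls$maturity_colocalized <- vapply(seq_len(nrow(qtls)), function(i) {
    mt <- mt_markers$pos_bp[mt_markers$chrom == qtls$chrom[i]]
    if (!length(mt)) return(FALSE)
    any(vapply(qtls$members[[i]], function(p) any(abs(p - mt) <= window_bp),
               TRUE))
  }, TRUE)
  qtls
}

#' Compare maturity-corrected and uncorrected QTL sets
#'
#' QTLs are matched across the two analyses when they share trait and
#' chromosome and their member markers come within `merge_dist_bp` of
#' each other.
#'
#' @param qtls_uncorrected,qtls_corrected Outputs of
#'   [consolidate_qtls()].
#' @param merge_dist_bp Matching distance in bp (default 4,000,000).
#' @return A list with data frames `both` (pairs of matched indices plus
#'   trait/chrom/n_class of each side), `uncorrected_only` and
#'   `corrected_only` (unmatched QTL rows).
#' @export
compare_analyses <- function(qtls_uncorrected, qtls_corrected,
                             merge_dist_bp = 4e6) {
  nu <- nrow(qtls_uncorrected); nc <- nrow(qtls_corrected)
  matched_u <- logical(nu); matched_c <- logical(nc)
  pairs <- list()
  for (i in seq_len(nu)) {
    for (j in seq_len(nc)) {
      if (qtls_uncorrected$trait[i] != qtls_corrected$trait[j]) next
      if (qtls_uncorrected$chrom[i] != qtls_corrected$chrom[j]) next
      du <- qtls_uncorrected$members[[i]]
      dc <- qtls_corrected$members[[j]]
      if (min(abs(outer(du, dc, "-"))) <= merge_dist_bp) {
        matched_u[i] <- TRUE; matched_c[j] <- TRUE
        pairs[[length(pairs) + 1L]] <- data.frame(
          trait = qtls_uncorrected$trait[i],
          chrom = qtls_uncorrected$chrom[i],
          n_class_uncorrected = qtls_uncorrected$n_class[i],
          n_class_corrected = qtls_corrected$n_class[j])
      }
    }
  }
  list(both = if (length(pairs)) do.call(rbind, pairs) else NULL,
       uncorrected_only = qtls_uncorrected[!matched_u, , drop = FALSE],
       corrected_only = qtls_corrected[!matched_c, , drop = FALSE])
}

#' Bookkeeping summary of marker-trait associations
#'
#' Tallies associations the way the published accounting tables do:
#' marker-trait-dataset associations, distinct marker-trait pairs,
#' distinct markers and traits, the both-years counts split by nitrogen
#' class, and the share of marker-trait pairs (and markers) lying within
#' `window_bp` of a maturity-assessment-associated marker.
#'
#' @param records Thresholded association records with columns `trait`,
#'   `marker`, `chrom`, `pos_bp`, `year`, `n_level`.
#' @param mt_trait Name of the maturity-assessment trait (default
#'   `"mt_as"`).
#' @param window_bp Colocalization distance in bp (default 4,000,000).
#' @return A list of counts: `n_assoc_set`, `n_marker_trait`, `n_marker`,
#'   `n_trait`, `both_years` (per n_class and total) and
#'   `pct_maturity_related` (marker-trait and marker bases, both-years
#'   set).
#' @export
summarize_associations <- function(records, mt_trait = "mt_as",
                                   window_bp = 4e6) {
  mt_key <- paste(records$trait, records$marker)
  n_assoc_set <- nrow(unique(records[, c("trait", "marker", "year",
                                         "n_level")]))
  n_marker_trait <- length(unique(mt_key))
  yc <- classify_n(year_consistent(records))
  mt_pos <- unique(records[records$trait == mt_trait &
                             paste(records$trait, records$marker) %in%
                             paste(yc$trait, yc$marker),
                           c("chrom", "pos_bp")])
  yc$mt_related <- vapply(seq_len(nrow(yc)), function(i) {
    p <- mt_pos$pos_bp[mt_pos$chrom == yc$chrom[i]]
    length(p) > 0 && any(abs(yc$pos_bp[i] - p) <= window_bp)
  }, TRUE)
  per_class <- function(cls) {
    sub <- yc[yc$n_class == cls, , drop = FALSE]
    list(n_marker_trait = nrow(sub),
         n_marker = length(unique(sub$marker)),
         n_trait = length(unique(sub$trait)),
         pct_mt_marker_trait = if (nrow(sub)) 100 * mean(sub$mt_related)
                               else 0,
         pct_mt_marker = if (nrow(sub)) {
           100 * mean(tapply(sub$mt_related, sub$marker, any))
         } else 0)
  }
  list(n_assoc_set = n_assoc_set,
       n_marker_trait = n_marker_trait,
       n_marker = length(unique(records$marker)),
       n_trait = length(unique(records$trait)),
       both_years = list(
         total = list(
           n_marker_trait = nrow(yc),
           n_marker = length(unique(yc$marker)),
           n_trait = length(unique(yc$trait)),
           pct_mt_marker_trait = if (nrow(yc)) 100 * mean(yc$mt_related)
                                 else 0,
           pct_mt_marker = if (nrow(yc)) {
             100 * mean(tapply(yc$mt_related, yc$marker, any))
           } else 0),
         cm = per_class("cm"),
         HN = per_class("HN"),
         LN = per_class("LN")))
}
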