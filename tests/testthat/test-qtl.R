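mk_rec <- function(trait, marker, chrom, pos, year, n_level,
                   logp = 5, ev = 15) {
  data.frame(trait = trait, marker = marker, chrom = chrom, pos_bp = pos,
             year = year, n_level = n_level, minus_log10_p = logp,
             explained_var_pct = ev)
}

test_that("year consistency keeps pairs detected in both years per N level", {
  recs <- rbind(
    mk_rec("t", "m1", 1, 1e6, 2009, "HN"), mk_rec("t", "m1", 1, 1e6, 2010, "HN"),
    mk_rec("t", "m2", 1, 2e6, 2009, "HN"),                       # one year only
    mk_rec("t", "m3", 1, 3e6, 2009, "HN"), mk_rec("t", "m3", 1, 3e6, 2010, "LN"))
  out <- year_consistent(recs)
  expect_equal(out$marker, "m1")
  expect_equal(out$n_level, "HN")
  expect_error(year_consistent(mk_rec("t", "m1", 1, 1e6, 2009, "HN")),
               "both years")
})

test_that("year consistency matches brute-force enumeration of flag patterns", {
  set.seed(51)
  combos <- expand.grid(y2009_HN = c(TRUE, FALSE), y2010_HN = c(TRUE, FALSE),
                        y2009_LN = c(TRUE, FALSE), y2010_LN = c(TRUE, FALSE))
  combos <- combos[rowSums(combos) > 0, ]
  recs <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    f <- combos[i, ]
    mk <- sprintf("m%02d", i)
    rows <- list()
    if (f$y2009_HN) rows <- c(rows, list(mk_rec("t", mk, 1, i * 1e7, 2009, "HN")))
    if (f$y2010_HN) rows <- c(rows, list(mk_rec("t", mk, 1, i * 1e7, 2010, "HN")))
    if (f$y2009_LN) rows <- c(rows, list(mk_rec("t", mk, 1, i * 1e7, 2009, "LN")))
    if (f$y2010_LN) rows <- c(rows, list(mk_rec("t", mk, 1, i * 1e7, 2010, "LN")))
    do.call(rbind, rows)
  }))
  out <- year_consistent(recs)
  expected_hn <- sprintf("m%02d", which(combos$y2009_HN & combos$y2010_HN))
  expected_ln <- sprintf("m%02d", which(combos$y2009_LN & combos$y2010_LN))
  expect_setequal(out$marker[out$n_level == "HN"], expected_hn)
  expect_setequal(out$marker[out$n_level == "LN"], expected_ln)
})

test_that("N classification assigns cm/HN/LN from the surviving levels", {
  yc <- rbind(mk_rec("t", "m1", 1, 1e6, NA, "HN")[-5],
              mk_rec("t", "m1", 1, 1e6, NA, "LN")[-5],
              mk_rec("t", "m2", 1, 2e6, NA, "HN")[-5])
  yc$year <- NULL
  out <- classify_n(yc)
  expect_equal(out$n_class[out$marker == "m1"], "cm")
  expect_equal(out$n_class[out$marker == "m2"], "HN")
  empty <- classify_n(yc[0, ])
  expect_equal(nrow(empty), 0)
})

mk_assoc <- function(trait, chrom, pos, n_class, logp = 5, ev = 15,
                     marker = NULL) {
  data.frame(trait = trait,
             marker = if (is.null(marker)) sprintf("mk_%d_%d", chrom, pos)
                      else marker,
             chrom = chrom, pos_bp = pos, n_class = n_class,
             minus_log10_p = logp, explained_var_pct = ev)
}

test_that("markers merge within 4 Mb and stay apart beyond it", {
  near <- rbind(mk_assoc("t", 2, 10e6, "HN"), mk_assoc("t", 2, 13e6, "HN"))
  expect_equal(nrow(consolidate_qtls(near)), 1)
  far <- rbind(mk_assoc("t", 2, 10e6, "HN"), mk_assoc("t", 2, 15e6, "HN"))
  expect_equal(nrow(consolidate_qtls(far)), 2)
  # different traits never merge
  two <- rbind(mk_assoc("a", 2, 10e6, "HN"), mk_assoc("b", 2, 10.5e6, "HN"))
  expect_equal(nrow(consolidate_qtls(two)), 2)
})

test_that("cross-N merging yields a common QTL with the right peak", {
  assoc <- rbind(mk_assoc("t", 3, 212547269, "LN", logp = 4.49, ev = 10.32),
                 mk_assoc("t", 3, 212548683, "HN", logp = 5.08, ev = 11.57))
  out <- consolidate_qtls(assoc)
  expect_equal(nrow(out), 1)
  expect_equal(out$n_class, "cm")
  expect_equal(out$peak_pos_bp, 212548683)
  expect_equal(out$minus_log10_p, 5.08)
})

test_that("consolidation is invariant to input order and obeys the gap rule", {
  set.seed(52)
  for (rep in 1:10) {
    n <- 25
    assoc <- mk_assoc("t", sample(1:3, n, TRUE),
                      sample(seq(1e6, 70e6, by = 5e5), n), "HN",
                      logp = runif(n, 4, 9), ev = runif(n, 10, 25))
    assoc$marker <- sprintf("m%02d", seq_len(n))
    q1 <- consolidate_qtls(assoc)
    q2 <- consolidate_qtls(assoc[sample(n), ])
    expect_equal(q1[order(q1$chrom, q1$start_bp), ],
                 q2[order(q2$chrom, q2$start_bp), ],
                 ignore_attr = TRUE)
    # every adjacent pair of member positions within a QTL is <= 4 Mb apart
    for (m in q1$members) {
      if (length(m) > 1) expect_true(all(diff(sort(m)) <= 4e6))
    }
    # peak is always a member
    expect_true(all(mapply(function(p, m) p %in% m, q1$peak_pos_bp,
                           q1$members)))
  }
})

test_that("peak ties break by explained variance, then position", {
  assoc <- rbind(
    mk_assoc("t", 1, 10e6, "HN", logp = 5, ev = 12),
    mk_assoc("t", 1, 11e6, "HN", logp = 5, ev = 18),
    mk_assoc("t", 1, 12e6, "HN", logp = 5, ev = 18))
  out <- consolidate_qtls(assoc)
  expect_equal(out$peak_pos_bp, 11e6)
})

test_that("maturity colocalization respects the 4 Mb window", {
  qtls <- consolidate_qtls(rbind(
    mk_assoc("te-t2", 5, 316045624, "LN"),
    mk_assoc("TbnB", 3, 216014512, "LN"),
    mk_assoc("x", 7, 10e6, "HN")))
  mt <- data.frame(chrom = c(5, 3), pos_bp = c(316045624, 204691153))
  out <- colocalize_maturity(qtls, mt)
  expect_true(out$maturity_colocalized[out$trait == "te-t2"])   # same position
  expect_false(out$maturity_colocalized[out$trait == "TbnB"])   # 11.3 Mb away
  expect_false(out$maturity_colocalized[out$trait == "x"])      # no mt marker
})

test_that("analysis comparison partitions identical and disjoint sets", {
  qa <- consolidate_qtls(rbind(mk_assoc("a", 1, 10e6, "HN"),
                               mk_assoc("b", 2, 20e6, "cm")))
  cmp <- compare_analyses(qa, qa)
  expect_equal(nrow(cmp$both), 2)
  expect_equal(nrow(cmp$uncorrected_only), 0)
  expect_equal(nrow(cmp$corrected_only), 0)
  qb <- consolidate_qtls(mk_assoc("a", 5, 10e6, "HN"))
  cmp2 <- compare_analyses(qa, qb)
  expect_null(cmp2$both)
  expect_equal(nrow(cmp2$uncorrected_only), 2)
  expect_equal(nrow(cmp2$corrected_only), 1)
})

test_that("association bookkeeping matches brute-force tallies", {
  recs <- rbind(
    mk_rec("mt_as", "m1", 5, 50e6, 2009, "HN"),
    mk_rec("mt_as", "m1", 5, 50e6, 2010, "HN"),
    mk_rec("mt_as", "m1", 5, 50e6, 2009, "LN"),
    mk_rec("mt_as", "m1", 5, 50e6, 2010, "LN"),
    mk_rec("yld", "m2", 5, 51e6, 2009, "HN"),   # within 4 Mb of m1
    mk_rec("yld", "m2", 5, 51e6, 2010, "HN"),
    mk_rec("dm", "m3", 2, 10e6, 2009, "LN"),
    mk_rec("dm", "m3", 2, 10e6, 2010, "LN"),
    mk_rec("dm", "m4", 9, 30e6, 2009, "HN"))    # single year
  s <- summarize_associations(recs)
  expect_equal(s$n_assoc_set, 9)
  expect_equal(s$n_marker_trait, 4)
  expect_equal(s$n_marker, 4)
  expect_equal(s$n_trait, 3)
  expect_equal(s$both_years$total$n_marker_trait, 3)
  expect_equal(s$both_years$cm$n_marker_trait, 1)   # mt_as itself
  expect_equal(s$both_years$HN$n_marker_trait, 1)   # yld
  expect_equal(s$both_years$LN$n_marker_trait, 1)   # dm
  expect_equal(s$both_years$HN$pct_mt_marker_trait, 100)  # yld near mt_as
  expect_equal(s$both_years$LN$pct_mt_marker_trait, 0)
})

test_that("a single repeated association deduplicates to one marker-trait pair", {
  recs <- rbind(mk_rec("t", "m1", 1, 1e6, 2009, "HN"),
                mk_rec("t", "m1", 1, 1e6, 2010, "HN"),
                mk_rec("t", "m1", 1, 1e6, 2009, "LN"),
                mk_rec("t", "m1", 1, 1e6, 2010, "LN"))
  s <- summarize_associations(recs)
  expect_equal(s$n_marker_trait, 1)
  expect_equal(s$both_years$cm$n_marker_trait, 1)
  expect_equal(s$both_years$cm$pct_mt_marker_trait, 0)  # no mt_as trait
})
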