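#' Tetraploid SNP dosage panel
#'
#' Individuals-by-markers dosage matrix (values 0-4 or `NA`) with a marker
#' map.
#'
#' @param dosages Numeric matrix, individuals in rows (rownames =
#'   genotype ids), markers in columns (colnames = marker ids); entries
#'   integral in `[0, 4]` or `NA`.
#' @param map Data frame with columns `marker`, `chrom` (1-12) and
#'   `pos_bp`, covering every dosage column; positions sorted within
#'   chromosome.
#' @return An object of class `dosage_panel` (list with `dosages`, `map`).
#' @export
dosage_panel <- function(dosages, map) {
  stopifnot(is.matrix(dosages), is.data.frame(map),
            all(c("marker", "chrom", "pos_bp") %in% names(map)))
  vals <- dosages[!is.na(dosages)]
  if (any(vals < 0 | vals > 4 | vals != round(vals))) {
    stop("dosages must be integers in [0, 4] or NA")
  }
  if (is.null(colnames(dosages))) stop("dosage columns must be named")
  if (!setequal(colnames(dosages), map$marker)) {
    stop("marker map must cover exactly the dosage columns")
  }
  map <- map[match(colnames(dosages), map$marker), , drop = FALSE]
  if (any(map$pos_bp < 0)) stop("positions must be non-negative")
  for (ch in unique(map$chrom)) {
    if (is.unsorted(map$pos_bp[map$chrom == ch])) {
      stop("positions must be sorted within chromosome ", ch)
    }
  }
  rownames(map) <- NULL
  structure(list(dosages = dosages, map = map), class = "dosage_panel")
}

#' @export
print.dosage_panel <- function(x, ...) {
  cat(sprintf("Dosage panel: %d individuals x %d markers on %d chromosomes\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$map$chrom))))
  invisible(x)
}

#' Filter markers on dosage-class frequencies
#'
#' Keeps markers for which at least two of the five dosage classes
#' (nulliplex to tetraplex) each exceed `min_class_freq` among non-missing
#' calls; all other markers (including monomorphic ones) are dropped.
#'
#' @param panel A [dosage_panel()].
#' @param min_class_freq Minimum genotype-class frequency (default 0.05).
#' @return The filtered [dosage_panel()]; the number of dropped markers
#'   is stored in `attr(, "n_dropped")`.
#' @export
filter_markers <- function(panel, min_class_freq = 0.05) {
  stopifnot(inherits(panel, "dosage_panel"))
  if (ncol(panel$dosages) == 0) stop("empty panel")
  keep <- apply(panel$dosages, 2, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(FALSE)
    freq <- tabulate(x + 1L, nbins = 5L) / length(x)
    sum(freq > min_class_freq) >= 2
  })
  out <- dosage_panel(panel$dosages[, keep, drop = FALSE],
                      panel$map[keep, , drop = FALSE])
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Realised kinship matrix from a dosage subset
#'
#' Draws `n_subset` markers stratified by chromosome (proportional to
#' marker counts), centres each dosage column (missing values imputed at
#' the marker mean) and forms `K = Z Z' / c` with `c` the mean diagonal,
#' so that `trace(K)/n = 1`.
#'
#' @param panel A [dosage_panel()].
#' @param n_subset Number of markers used (default 764); if the panel has
#'   fewer, all markers are used with a warning.
#' @param seed Optional integer seed for the stratified draw.
#' @return Symmetric positive semi-definite kinship matrix with genotype
#'   ids as dimnames.
#' @export
compute_kinship <- function(panel, n_subset = 764, seed = NULL) {
  stopifnot(inherits(panel, "dosage_panel"))
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(panel$dosages)
  if (p < n_subset) {
    warning("panel has fewer than ", n_subset, " markers; using all ", p)
    idx <- seq_len(p)
  } else {
    by_chr <- split(seq_len(p), panel$map$chrom)
    alloc <- vapply(by_chr, length, 1L)
    take <- pmax(1L, round(n_subset * alloc / sum(alloc)))
    idx <- unlist(mapply(function(cols, k) {
      sample(cols, min(k, length(cols)))
    }, by_chr, take, SIMPLIFY = FALSE), use.names = FALSE)
  }
  Z <- panel$dosages[, idx, drop = FALSE]
  Z <- apply(Z, 2, function(x) {
    m <- mean(x, na.rm = TRUE)
    x[is.na(x)] <- m
    x - m
  })
  K <- tcrossprod(Z)
  K / mean(diag(K))
}

## EMMA-style restricted likelihood for y = mu + g + e with
## var(g) = sigma_g^2 K, on the eigenbasis of K. Returns variance
## components maximising the REML criterion over the ratio
## delta = sigma_g^2 / sigma_e^2.
reml_null <- function(y, eig) {
  n <- length(y)
  uty <- crossprod(eig$vectors, y)
  utx <- crossprod(eig$vectors, rep(1, n))
  d <- pmax(eig$values, 0)
  neg_restll <- function(log_delta) {
    delta <- exp(log_delta)
    v <- delta * d + 1
    w <- 1 / v
    xwx <- sum(utx^2 * w)
    beta <- sum(utx * uty * w) / xwx
    r <- uty - utx * beta
    rss_w <- sum(r^2 * w)
    s2 <- rss_w / (n - 1)
    0.5 * ((n - 1) * log(s2) + sum(log(v)) + log(xwx))
  }
  opt <- stats::optimize(neg_restll, interval = c(-12, 12))
  delta <- exp(opt$minimum)
  v <- delta * d + 1
  w <- 1 / v
  xwx <- sum(utx^2 * w)
  beta <- sum(utx * uty * w) / xwx
  rss_w <- sum((uty - utx * beta)^2 * w)
  sigma_e2 <- rss_w / (n - 1)
  list(sigma_g2 = delta * sigma_e2, sigma_e2 = sigma_e2, delta = delta)
}

#' Kinship-corrected association scan over a dosage panel
#'
#' Mixed-model scan `trait = marker + genotype + residual` with
#' `var(genotype) = K sigma_g^2`. Variance components are estimated once
#' per trait under the no-marker null by restricted maximum likelihood on
#' the eigendecomposition of `K`, then reused for every marker
#' (the "population parameters previously determined" scheme). Each
#' marker enters as an additive dosage predictor (0-4, marker-mean
#' imputation for missing calls); the marker effect gets a two-sided Wald
#' test on the decorrelated scale, and the explained variance is
#' `100 * (1 - RSS_marker / RSS_null)` on that same scale.
#'
#' @param traits Data frame with a `genotype` column and one column per
#'   trait, or a named numeric vector (single trait named via `trait_name`).
#' @param panel A filtered [dosage_panel()] whose individuals match the
#'   trait genotypes.
#' @param K Kinship matrix from [compute_kinship()] (dimnames = genotype
#'   ids).
#' @param trait_name Trait label used when `traits` is a vector.
#' @param dataset Optional label (e.g. `"2009.HN"`) copied into the
#'   records.
#' @return Data frame of association records: `trait`, `dataset`,
#'   `marker`, `chrom`, `pos_bp`, `effect`, `minus_log10_p`,
#'   `explained_var_pct`. Markers with zero variance after decorrelation
#'   are skipped.
#' @export
association_scan <- function(traits, panel, K, trait_name = "trait",
                             dataset = NA_character_) {
  stopifnot(inherits(panel, "dosage_panel"))
  if (is.numeric(traits)) {
    traits <- data.frame(genotype = names(traits), value = as.numeric(traits))
    names(traits)[2] <- trait_name
  }
  ids <- traits$genotype
  if (!all(ids %in% rownames(panel$dosages)) || !all(ids %in% rownames(K))) {
    stop("genotype ids of traits, panel and kinship are not aligned")
  }
  M <- panel$dosages[ids, , drop = FALSE]
  M <- apply(M, 2, function(x) {
    m <- mean(x, na.rm = TRUE)
    x[is.na(x)] <- m
    x
  })
  K <- K[ids, ids]
  eig <- eigen(K, symmetric = TRUE)
  n <- length(ids)
  UtM <- crossprod(eig$vectors, M)
  Ut1 <- crossprod(eig$vectors, rep(1, n))
  d <- pmax(eig$values, 0)

  trait_cols <- setdiff(names(traits), c("genotype", "maturity_group"))
  res <- lapply(trait_cols, function(tc) {
    y <- traits[[tc]]
    ok <- !is.na(y)
    if (sum(ok) < n) {
      ## refit alignment on complete cases only
      sub <- traits[ok, c("genotype", tc)]
      return(association_scan(stats::setNames(sub[[tc]], sub$genotype),
                              panel, K, trait_name = tc, dataset = dataset))
    }
    vc <- reml_null(y, eig)
    v <- vc$delta * d + 1
    w <- 1 / sqrt(v)
    ys <- w * as.numeric(crossprod(eig$vectors, y))
    xs <- w * as.numeric(Ut1)
    Ms <- UtM * w
    ## project out the (decorrelated) intercept
    xx <- sum(xs^2)
    ys_r <- ys - xs * (sum(xs * ys) / xx)
    Ms_r <- Ms - outer(xs, colSums(Ms * xs) / xx)
    mm <- colSums(Ms_r^2)
    keep <- mm > 1e-10
    my <- colSums(Ms_r * ys_r)[keep]
    mm <- mm[keep]
    beta <- my / mm
    rss0 <- sum(ys_r^2)
    rss <- pmax(rss0 - beta * my, 0)
    df <- n - 2
    se <- sqrt(rss / df / mm)
    tstat <- beta / se
    logp <- -(log(2) + stats::pt(-abs(tstat), df, log.p = TRUE)) / log(10)
    data.frame(trait = tc, dataset = dataset,
               marker = panel$map$marker[keep],
               chrom = panel$map$chrom[keep],
               pos_bp = panel$map$pos_bp[keep],
               effect = beta, minus_log10_p = logp,
               explained_var_pct = 100 * (1 - rss / rss0),
               row.names = NULL)
  })
  do.call(rbind, res)
}

#' Apply the reporting thresholds to association records
#'
#' Keeps records with `minus_log10_p > min_logp` and
#' `explained_var_pct > min_ev` (both strict).
#'
#' @param records Data frame of association records.
#' @param min_logp Threshold on `-log10(p)` (default 4).
#' @param min_ev Threshold on explained variance in percent (default 10).
#' @return The filtered records.
#' @export
threshold_associations <- function(records, min_logp = 4.0, min_ev = 10.0) {
  records[records$minus_log10_p > min_logp &
            records$explained_var_pct > min_ev, , drop = FALSE]
}
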