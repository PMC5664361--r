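# Profile similarity vs gene co-expression and protein-protein interaction.

#' Quantile-normalise an expression matrix
#'
#' Every sample (column) is forced onto the common distribution obtained by
#' averaging the sorted columns: the value at rank r becomes the
#' across-sample mean of the r-th smallest values. Ties within a column
#' receive the mean of their rank-slot values. Idempotent on tie-free data.
#'
#' @param m numeric matrix (genes x samples).
#' @return matrix of the same shape.
#' @export
quantile_normalize <- function(m) {
  sorted <- apply(m, 2L, sort)
  ref <- rowMeans(sorted)
  # rank-slots already constant across samples must average bit-exactly,
  # so that re-normalising normalized data is the identity
  const <- rowSums(sorted == sorted[, 1L]) == ncol(sorted)
  ref[const] <- sorted[const, 1L]
  out <- m
  for (j in seq_len(ncol(m))) {
    r <- rank(m[, j], ties.method = "average")
    lo <- floor(r); hi <- ceiling(r)
    out[, j] <- (ref[lo] + ref[hi]) / 2
  }
  out
}

#' Preprocess an expression matrix
#'
#' Natural-log transform, quantile normalization, then independent
#' Bernoulli column subsampling (keeping each sample with probability
#' `sample_keep_prob`) to cut computation, the usual screening shortcut for
#' very large hybridization collections.
#'
#' @param m numeric matrix of strictly positive intensities.
#' @param sample_keep_prob per-sample keep probability (default 0.10).
#' @param seed integer seed for the subsampling.
#' @return preprocessed matrix (possibly fewer columns; at least one column
#'   is always retained).
#' @export
preprocess_expression <- function(m, sample_keep_prob = 0.10, seed = 1L) {
  if (any(m <= 0)) stop("expression intensities must be strictly positive")
  out <- quantile_normalize(log(m))
  if (sample_keep_prob < 1) {
    old <- .save_rng(seed)
    on.exit(.restore_rng(old))
    keep <- stats::runif(ncol(out)) < sample_keep_prob
    if (!any(keep)) keep[sample.int(ncol(out), 1L)] <- TRUE
    out <- out[, keep, drop = FALSE]
  }
  out
}

# d_PP for gene pairs via their containing objects; genes sharing an object
# get d_PP = 1 (drop_same_object removes them instead).
.gene_pair_dpp <- function(g1, g2, gene2object, profiles,
                           drop_same_object = FALSE) {
  o1 <- gene2object[g1]; o2 <- gene2object[g2]
  same <- o1 == o2
  p <- profiles > 0
  d <- numeric(length(g1))
  d[same] <- 1
  if (any(!same)) {
    A <- p[o1[!same], , drop = FALSE]; B <- p[o2[!same], , drop = FALSE]
    d[!same] <- rowSums(A & B) / rowSums(A | B)
  }
  if (drop_same_object) d[same] <- NA_real_
  d
}

#' Co-expression against profile similarity
#'
#' Selects `n_genes` genes at random among those with both an expression row
#' and a profiled object, forms all unordered pairs, and relates each pair's
#' profile similarity d_PP to its Pearson expression correlation r_GE.
#' Reports the raw records, the Pearson correlation between d_PP and r_GE
#' with its test, a linear fit, a logistic fit, and the median r_GE per
#' 0.1-wide d_PP bin.
#'
#' @param expr preprocessed expression matrix (genes x samples).
#' @param gene2object named character vector gene id -> object id.
#' @param profiles 0/1 profile matrix over the objects.
#' @param n_genes genes to sample (default 500).
#' @param seed integer seed.
#' @param bin_width d_PP bin width for the medians (default 0.1).
#' @param drop_same_object drop pairs whose genes share an object (default
#'   `FALSE`: they are kept with d_PP = 1).
#' @return list: `records` (data.frame `gene1`, `gene2`, `d_pp`, `r_ge`),
#'   `correlation`, `cor_p`, `linear` (intercept/slope), `logistic`
#'   (a [fit_logistic()] result), `binned` (data.frame `bin_lo`, `bin_hi`,
#'   `n`, `median_r_ge`), `n_dropped`.
#' @export
coexpression_vs_profile <- function(expr, gene2object, profiles,
                                    n_genes = 500L, seed = 1L,
                                    bin_width = 0.1,
                                    drop_same_object = FALSE) {
  if (ncol(expr) < 3L)
    stop("need at least 3 expression samples to correlate genes")
  eligible <- intersect(rownames(expr), names(gene2object))
  eligible <- eligible[gene2object[eligible] %in% rownames(profiles)]
  if (length(eligible) < 2L) stop("need at least 2 eligible genes")
  old <- .save_rng(seed)
  sel <- if (length(eligible) > n_genes)
    sort(sample(eligible, n_genes)) else sort(eligible)
  .restore_rng(old)
  cm <- stats::cor(t(expr[sel, , drop = FALSE]))
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  g1 <- sel[pairs[, 1L]]; g2 <- sel[pairs[, 2L]]
  d_pp <- .gene_pair_dpp(g1, g2, gene2object, profiles,
                         drop_same_object = drop_same_object)
  r_ge <- cm[pairs]
  keep <- !is.na(d_pp) & !is.na(r_ge)
  records <- data.frame(gene1 = g1[keep], gene2 = g2[keep],
                        d_pp = d_pp[keep], r_ge = r_ge[keep],
                        stringsAsFactors = FALSE)
  if (nrow(records) >= 3L && stats::sd(records$d_pp) > 0) {
    ct <- stats::cor.test(records$d_pp, records$r_ge)
    correlation <- unname(ct$estimate); cor_p <- ct$p.value
  } else {
    correlation <- NA_real_; cor_p <- NA_real_
  }
  lin <- stats::lm(r_ge ~ d_pp, data = records)
  logi <- fit_logistic(records$d_pp, records$r_ge)
  lo <- seq(0, 1 - bin_width, by = bin_width)
  bins <- data.frame(bin_lo = lo, bin_hi = lo + bin_width)
  bins$n <- 0L; bins$median_r_ge <- NA_real_
  idx <- pmin(floor(records$d_pp / bin_width) + 1L, nrow(bins))
  for (b in unique(idx)) {
    v <- records$r_ge[idx == b]
    bins$n[b] <- length(v)
    bins$median_r_ge[b] <- stats::median(v)
  }
  list(records = records,
       correlation = correlation, cor_p = cor_p,
       linear = stats::coef(lin), logistic = logi, binned = bins,
       n_dropped = sum(!keep))
}

#' Profile similarity of interacting vs non-interacting protein pairs
#'
#' Maps the interaction pairs onto gene objects, computes d_PP for every
#' reported (experimentally supported) pair, and compares the distribution
#' with the d_PP of all other mappable gene pairs (the exhaustive
#' non-interacting background, uniformly subsampled above `max_background`
#' pairs) by a two-sided Wilcoxon rank-sum test.
#'
#' @param ppi data.frame from [read_ppi_table()].
#' @param gene2object named character vector gene id -> object id.
#' @param profiles 0/1 profile matrix.
#' @param max_background background pairs computed exhaustively up to this
#'   many (default 1e6), beyond that subsampled.
#' @param seed seed for background subsampling.
#' @param drop_same_object see [coexpression_vs_profile()].
#' @return list of class `ppi_comparison`: `d_interacting`,
#'   `d_noninteracting`, `median_interacting`, `median_noninteracting`,
#'   `p_value`, `n_interacting`, `n_noninteracting`,
#'   `background_subsampled`.
#' @export
ppi_profile_comparison <- function(ppi, gene2object, profiles,
                                   max_background = 1e6, seed = 1L,
                                   drop_same_object = FALSE) {
  mapped <- names(gene2object)[gene2object %in% rownames(profiles)]
  keep <- ppi$gene_a %in% mapped & ppi$gene_b %in% mapped
  int <- unique(ppi[keep, c("gene_a", "gene_b")])
  if (nrow(int) == 0L) stop("no interacting pair maps onto profiled objects")
  d_int <- .gene_pair_dpp(int$gene_a, int$gene_b, gene2object, profiles,
                          drop_same_object = drop_same_object)
  d_int <- d_int[!is.na(d_int)]
  genes <- sort(mapped)
  n <- length(genes)
  int_key <- paste(int$gene_a, int$gene_b, sep = "\r")
  n_total <- n * (n - 1) / 2
  subsampled <- n_total > max_background
  if (!subsampled) {
    pairs <- t(utils::combn(genes, 2L))
    g1 <- pairs[, 1L]; g2 <- pairs[, 2L]
  } else {
    old <- .save_rng(seed)
    on.exit(.restore_rng(old))
    i <- sample.int(n, max_background, replace = TRUE)
    j <- sample.int(n, max_background, replace = TRUE)
    ok <- i != j
    i <- i[ok]; j <- j[ok]
    g1 <- pmin(genes[i], genes[j]); g2 <- pmax(genes[i], genes[j])
  }
  key <- paste(g1, g2, sep = "\r")
  bg <- !(key %in% int_key)
  d_non <- .gene_pair_dpp(g1[bg], g2[bg], gene2object, profiles,
                          drop_same_object = drop_same_object)
  d_non <- d_non[!is.na(d_non)]
  w <- suppressWarnings(stats::wilcox.test(d_int, d_non))
  structure(list(d_interacting = d_int, d_noninteracting = d_non,
                 median_interacting = stats::median(d_int),
                 median_noninteracting = stats::median(d_non),
                 p_value = w$p.value,
                 n_interacting = length(d_int),
                 n_noninteracting = length(d_non),
                 background_subsampled = subsampled),
            class = "ppi_comparison")
}

#' @export
print.ppi_comparison <- function(x, ...) {
  cat(sprintf(paste0("<ppi_comparison> median d_PP: interacting %.3f (n=%d)",
                     " vs non-interacting %.3f (n=%d), Wilcoxon p = %.3g\n"),
              x$median_interacting, x$n_interacting,
              x$median_noninteracting, x$n_noninteracting, x$p_value))
  invisible(x)
}
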