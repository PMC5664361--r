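# Independent brute-force oracles. These deliberately re-derive every
# statistic from first principles (explicit pair loops, exhaustive threshold
# sweeps, pair-counting agreement) and never call the implementation paths
# they check.

# fraction of identical unordered pairs within a key vector
oracle_fraction_within <- function(keys) {
  n <- length(keys)
  if (n < 2) return(NA_real_)
  hits <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    hits <- hits + (keys[i] == keys[j])
  hits / (n * (n - 1) / 2)
}

# within pairs + member-vs-outside cross pairs over the combined denominator
oracle_fraction_overall <- function(kin, kout) {
  n <- length(kin); m <- length(kout)
  denom <- n * (n - 1) / 2 + n * m
  if (denom == 0) return(NA_real_)
  hits <- 0
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n)
    hits <- hits + (kin[i] == kin[j])
  if (m >= 1) for (i in seq_len(n)) for (j in seq_len(m))
    hits <- hits + (kin[i] == kout[j])
  hits / denom
}

# adjusted Rand via explicit pair-category counting
oracle_ari <- function(a, b) {
  n <- length(a)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (sa && !sb) n10 <- n10 + 1
    else if (!sa && sb) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  num <- 2 * (n00 * n11 - n01 * n10)
  den <- (n00 + n01) * (n01 + n11) + (n00 + n10) * (n10 + n11)
  if (den == 0) return(1)
  num / den
}

# step-wise PR area by explicit sweep over distinct thresholds
oracle_aucprc <- function(scores, truth) {
  truth <- as.logical(truth)
  P <- sum(truth)
  if (P == 0) return(NA_real_)
  thr <- sort(unique(scores), decreasing = TRUE)
  area <- 0
  prev_recall <- 0
  for (t in thr) {
    called <- scores >= t
    tp <- sum(called & truth)
    precision <- tp / sum(called)
    recall <- tp / P
    area <- area + precision * (recall - prev_recall)
    prev_recall <- recall
  }
  area
}

# random label-set list for prediction tests
random_label_sets <- function(ids, universe, max_k = 3) {
  out <- lapply(ids, function(i) sample(universe, sample.int(max_k, 1)))
  stats::setNames(out, ids)
}

# random 0/1 profile matrix with guaranteed non-zero rows
random_profiles <- function(n_obj, n_sp, p = 0.5) {
  m <- matrix(rbinom(n_obj * n_sp, 1, p), n_obj, n_sp,
              dimnames = list(sprintf("O%04d", seq_len(n_obj)),
                              sprintf("SP%02d", seq_len(n_sp))))
  zero <- rowSums(m) == 0
  m[cbind(which(zero), sample.int(n_sp, sum(zero), replace = TRUE))] <- 1L
  m
}

write_tsv_fixture <- function(lines, file = tempfile(fileext = ".tsv")) {
  writeLines(lines, file)
  file
}
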