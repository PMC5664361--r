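# Identical-profile enrichment.
#
# For a pathway with n_f member gene objects, F_pw is the fraction of the
# n_f(n_f-1)/2 unordered member pairs whose profiles are bit-identical.
# F_all extends the comparison to the n_allO objects outside the pathway:
#   F_all = (identical within pairs + identical cross pairs)
#           / (n_f(n_f-1)/2 + n_f * n_allO),
# outside-outside pairs are never compared. The enrichment is E = F_pw/F_all.
# Significance is assessed by an empirical null: redraw n_f objects uniformly
# without replacement from the full object pool, recompute E, and report the
# fraction of draws reaching the observed E or more.

.as_keys <- function(profiles) {
  if (is.matrix(profiles)) profile_keys(profiles) else as.character(profiles)
}

#' Fraction of identical profile pairs within a pathway
#'
#' @param pathway_profiles profiles of the pathway's member objects: a 0/1
#'   matrix (rows = objects) or a character vector of profile keys.
#' @return fraction in \[0,1\], or `NA` (undefined) when fewer than two
#'   members exist — such pathways must be excluded from testing, not scored
#'   as 0.
#' @export
fraction_identical_within <- function(pathway_profiles) {
  keys <- .as_keys(pathway_profiles)
  n <- length(keys)
  if (n < 2L) return(NA_real_)
  counts <- table(keys)
  sum(counts * (counts - 1) / 2) / (n * (n - 1) / 2)
}

#' Fraction of identical pairs against the full object pool
#'
#' Combines the within-pathway pairs with all (member, outside) cross pairs;
#' outside-outside pairs are not compared. With an empty outside set this
#' reduces exactly to [fraction_identical_within()].
#'
#' @param pathway_profiles member profiles (matrix or keys).
#' @param outside_profiles profiles of all objects not in the pathway.
#' @return fraction in \[0,1\], or `NA` when no pair exists (single member
#'   and empty outside set).
#' @export
fraction_identical_overall <- function(pathway_profiles, outside_profiles) {
  kin <- .as_keys(pathway_profiles)
  kout <- .as_keys(outside_profiles)
  n <- length(kin); m <- length(kout)
  denom <- n * (n - 1) / 2 + n * m
  if (denom == 0) return(NA_real_)
  counts_in <- table(kin)
  within <- sum(counts_in * (counts_in - 1) / 2)
  cross <- if (m) sum(counts_in * table(factor(kout, levels = names(counts_in))))
           else 0
  (within + cross) / denom
}

#' Enrichment score E
#'
#' @param f_pw within-pathway identical fraction.
#' @param f_all overall identical fraction.
#' @return `f_pw / f_all`; `NA` (undefined) when `f_all` is 0 or either
#'   input is `NA`.
#' @export
enrichment_score <- function(f_pw, f_all) {
  ifelse(is.na(f_pw) | is.na(f_all) | f_all == 0, NA_real_, f_pw / f_all)
}

# Integer-coded engine shared by the observed statistic and the permutations.
# codes: integer profile code per object in the pool; idx: member indices.
.enrich_counts <- function(codes, n_codes, idx, pool_counts) {
  k <- tabulate(codes[idx], nbins = n_codes)
  n <- length(idx)
  within <- sum(k * (k - 1)) / 2
  cross <- sum(k * (pool_counts - k))
  c(within = within, cross = cross,
    denom_pw = n * (n - 1) / 2,
    denom_all = n * (n - 1) / 2 + n * (length(codes) - n))
}

#' Empirical permutation p-value for an enrichment score
#'
#' Each draw samples `n_f` objects uniformly without replacement from the
#' full pool of gene objects (profile multiplicities preserved), recomputes
#' F_pw, F_all and E against the complementary outside set, and the p-value
#' is the fraction of draws with `E_r >= observed_E`. Draws whose `E_r` is
#' undefined (`F_all = 0`) are counted as non-exceeding; their number is
#' returned. When no draw reaches the observed score the p-value is reported
#' as `1/n_draws` floored (flag `p_floored`), avoiding a literal zero.
#'
#' @param observed_E observed enrichment (`NA` marks an untestable pathway).
#' @param all_object_profiles profile matrix or key vector for the full pool.
#' @param n_f number of member objects to redraw.
#' @param n_draws number of random draws (default 10000).
#' @param seed integer seed; the draw sequence is deterministic given it.
#' @return list: `p_empirical`, `p_floored` (logical), `mean_E_r` (mean over
#'   defined draws), `n_undefined`, `n_draws`.
#' @export
permutation_pvalue <- function(observed_E, all_object_profiles, n_f,
                               n_draws = 10000, seed = 1L) {
  keys <- .as_keys(all_object_profiles)
  n_all <- length(keys)
  if (n_f > n_all) stop("n_f exceeds the object pool size")
  if (n_draws < 1L) stop("n_draws must be >= 1")
  if (is.na(observed_E)) {
    return(list(p_empirical = NA_real_, p_floored = FALSE,
                mean_E_r = NA_real_, n_undefined = NA_integer_,
                n_draws = n_draws))
  }
  uk <- unique(keys)
  codes <- match(keys, uk)
  pool_counts <- tabulate(codes, nbins = length(uk))
  e_r <- numeric(n_draws)
  undef <- logical(n_draws)
  old <- .save_rng(seed)
  on.exit(.restore_rng(old))
  for (d in seq_len(n_draws)) {
    idx <- sample.int(n_all, n_f)
    ct <- .enrich_counts(codes, length(uk), idx, pool_counts)
    f_pw <- if (ct[["denom_pw"]] > 0) ct[["within"]] / ct[["denom_pw"]] else NA_real_
    f_all <- (ct[["within"]] + ct[["cross"]]) / ct[["denom_all"]]
    if (is.na(f_pw) || f_all == 0) {
      undef[d] <- TRUE
      e_r[d] <- -Inf  # counted as non-exceeding
    } else {
      e_r[d] <- f_pw / f_all
    }
  }
  k <- sum(e_r >= observed_E)
  p <- k / n_draws
  floored <- FALSE
  if (k == 0L) { p <- 1 / n_draws; floored <- TRUE }
  list(p_empirical = p, p_floored = floored,
       mean_E_r = if (all(undef)) NA_real_ else mean(e_r[!undef]),
       n_undefined = sum(undef), n_draws = n_draws)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction: sort p ascending, multiply by
#' m/i, enforce monotonicity from the largest down, cap at 1, restore the
#' original order. `NA` entries (untestable pathways) are passed through and
#' do not count toward m.
#'
#' @param p_values numeric vector in \[0,1\] (NAs allowed).
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0,1]")
  out <- rep(NA_real_, length(p_values))
  ok <- !is.na(p_values)
  p <- p_values[ok]
  m <- length(p)
  if (m) {
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
    out[ok] <- adj
  }
  out
}

# RNG bookkeeping: localise randomness so library calls stay reproducible.
.save_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Derive a stable child seed from a root seed and a string id
#'
#' Pathway-level reproducibility: the permutation stream of each pathway
#' depends only on the root seed and the pathway id, never on scan order.
#' Uses a small polynomial rolling hash over the id bytes, folded into
#' \[0, 2^31).
#'
#' @param root_seed integer root seed.
#' @param id character id.
#' @return integer seed.
#' @export
derive_seed <- function(root_seed, id) {
  h <- 0
  for (v in utf8ToInt(id)) h <- (h * 131 + v) %% 2147480009
  as.integer((h + as.numeric(root_seed) %% 2147480009) %% 2147480009)
}

#' Scan all pathways at one level for identical-profile enrichment
#'
#' Computes F_pw, F_all, E and the empirical permutation p-value for every
#' pathway, then applies Benjamini-Hochberg correction across all testable
#' pathways at that level. Pathways with fewer than `min_objects` members are
#' reported but flagged untestable (NA statistics) and excluded from the BH
#' family by default.
#'
#' @param memberships named list pathway id -> member object ids (see
#'   [pathway_memberships()]).
#' @param profiles 0/1 profile matrix over the object pool used for testing.
#' @param n_draws permutation draws per pathway (default 10000).
#' @param seed root seed; per-pathway seeds derive from it via
#'   [derive_seed()].
#' @param min_objects minimum member count for testing (default 2).
#' @return data.frame of class `enrichment_scan`: `pathway`, `n_f`, `f_pw`,
#'   `f_all`, `enrichment`, `mean_E_r`, `p_empirical`, `p_floored`,
#'   `p_adjusted`, `testable`, `n_draws`; sorted by adjusted p then by
#'   descending E.
#' @export
enrichment_scan <- function(memberships, profiles, n_draws = 10000,
                            seed = 1L, min_objects = 2L) {
  keys <- profile_keys(profiles)
  pool_ids <- rownames(profiles)
  ids <- names(memberships)
  res <- data.frame(pathway = ids, n_f = 0L, f_pw = NA_real_,
                    f_all = NA_real_, enrichment = NA_real_,
                    mean_E_r = NA_real_, p_empirical = NA_real_,
                    p_floored = FALSE, p_adjusted = NA_real_,
                    testable = FALSE, n_draws = as.integer(n_draws),
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    mem <- intersect(memberships[[i]], pool_ids)
    res$n_f[i] <- length(mem)
    if (length(mem) < min_objects) next
    kin <- keys[mem]
    kout <- keys[setdiff(pool_ids, mem)]
    f_pw <- fraction_identical_within(kin)
    f_all <- fraction_identical_overall(kin, kout)
    e <- enrichment_score(f_pw, f_all)
    res$f_pw[i] <- f_pw; res$f_all[i] <- f_all; res$enrichment[i] <- e
    if (is.na(e)) next
    perm <- permutation_pvalue(e, keys, length(mem), n_draws = n_draws,
                               seed = derive_seed(seed, ids[i]))
    res$mean_E_r[i] <- perm$mean_E_r
    res$p_empirical[i] <- perm$p_empirical
    res$p_floored[i] <- perm$p_floored
    res$testable[i] <- TRUE
  }
  res$p_adjusted <- bh_adjust(ifelse(res$testable, res$p_empirical, NA_real_))
  ord <- order(res$p_adjusted, -ifelse(is.na(res$enrichment), -Inf,
                                       res$enrichment), res$pathway)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_scan", "data.frame")
  res
}
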