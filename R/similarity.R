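# Pairwise profile similarity and pathway agreement.
#
# d_PP between two binary profiles is the Jaccard index of their presence
# bits: |p1 AND p2| / |p1 OR p2|. A_PW between two pathway sets is the
# overlap coefficient |PW1 n PW2| / min(N1, N2); a true Jaccard variant is
# available as a configuration switch. The relationship between the two is
# summarised by a logistic fit A_PW = 1 / (1 + exp(-a * (d_PP - b))).

#' Jaccard similarity of two phylogenetic profiles
#'
#' @param pp1,pp2 0/1 vectors of equal length (at least one bit set in their
#'   union).
#' @return d_PP in \[0,1\]; 1 iff the profiles are identical.
#' @export
profile_similarity <- function(pp1, pp2) {
  if (length(pp1) != length(pp2)) stop("profile length mismatch")
  u <- sum(pp1 | pp2)
  if (u == 0) stop("both profiles are all-zero")
  sum(pp1 & pp2) / u
}

#' Pathway agreement of two pathway sets
#'
#' The printed-form agreement uses the overlap coefficient (intersection over
#' the smaller list), which equals 1 whenever one set contains the other.
#'
#' @param pw1,pw2 character vectors of pathway ids.
#' @param method `"overlap"` (default, intersection / min) or `"jaccard"`
#'   (intersection / union).
#' @return A_PW in \[0,1\]; `NA` (undefined) when either set is empty — such
#'   pairs are excluded from downstream fits.
#' @export
pathway_agreement <- function(pw1, pw2, method = c("overlap", "jaccard")) {
  method <- match.arg(method)
  pw1 <- unique(pw1); pw2 <- unique(pw2)
  if (length(pw1) == 0L || length(pw2) == 0L) return(NA_real_)
  inter <- length(intersect(pw1, pw2))
  denom <- if (method == "overlap") min(length(pw1), length(pw2))
           else length(union(pw1, pw2))
  inter / denom
}

#' Sample random gene-object pairs with d_PP and A_PW
#'
#' Draws `n_pairs` independent unordered pairs of distinct objects, uniformly
#' with replacement across draws (repeats of a pair are allowed, as with a
#' large pool collisions are immaterial). Sampling is over objects, not
#' genes, so large families carry no extra weight. Objects without pathway
#' annotation are excluded before sampling.
#'
#' @param profiles 0/1 profile matrix (rownames = object ids).
#' @param pathways named list object id -> character vector of pathway ids.
#' @param n_pairs number of draws (default 100000).
#' @param seed integer seed.
#' @param method agreement variant, see [pathway_agreement()].
#' @return data.frame `g1`, `g2`, `d_pp`, `a_pw`, `n1`, `n2`.
#' @export
sample_pairs <- function(profiles, pathways, n_pairs = 100000, seed = 1L,
                         method = c("overlap", "jaccard")) {
  method <- match.arg(method)
  eligible <- intersect(rownames(profiles),
                        names(pathways)[lengths(pathways) > 0L])
  n <- length(eligible)
  if (n < 2L) stop("need at least 2 objects with pathway annotation")
  old <- .save_rng(seed)
  on.exit(.restore_rng(old))
  i <- sample.int(n, n_pairs, replace = TRUE)
  j <- sample.int(n, n_pairs, replace = TRUE)
  while (any(eq <- i == j)) j[eq] <- sample.int(n, sum(eq), replace = TRUE)
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  g1 <- eligible[i]; g2 <- eligible[j]
  # similarity via vectorised bit counts
  p <- profiles[eligible, , drop = FALSE] > 0
  A <- p[i, , drop = FALSE]; B <- p[j, , drop = FALSE]
  d_pp <- rowSums(A & B) / rowSums(A | B)
  pw <- pathways[eligible]
  a_pw <- vapply(seq_len(n_pairs), function(k)
    pathway_agreement(pw[[i[k]]], pw[[j[k]]], method = method), 0)
  data.frame(g1 = g1, g2 = g2, d_pp = d_pp, a_pw = a_pw,
             n1 = lengths(pw)[i], n2 = lengths(pw)[j],
             stringsAsFactors = FALSE)
}

#' Fit the logistic pathway-agreement curve
#'
#' Least-squares fit of `y = 1 / (1 + exp(-a * (x - b)))` via `nls` with a
#' multi-start grid over slope and midpoint (a single start is fragile for
#' flat relationships); the start with the smallest residual sum of squares
#' wins. Degenerate inputs (constant x or constant y) are flagged
#' non-converged with parameters withheld.
#'
#' @param x predictor (e.g. d_PP).
#' @param y response in \[0,1\] (e.g. A_PW); NAs dropped pairwise.
#' @param boot_se number of bootstrap resamples for a standard error of the
#'   slope (0 = skip).
#' @param seed seed for the bootstrap.
#' @return list of class `logistic_fit`: `a`, `b`, `converged`, `flat`
#'   (`TRUE` when the best fit is an unidentifiable near-constant curve),
#'   `rss`, `n`, and optionally `a_se`.
#' @export
fit_logistic <- function(x, y, boot_se = 0L, seed = 1L) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  out <- list(a = NA_real_, b = NA_real_, converged = FALSE,
              flat = FALSE, rss = NA_real_, n = length(x))
  class(out) <- "logistic_fit"
  if (length(x) < 10L) return(out)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(out)
  starts <- expand.grid(a = c(-20, -5, -1, 1, 5, 20),
                        b = c(0.25, 0.5, 0.75))
  rss_fun <- function(par) {
    mu <- 1 / (1 + exp(-par[1] * (x - par[2])))
    sum((y - mu)^2)
  }
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(c(starts$a[s], starts$b[s]), rss_fun,
                   method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit) || fit$convergence != 0L) next
    if (is.null(best) || fit$value < best$rss)
      best <- list(a = fit$par[1], b = fit$par[2], rss = fit$value)
  }
  if (is.null(best)) return(out)
  # flat-fit guard: on trendless data the parameters sit on the a*b ridge
  # (any near-constant curve fits equally well) and are unidentifiable —
  # flag non-informative and withhold them
  mu <- 1 / (1 + exp(-best$a * (x - best$b)))
  if (diff(range(mu)) < 0.01) {
    out$flat <- TRUE
    return(out)
  }
  out$a <- best$a; out$b <- best$b; out$rss <- best$rss; out$converged <- TRUE
  if (boot_se > 0L) {
    old <- .save_rng(seed)
    on.exit(.restore_rng(old))
    slopes <- rep(NA_real_, boot_se)
    for (r in seq_len(boot_se)) {
      idx <- sample.int(length(x), replace = TRUE)
      f <- fit_logistic(x[idx], y[idx])
      if (f$converged) slopes[r] <- f$a
    }
    out$a_se <- stats::sd(slopes, na.rm = TRUE)
  }
  out
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("<logistic_fit> a = %.4g, b = %.4g (rss = %.4g, n = %d)\n",
                x$a, x$b, x$rss, x$n))
  else cat("<logistic_fit> not converged / degenerate (n =", x$n, ")\n")
  invisible(x)
}
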