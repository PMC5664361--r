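# Hierarchical multi-label pathway prediction from binary profiles.
#
# A self-contained bagged ensemble of multi-label decision trees over the
# 0/1 profile features. Each tree is grown on a bootstrap sample; splits are
# on single presence bits, chosen to maximise the mean per-label Gini
# reduction; leaves predict per-label frequencies. Per-object scores are
# averaged over the trees whose bootstrap excluded the object (out-of-bag),
# and the two-level hierarchy (class -> map) is enforced afterwards by a
# max-normalisation pass that lifts each class score to at least the best of
# its child map scores. Performance is judged per label by the area under
# the precision-recall curve, the appropriate summary for heavily imbalanced
# multi-label data.

#' Build a label hierarchy
#'
#' @param map_ids character vector of map (leaf) labels.
#' @param class_ids parent class of each map.
#' @return list of class `label_hierarchy`: `maps`, `classes`,
#'   `map_to_class` (named character).
#' @export
label_hierarchy <- function(map_ids, class_ids) {
  stopifnot(length(map_ids) == length(class_ids))
  if (anyDuplicated(map_ids)) stop("each map must have exactly one class")
  m2c <- stats::setNames(as.character(class_ids), as.character(map_ids))
  structure(list(maps = as.character(map_ids),
                 classes = sort(unique(as.character(class_ids))),
                 map_to_class = m2c),
            class = "label_hierarchy")
}

# ---- tree induction -------------------------------------------------------

# Y: logical matrix (objects x labels). Returns mean per-label Gini.
.gini <- function(Y) {
  if (nrow(Y) == 0L) return(0)
  p <- colMeans(Y)
  mean(p * (1 - p))
}

# Recursive growth; X logical matrix, Y logical matrix, idx rows in node.
# The split search is vectorised over all features at once: one crossprod
# yields per-feature, per-label positive counts on the bit=1 side, from
# which both children's mean Gini follows in closed form.
.grow_tree <- function(X, Y, idx, min_node = 2L) {
  n <- length(idx)
  Yn <- Y[idx, , drop = FALSE]
  pred <- colMeans(Yn)
  leaf <- list(leaf = TRUE, pred = pred)
  if (n < min_node) return(leaf)
  imp <- mean(pred * (1 - pred))
  if (imp <= 0) return(leaf)
  Xn <- X[idx, , drop = FALSE]
  nR <- colSums(Xn)
  valid <- nR > 0L & nR < n
  if (!any(valid)) return(leaf)
  cnt <- crossprod(Xn, Yn)              # features x labels, counts on bit=1
  tot <- colSums(Yn)
  pR <- cnt / nR
  pL <- (matrix(tot, nrow(cnt), ncol(cnt), byrow = TRUE) - cnt) / (n - nR)
  giniR <- rowMeans(pR * (1 - pR))
  giniL <- rowMeans(pL * (1 - pL))
  child <- ((n - nR) * giniL + nR * giniR) / n
  child[!valid] <- Inf
  f <- which.min(child)                  # lowest index wins ties
  if (imp - child[f] <= 1e-12) return(leaf)
  right <- idx[Xn[, f]]
  left <- idx[!Xn[, f]]
  list(leaf = FALSE, feature = f,
       left = .grow_tree(X, Y, left, min_node),
       right = .grow_tree(X, Y, right, min_node))
}

.predict_tree <- function(tree, X, idx, out) {
  if (tree$leaf) {
    out[idx, ] <- matrix(tree$pred, nrow = length(idx), ncol = ncol(out),
                         byrow = TRUE)
    return(out)
  }
  right <- idx[X[idx, tree$feature]]
  left <- idx[!X[idx, tree$feature]]
  if (length(left)) out <- .predict_tree(tree$left, X, left, out)
  if (length(right)) out <- .predict_tree(tree$right, X, right, out)
  out
}

# ---- ensemble -------------------------------------------------------------

#' Label sets to a logical indicator matrix
#' @param labels named list object id -> character vector of labels.
#' @param label_universe columns of the result.
#' @return logical matrix objects x labels.
#' @export
label_matrix <- function(labels, label_universe) {
  Y <- matrix(FALSE, nrow = length(labels), ncol = length(label_universe),
              dimnames = list(names(labels), label_universe))
  for (i in seq_along(labels)) {
    hit <- intersect(labels[[i]], label_universe)
    if (length(hit)) Y[i, hit] <- TRUE
  }
  Y
}

#' Train a bagged multi-label ensemble and score out-of-bag
#'
#' Trains `n_trees` multi-label decision trees on bootstrap samples of the
#' objects and returns, for every object and label, the mean predicted label
#' frequency over the trees in which the object was out-of-bag. Map labels
#' are augmented with their parent classes before training (one joint
#' hierarchy); after scoring, each class score is raised to the maximum of
#' its child map scores so that no map outranks its own class. Objects with
#' an empty label set are excluded from training and flagged; objects that
#' were never out-of-bag have `NA` scores and are flagged.
#'
#' @param profiles 0/1 matrix (objects x species), the features.
#' @param labels named list object id -> character vector of map labels
#'   (class labels are derived via the hierarchy). Ids must match
#'   `rownames(profiles)`.
#' @param hierarchy a [label_hierarchy()].
#' @param n_trees ensemble size (default 50).
#' @param seed integer seed; deterministic given it.
#' @param min_node minimum node size before a split is attempted.
#' @return list of class `prediction_scores`: `scores` (numeric matrix
#'   objects x labels, NA where never out-of-bag), `oob_counts`,
#'   `unlabelled` (excluded object ids), `never_oob` (object ids),
#'   `hierarchy`, `n_trees`.
#' @export
train_predict_oob <- function(profiles, labels, hierarchy, n_trees = 50L,
                              seed = 1L, min_node = 2L) {
  ids <- rownames(profiles)
  stopifnot(!is.null(ids), all(names(labels) %in% ids))
  labels <- labels[ids[ids %in% names(labels)]]
  # augment map labels with parent classes
  aug <- lapply(labels, function(v) {
    maps <- intersect(v, hierarchy$maps)
    extra_classes <- intersect(v, hierarchy$classes)
    unique(c(maps, unname(hierarchy$map_to_class[maps]), extra_classes))
  })
  unlabelled <- names(aug)[lengths(aug) == 0L]
  train_ids <- setdiff(names(aug), unlabelled)
  if (length(train_ids) < 2L) stop("need at least 2 labelled objects")
  universe <- c(hierarchy$classes, hierarchy$maps)
  X <- profiles[train_ids, , drop = FALSE] > 0
  if (nrow(unique(X)) < 2L) stop("need at least 2 distinct profiles")
  Y <- label_matrix(aug[train_ids], universe)
  n <- length(train_ids)
  score_sum <- matrix(0, nrow = n, ncol = length(universe),
                      dimnames = list(train_ids, universe))
  oob_n <- integer(n)
  old <- .save_rng(seed)
  on.exit(.restore_rng(old))
  tmp <- matrix(0, nrow = n, ncol = length(universe))
  for (t in seq_len(n_trees)) {
    bag <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), unique(bag))
    tree <- .grow_tree(X[bag, , drop = FALSE],
                       Y[bag, , drop = FALSE],
                       seq_along(bag), min_node = min_node)
    if (length(oob)) {
      pred <- .predict_tree(tree, X, oob, tmp)
      score_sum[oob, ] <- score_sum[oob, ] + pred[oob, , drop = FALSE]
      oob_n[oob] <- oob_n[oob] + 1L
    }
  }
  scores <- score_sum / ifelse(oob_n > 0L, oob_n, NA_integer_)
  # hierarchy consistency: class >= max of its child maps
  for (cl in hierarchy$classes) {
    kids <- hierarchy$maps[hierarchy$map_to_class == cl]
    if (length(kids))
      scores[, cl] <- pmax(scores[, cl],
                           apply(scores[, kids, drop = FALSE], 1L, max))
  }
  structure(list(scores = scores, oob_counts = oob_n,
                 unlabelled = unlabelled,
                 never_oob = train_ids[oob_n == 0L],
                 hierarchy = hierarchy, n_trees = n_trees),
            class = "prediction_scores")
}

#' Area under the precision-recall curve
#'
#' Curve over descending score thresholds, one point per distinct score
#' value (ties share a threshold); the area is the step-wise sum of
#' precision times the recall increment, with the recall = 0 anchor taken at
#' the first threshold's precision. No linear interpolation between points
#' (trapezoidal PR interpolation is known to be optimistic). A constant
#' score yields a single point and an area equal to the label prevalence.
#'
#' @param scores numeric vector (NAs dropped together with their truth).
#' @param truth logical/0-1 vector of the same length.
#' @return area in \[0,1\]; `NA` when there is no positive.
#' @export
aucprc <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  ok <- !is.na(scores)
  scores <- scores[ok]; truth <- as.logical(truth[ok])
  P <- sum(truth)
  if (P == 0L) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; t <- truth[o]
  last <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie group
  tp <- cumsum(t)[last]
  pred <- last  # number predicted positive at each threshold
  precision <- tp / pred
  recall <- tp / P
  sum(precision * diff(c(0, recall)))
}

#' Per-label AUCPRC of an out-of-bag score set
#'
#' @param pred a `prediction_scores` object.
#' @param labels named list object id -> map labels (truth).
#' @param level `"class"` or `"map"`.
#' @return data.frame `label`, `level`, `n_pos`, `aucprc` (NA for labels
#'   without positives among scored objects).
#' @export
score_labels <- function(pred, labels, level = c("class", "map")) {
  level <- match.arg(level)
  hier <- pred$hierarchy
  targets <- if (level == "class") hier$classes else hier$maps
  ids <- rownames(pred$scores)
  truth_sets <- lapply(labels[ids], function(v) {
    maps <- intersect(v, hier$maps)
    unique(c(maps, unname(hier$map_to_class[maps]),
             intersect(v, hier$classes)))
  })
  Y <- label_matrix(truth_sets, targets)
  out <- data.frame(label = targets, level = level,
                    n_pos = colSums(Y), aucprc = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(targets)) {
    out$aucprc[k] <- aucprc(pred$scores[, targets[k]], Y[, k])
  }
  rownames(out) <- NULL
  out
}

#' Occurrence-preserving label shuffle
#'
#' Redistributes the label tokens of one level uniformly at random over the
#' objects such that (i) each label's total occurrence count is preserved
#' exactly and (ii) no object receives the same label twice (each label's
#' tokens go to distinct objects, sampled without replacement).
#'
#' @param labels named list object id -> character vector of labels at one
#'   level.
#' @param seed integer seed.
#' @return named list of the same shape (objects may end up with empty
#'   label sets).
#' @export
shuffle_labels <- function(labels, seed = 1L) {
  ids <- names(labels)
  n <- length(ids)
  counts <- table(unlist(labels, use.names = FALSE))
  if (any(counts > n))
    stop("infeasible shuffle: label occurs more often than there are objects")
  old <- .save_rng(seed)
  on.exit(.restore_rng(old))
  out <- stats::setNames(vector("list", n), ids)
  for (lab in sort(names(counts))) {
    hit <- sample.int(n, counts[[lab]])
    for (i in hit) out[[i]] <- c(out[[i]], lab)
  }
  lapply(out, function(v) if (is.null(v)) character() else v)
}

#' Compare true predictions with occurrence-preserving label shuffles
#'
#' Trains and scores once on the true labels, then `n_shuffles` times on
#' shuffled labels of the chosen level, and compares the per-label AUCPRC of
#' the true run with the per-label AUCPRC averaged over shuffle runs by a
#' two-sided Wilcoxon rank-sum test.
#'
#' For `level = "map"` the map tokens are shuffled and classes re-derived
#' through the hierarchy; for `level = "class"` the class tokens themselves
#' are shuffled and used directly as class labels (maps play no role).
#'
#' @param profiles 0/1 feature matrix.
#' @param labels named list object id -> map labels.
#' @param hierarchy a [label_hierarchy()].
#' @param level `"class"` or `"map"`.
#' @param n_shuffles shuffle repetitions (conventionally 100 for classes,
#'   20 for maps).
#' @param n_trees trees per run (default 50).
#' @param seed root seed.
#' @return list: `mean_true`, `mean_random`, `wilcoxon_p`, `true` (per-label
#'   data.frame), `random_mean_by_label`, `n_shuffles`.
#' @export
compare_true_vs_random <- function(profiles, labels, hierarchy,
                                   level = c("class", "map"),
                                   n_shuffles = 20L, n_trees = 50L,
                                   seed = 1L) {
  level <- match.arg(level)
  true_pred <- train_predict_oob(profiles, labels, hierarchy,
                                 n_trees = n_trees,
                                 seed = derive_seed(seed, "true"))
  true_scores <- score_labels(true_pred, labels, level = level)
  targets <- true_scores$label
  if (level == "class") {
    class_labels <- lapply(labels, function(v)
      unique(c(unname(hierarchy$map_to_class[intersect(v, hierarchy$maps)]),
               intersect(v, hierarchy$classes))))
    names(class_labels) <- names(labels)
  }
  rand_mat <- matrix(NA_real_, nrow = length(targets), ncol = n_shuffles,
                     dimnames = list(targets, NULL))
  for (r in seq_len(n_shuffles)) {
    sseed <- derive_seed(seed, paste0("shuffle", r))
    if (level == "map") {
      shuf <- shuffle_labels(labels, seed = sseed)
    } else {
      shuf <- shuffle_labels(class_labels, seed = sseed)
    }
    pred <- train_predict_oob(profiles, shuf, hierarchy, n_trees = n_trees,
                              seed = derive_seed(sseed, "trees"))
    sc <- score_labels(pred, shuf, level = level)
    rand_mat[match(sc$label, targets), r] <- sc$aucprc
  }
  rand_mean <- rowMeans(rand_mat, na.rm = TRUE)
  x <- true_scores$aucprc
  ok <- !is.na(x) & !is.nan(rand_mean)
  w_p <- if (sum(ok) >= 2L)
    suppressWarnings(stats::wilcox.test(x[ok], rand_mean[ok])$p.value)
  else NA_real_
  list(mean_true = mean(x, na.rm = TRUE),
       mean_random = mean(rand_mat, na.rm = TRUE),
       wilcoxon_p = w_p,
       true = true_scores,
       random_mean_by_label = rand_mean,
       n_shuffles = n_shuffles)
}
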