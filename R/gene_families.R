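# Gene family construction and evaluation.
#
# Genes are clustered into "gene objects" — multi-member gene families or
# singletons — as connected components of a homology network in which an edge
# is retained iff it is reported in the homology table AND passes the percent
# identity threshold (and, optionally, a high-confidence filter). Orthologous
# and paralogous relations are treated identically.

#' Cluster genes into gene objects
#'
#' Builds the identity-thresholded homology network and returns its connected
#' components as a gene partition. Two genes share an object iff they are
#' connected by a path of retained edges; the threshold comparison is
#' inclusive (`pct_identity >= min_identity`). Every annotated gene absent
#' from the retained network becomes a singleton object.
#'
#' @param edges homology data.frame from [read_homology_table()].
#' @param genes annotation data.frame from [read_annotation_table()], defines
#'   the gene universe.
#' @param min_identity retained edges need at least this percent identity
#'   (default 30; 70 gives the finer clustering).
#' @param require_high_confidence drop low-confidence edges (default `TRUE`).
#' @param confidence_scope `"all"` applies the confidence filter to every
#'   edge; `"orthologs"` applies it to ortholog edges only and keeps all
#'   paralog edges, mirroring annotation sources that only grade orthology
#'   calls.
#' @return data.frame of class `gene_partition` with columns `gene_id`,
#'   `object_id`, `singleton` (logical). Object ids are `GO000001`-style,
#'   assigned in order of each object's lexicographically smallest member so
#'   the labelling is deterministic and independent of edge order.
#' @export
build_families <- function(edges, genes, min_identity = 30,
                           require_high_confidence = TRUE,
                           confidence_scope = c("all", "orthologs")) {
  confidence_scope <- match.arg(confidence_scope)
  stopifnot(min_identity >= 0, min_identity <= 100)
  universe <- genes$gene_id
  unknown <- setdiff(unique(c(edges$gene_a, edges$gene_b)), universe)
  if (length(unknown))
    stop("homology edges reference unknown gene(s): ",
         paste(sort(unknown), collapse = ", "))
  keep <- edges$pct_identity >= min_identity
  if (require_high_confidence) {
    conf_ok <- edges$confidence == "high"
    if (confidence_scope == "orthologs")
      conf_ok <- conf_ok | edges$relation == "paralog"
    keep <- keep & conf_ok
  }
  e <- edges[keep, c("gene_a", "gene_b"), drop = FALSE]
  g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                     vertices = data.frame(name = universe))
  comp <- igraph::components(g)$membership
  comp <- comp[universe]  # vertex order == universe order
  # relabel deterministically by smallest member id
  rep_gene <- tapply(universe, comp, function(v) min(v))
  rank <- match(rep_gene[as.character(comp)], sort(unname(rep_gene)))
  object_id <- sprintf("GO%06d", rank)
  sizes <- table(object_id)
  partition <- data.frame(gene_id = universe, object_id = object_id,
                          singleton = as.vector(sizes[object_id]) == 1L,
                          stringsAsFactors = FALSE)
  class(partition) <- c("gene_partition", "data.frame")
  partition
}

#' Summarise gene objects
#'
#' @param partition a `gene_partition` from [build_families()].
#' @param genes annotation data.frame (for species membership).
#' @return data.frame with one row per object: `object_id`, `n_genes`,
#'   `singleton`, and list-column `species` (union of member species).
#' @export
gene_objects <- function(partition, genes) {
  sp <- genes$species[match(partition$gene_id, genes$gene_id)]
  obj_ids <- sort(unique(partition$object_id))
  idx <- split(seq_len(nrow(partition)), partition$object_id)
  data.frame(object_id = obj_ids,
             n_genes = lengths(idx)[obj_ids],
             singleton = lengths(idx)[obj_ids] == 1L,
             species = I(lapply(idx[obj_ids], function(i) sort(unique(sp[i])))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Canonical function label of a gene
#'
#' Genes are considered functionally identical iff they carry the same *set*
#' of EC numbers; the canonical label is the sorted, ";"-joined EC set, with
#' the distinct label `"none"` for enzymes without any EC annotation.
#'
#' @param ec_numbers a character vector (one gene's EC set) or a list of such
#'   vectors.
#' @return character vector of labels.
#' @export
function_label <- function(ec_numbers) {
  if (!is.list(ec_numbers)) ec_numbers <- list(ec_numbers)
  vapply(ec_numbers, function(v) {
    v <- unique(as.character(v))
    if (length(v) == 0L) "none" else paste(sort(v), collapse = ";")
  }, "")
}

#' Adjusted Rand index between two labelings
#'
#' Hubert-Arabie chance-corrected Rand index computed from the contingency
#' table of the two labelings of the same element universe: 1 for identical
#' partitions, about 0 in expectation for independent ones, negative for
#' less-than-chance agreement.
#'
#' @param labels_a,labels_b vectors of equal length assigning each element to
#'   a cluster/label. If both are named, names must describe the same
#'   universe and are used for alignment.
#' @return a single numeric value.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    if (!setequal(names(labels_a), names(labels_b)))
      stop("labelings are defined over different universes")
    labels_b <- labels_b[names(labels_a)]
  }
  if (length(labels_a) != length(labels_b))
    stop("labelings are defined over different universes")
  n <- length(labels_a)
  if (n < 2L) stop("need at least 2 elements")
  tab <- table(as.character(labels_a), as.character(labels_b))
  sum_ij <- sum(choose(tab, 2))
  a_i <- rowSums(tab); b_j <- colSums(tab)
  sum_a <- sum(choose(a_i, 2)); sum_b <- sum(choose(b_j, 2))
  n2 <- choose(n, 2)
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions all-singletons or all-one
  (sum_ij - expected) / (max_index - expected)
}

#' Evaluate a gene partition against EC-based function labels
#'
#' Compares the family clustering to the clustering implied by identical EC
#' sets via the adjusted Rand index. Genes without any EC number share the
#' `"none"` label; set `include_unlabelled = FALSE` to restrict the comparison
#' to EC-annotated genes.
#'
#' @param partition a `gene_partition`.
#' @param genes annotation data.frame.
#' @param include_unlabelled keep EC-less genes under a common `"none"` label
#'   (default `TRUE`).
#' @return the adjusted Rand index.
#' @export
evaluate_partition <- function(partition, genes, include_unlabelled = TRUE) {
  lab <- function_label(genes$ec_numbers)
  names(lab) <- genes$gene_id
  fam <- partition$object_id
  names(fam) <- partition$gene_id
  if (!include_unlabelled) {
    keep <- names(lab)[lab != "none"]
    lab <- lab[keep]; fam <- fam[keep]
  } else {
    fam <- fam[names(lab)]
  }
  adjusted_rand_index(fam, lab)
}
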