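# Shared data model and tabular readers/writers.
#
# All interchange files are TSV with a header row; multi-valued cells use ";"
# as the in-cell separator. Identifiers are case-sensitive throughout.

LIST_SEP <- ";"

#' Construct a species set
#'
#' The ordered species set fixes the coordinate system of every phylogenetic
#' profile in an analysis: position i of a profile refers to `species_ids[i]`
#' for the lifetime of the analysis. A per-species flag records whether the
#' species carries pathway (KEGG-style) annotation; enrichment analyses are
#' typically restricted to objects touching at least one annotated species.
#'
#' @param species_ids character vector of unique short species codes
#'   (e.g. `"ATH"`). Order is meaningful and preserved.
#' @param kegg_flag logical vector, same length: is the species covered by the
#'   pathway annotation source? Defaults to all `TRUE`.
#' @return An object of class `species_set`: a list with elements
#'   `species_ids` and `kegg_flag`.
#' @export
species_set <- function(species_ids, kegg_flag = rep(TRUE, length(species_ids))) {
  species_ids <- as.character(species_ids)
  if (anyDuplicated(species_ids))
    stop("species ids must be unique: ",
         paste(unique(species_ids[duplicated(species_ids)]), collapse = ", "))
  if (length(species_ids) < 2L)
    stop("a species set needs at least 2 species")
  if (length(kegg_flag) != length(species_ids))
    stop("kegg_flag must align with species_ids")
  structure(list(species_ids = species_ids, kegg_flag = as.logical(kegg_flag)),
            class = "species_set")
}

#' @export
print.species_set <- function(x, ...) {
  cat("<species_set> ", length(x$species_ids), " species (",
      sum(x$kegg_flag), " pathway-annotated)\n", sep = "")
  invisible(x)
}

#' @export
length.species_set <- function(x) length(x$species_ids)

.read_tsv <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          check.names = FALSE, quote = "",
                          stringsAsFactors = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    stop("format error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  df
}

.split_cell <- function(x) {
  out <- strsplit(x, LIST_SEP, fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

.join_cell <- function(lst) vapply(lst, function(v) paste(v, collapse = LIST_SEP), "")

#' Read a species table
#'
#' Columns: `species_id`, `kegg_flag` (0/1 or TRUE/FALSE). Row order defines
#' profile coordinate order.
#'
#' @param path path to a TSV file.
#' @return A [species_set()].
#' @export
read_species_table <- function(path) {
  df <- .read_tsv(path, c("species_id", "kegg_flag"))
  flag <- df$kegg_flag %in% c("1", "TRUE", "true", "T")
  species_set(df$species_id, flag)
}

#' Write a species table
#' @param species a [species_set()].
#' @param path output path.
#' @export
write_species_table <- function(species, path) {
  df <- data.frame(species_id = species$species_ids,
                   kegg_flag = as.integer(species$kegg_flag))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pairwise homology table
#'
#' Expects columns `gene_a`, `gene_b`, `pct_identity` (percent identity
#' relative to the shorter of the two sequences, in \[0,100\]), `confidence`
#' (`high`/`low`) and `relation` (`ortholog`/`paralog`). Edges are undirected:
#' each pair is stored once under canonical (lexicographic) endpoint order.
#' Duplicate pairs are collapsed keeping the maximum identity, and `high`
#' confidence wins over `low` when duplicates disagree — a deterministic rule
#' that is conservative toward family merging.
#'
#' @param path path to a TSV file.
#' @return data.frame with columns `gene_a`, `gene_b`, `pct_identity`
#'   (numeric), `confidence`, `relation`; one row per undirected pair.
#' @export
read_homology_table <- function(path) {
  df <- .read_tsv(path, c("gene_a", "gene_b", "pct_identity", "confidence",
                          "relation"))
  validate_homology_edges(df, source = path)
}

#' Validate and canonicalise homology edges
#'
#' Same contract as [read_homology_table()] but starting from an in-memory
#' data.frame; used by the readers and by the synthetic-data generator.
#'
#' @param df data.frame with the homology columns.
#' @param source label used in error messages.
#' @return canonicalised, deduplicated data.frame.
#' @export
validate_homology_edges <- function(df, source = "homology table") {
  pct <- suppressWarnings(as.numeric(df$pct_identity))
  bad <- which(is.na(pct) | pct < 0 | pct > 100)
  if (length(bad))
    stop("validation error in ", source, ": pct_identity outside [0,100] at ",
         "line(s) ", paste(bad + 1L, collapse = ", "),
         " (values: ", paste(df$pct_identity[bad], collapse = ", "), ")")
  a <- as.character(df$gene_a); b <- as.character(df$gene_b)
  self <- which(a == b)
  if (length(self))
    stop("validation error in ", source, ": self edge at line(s) ",
         paste(self + 1L, collapse = ", "))
  conf <- as.character(df$confidence)
  badc <- which(!conf %in% c("high", "low"))
  if (length(badc))
    stop("validation error in ", source, ": confidence must be high/low at ",
         "line(s) ", paste(badc + 1L, collapse = ", "))
  rel <- as.character(df$relation)
  badr <- which(!rel %in% c("ortholog", "paralog"))
  if (length(badr))
    stop("validation error in ", source, ": relation must be ortholog/paralog",
         " at line(s) ", paste(badr + 1L, collapse = ", "))
  swap <- a > b
  ga <- ifelse(swap, b, a); gb <- ifelse(swap, a, b)
  out <- data.frame(gene_a = ga, gene_b = gb, pct_identity = pct,
                    confidence = conf, relation = rel,
                    stringsAsFactors = FALSE)
  # dedup: max identity; tie/merge rule high > low on confidence
  key <- paste(out$gene_a, out$gene_b, sep = "\r")
  ord <- order(key, -out$pct_identity, out$confidence)  # "high" < "low"
  out <- out[ord, , drop = FALSE]
  first <- !duplicated(key[ord])
  conf_best <- tapply(out$confidence, key[ord], function(v)
    if (any(v == "high")) "high" else "low")
  res <- out[first, , drop = FALSE]
  res$confidence <- as.character(conf_best[key[ord][first]])
  rownames(res) <- NULL
  res[order(res$gene_a, res$gene_b), , drop = FALSE]
}

#' Read a gene annotation table
#'
#' Expects columns `gene_id`, `species`, `ec`, `maps`, `classes`; the last
#' three are ";"-separated lists (possibly empty). Validates that gene ids are
#' unique, that species codes resolve against `species`, and — when the
#' map-to-class hierarchy is inferable — that each pathway map belongs to
#' exactly one pathway class.
#'
#' The hierarchy is inferred from rows whose `classes` cell holds a single
#' class (all maps of the row belong to it). Rows with several classes are
#' skipped for inference (their pairing is ambiguous); pass `hierarchy` to
#' validate against an explicit map/class table instead.
#'
#' @param path path to a TSV file.
#' @param species a [species_set()] to resolve species codes against.
#' @param hierarchy optional data.frame (`map_id`, `class_id`) used instead of
#'   inference.
#' @return data.frame with columns `gene_id`, `species` and list-columns
#'   `ec_numbers`, `pathway_maps`, `pathway_classes`; the map-to-class table is
#'   attached as attribute `"hierarchy"`.
#' @export
read_annotation_table <- function(path, species = NULL, hierarchy = NULL) {
  df <- .read_tsv(path, c("gene_id", "species", "ec", "maps", "classes"))
  genes <- data.frame(gene_id = df$gene_id, species = df$species,
                      stringsAsFactors = FALSE)
  if (anyDuplicated(genes$gene_id))
    stop("annotation error in ", path, ": duplicated gene_id(s): ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  if (!is.null(species)) {
    unknown <- setdiff(unique(genes$species), species$species_ids)
    if (length(unknown))
      stop("annotation error in ", path, ": unknown species code(s): ",
           paste(unknown, collapse = ", "))
  }
  genes$ec_numbers <- .split_cell(df$ec)
  genes$pathway_maps <- .split_cell(df$maps)
  genes$pathway_classes <- .split_cell(df$classes)
  attr(genes, "hierarchy") <- .resolve_hierarchy(genes, hierarchy, path)
  genes
}

.resolve_hierarchy <- function(genes, hierarchy, source) {
  if (!is.null(hierarchy)) {
    hierarchy <- data.frame(map_id = as.character(hierarchy$map_id),
                            class_id = as.character(hierarchy$class_id),
                            stringsAsFactors = FALSE)
    .check_hierarchy(hierarchy, source)
    return(hierarchy)
  }
  maps <- character(); classes <- character()
  for (i in seq_len(nrow(genes))) {
    cl <- genes$pathway_classes[[i]]
    mp <- genes$pathway_maps[[i]]
    if (length(cl) == 1L && length(mp) > 0L) {
      maps <- c(maps, mp); classes <- c(classes, rep(cl, length(mp)))
    }
  }
  h <- unique(data.frame(map_id = maps, class_id = classes,
                         stringsAsFactors = FALSE))
  .check_hierarchy(h, source)
  h[order(h$map_id), , drop = FALSE]
}

.check_hierarchy <- function(h, source) {
  dup <- unique(h$map_id[duplicated(h$map_id)])
  if (length(dup))
    stop("hierarchy error in ", source, ": map(s) assigned to two classes: ",
         paste(dup, collapse = ", "))
  invisible(h)
}

#' Read an expression matrix
#'
#' TSV with a `gene_id` column followed by one numeric column per sample.
#' All intensities must be finite; ids must be unique.
#'
#' @param path path to a TSV file.
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df))
    stop("format error in ", path, ": missing column gene_id")
  ids <- as.character(df$gene_id)
  if (anyDuplicated(ids)) stop("duplicate gene ids in ", path)
  m <- as.matrix(df[setdiff(names(df), "gene_id")])
  storage.mode(m) <- "double"
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in ", path)
  if (any(!is.finite(m))) stop("non-finite expression values in ", path)
  rownames(m) <- ids
  m
}

#' Write an expression matrix
#' @param m numeric matrix (genes x samples).
#' @param path output path.
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein-protein interaction table
#'
#' Columns: `gene_a`, `gene_b`, `evidence` (`experimental`/`predicted`).
#' Pairs are undirected; duplicates after canonical ordering are collapsed,
#' keeping `experimental` over `predicted`.
#'
#' @param path path to a TSV file.
#' @param experimental_only drop `predicted` pairs (default `TRUE`, the usual
#'   screening choice).
#' @return data.frame `gene_a`, `gene_b`, `evidence`.
#' @export
read_ppi_table <- function(path, experimental_only = TRUE) {
  df <- .read_tsv(path, c("gene_a", "gene_b", "evidence"))
  bad <- which(!df$evidence %in% c("experimental", "predicted"))
  if (length(bad))
    stop("validation error in ", path, ": evidence must be experimental/",
         "predicted at line(s) ", paste(bad + 1L, collapse = ", "))
  a <- df$gene_a; b <- df$gene_b
  if (any(a == b)) stop("validation error in ", path, ": self interaction")
  swap <- a > b
  out <- data.frame(gene_a = ifelse(swap, b, a), gene_b = ifelse(swap, a, b),
                    evidence = df$evidence, stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b, out$evidence), , drop = FALSE]
  out <- out[!duplicated(paste(out$gene_a, out$gene_b, sep = "\r")), ,
             drop = FALSE]
  if (experimental_only)
    out <- out[out$evidence == "experimental", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a result table
#'
#' Serialises any flat result data.frame as TSV or JSON. Floating point
#' columns are written with 6 significant digits; rows are sorted by the first
#' column so output is deterministic.
#'
#' @param results a data.frame.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(results))
  out <- results
  if (nrow(out) > 1L) out <- out[order(out[[1L]]), , drop = FALSE]
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  if (format == "tsv") {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read a result table written by [write_results()]
#' @param path file path.
#' @param format `"tsv"` or `"json"`.
#' @return data.frame.
#' @export
read_results <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                      check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}

#' Write an annotation table
#' @param genes annotation data.frame as returned by [read_annotation_table()].
#' @param path output path.
#' @export
write_annotation_table <- function(genes, path) {
  df <- data.frame(gene_id = genes$gene_id, species = genes$species,
                   ec = .join_cell(genes$ec_numbers),
                   maps = .join_cell(genes$pathway_maps),
                   classes = .join_cell(genes$pathway_classes),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
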