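# Two-level pathway hierarchy (class -> map), primary/secondary metabolism
# classification, membership resolution and presence surveys.

#' Default secondary-metabolism class ids
#'
#' Pathway classes whose maps count as secondary metabolism. The two
#' conventional categories are terpenoid/polyketide metabolism and the
#' biosynthesis of other secondary metabolites.
#' @export
SECONDARY_CLASSES <- c("Metabolism of terpenoids and polyketides",
                       "Biosynthesis of other secondary metabolites")

#' Build pathway definitions
#'
#' Resolves the map-to-class hierarchy into a definitions table with a
#' per-map secondary flag, after applying configured exclusions (curation
#' judgements such as non-plant pathways, or unspecific "Overview"-style
#' classes, are supplied as config rather than hard-coded).
#'
#' @param hierarchy data.frame with `map_id`, `class_id` (one row per map).
#' @param secondary_classes class ids considered secondary metabolism.
#' @param exclude_maps map ids to drop.
#' @param exclude_classes class ids to drop (all their maps).
#' @return data.frame `map_id`, `class_id`, `secondary` (logical), sorted by
#'   map id.
#' @export
pathway_definitions <- function(hierarchy,
                                secondary_classes = SECONDARY_CLASSES,
                                exclude_maps = character(),
                                exclude_classes = character()) {
  h <- data.frame(map_id = as.character(hierarchy$map_id),
                  class_id = as.character(hierarchy$class_id),
                  stringsAsFactors = FALSE)
  dup <- unique(h$map_id[duplicated(h$map_id)])
  if (length(dup))
    stop("hierarchy error: map(s) assigned to two classes: ",
         paste(dup, collapse = ", "))
  h <- h[!(h$map_id %in% exclude_maps) & !(h$class_id %in% exclude_classes), ,
         drop = FALSE]
  h$secondary <- h$class_id %in% secondary_classes
  h <- h[order(h$map_id), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Classify a gene as primary or secondary metabolism
#'
#' A gene is `secondary` iff all of its annotated maps are secondary
#' metabolism maps; a single primary map makes it `primary` (genes on both
#' kinds of pathway are treated as primary metabolism genes); a gene without
#' map annotation is `none`.
#'
#' @param pathway_maps character vector of one gene's maps, or a list of such
#'   vectors.
#' @param definitions data.frame from [pathway_definitions()].
#' @return character vector in `{"primary","secondary","none"}`.
#' @export
classify_gene_metabolism <- function(pathway_maps, definitions) {
  if (!is.list(pathway_maps)) pathway_maps <- list(pathway_maps)
  sec <- definitions$secondary
  names(sec) <- definitions$map_id
  vapply(pathway_maps, function(maps) {
    if (length(maps) == 0L) return("none")
    unknown <- setdiff(maps, names(sec))
    if (length(unknown))
      stop("unknown pathway map(s): ", paste(unknown, collapse = ", "))
    if (all(sec[maps])) "secondary" else "primary"
  }, "")
}

#' Pathway presence across species
#'
#' A pathway (map or class) is present in a species iff at least one gene of
#' that species is annotated to it. Also reports per-EC presence vectors
#' grouped by map: an enzymatic activity is present in a species iff a gene
#' of that species carries the same EC number and the map annotation.
#'
#' @param genes annotation data.frame.
#' @param definitions data.frame from [pathway_definitions()].
#' @param species a [species_set()].
#' @param level `"map"` or `"class"`.
#' @return list with `presence` (pathway x species 0/1 matrix),
#'   `species_counts` (row sums) and `ec_presence` (data.frame `map_id`,
#'   `ec`, `n_species`).
#' @export
pathway_presence_matrix <- function(genes, definitions, species,
                                    level = c("map", "class")) {
  level <- match.arg(level)
  ids <- if (level == "map") definitions$map_id else
    sort(unique(definitions$class_id))
  m <- matrix(0L, nrow = length(ids), ncol = length(species$species_ids),
              dimnames = list(ids, species$species_ids))
  n <- nrow(genes)
  map2class <- definitions$class_id
  names(map2class) <- definitions$map_id
  ec_key <- character(); ec_sp <- character()
  for (i in seq_len(n)) {
    maps <- intersect(genes$pathway_maps[[i]], definitions$map_id)
    if (length(maps) == 0L) next
    sp <- genes$species[[i]]
    if (!sp %in% species$species_ids) next
    rows <- if (level == "map") maps else unique(map2class[maps])
    m[cbind(match(rows, ids), match(sp, species$species_ids))] <- 1L
    ecs <- genes$ec_numbers[[i]]
    if (length(ecs)) {
      grid <- expand.grid(map = maps, ec = ecs, stringsAsFactors = FALSE)
      ec_key <- c(ec_key, paste(grid$map, grid$ec, sep = "\r"))
      ec_sp <- c(ec_sp, rep(sp, nrow(grid)))
    }
  }
  ec_presence <- if (length(ec_key)) {
    tab <- tapply(ec_sp, ec_key, function(v) length(unique(v)))
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    out <- data.frame(map_id = vapply(parts, `[[`, "", 1L),
                      ec = vapply(parts, `[[`, "", 2L),
                      n_species = as.integer(tab), stringsAsFactors = FALSE)
    out <- out[order(out$map_id, out$ec), , drop = FALSE]
    rownames(out) <- NULL
    out
  } else data.frame(map_id = character(), ec = character(),
                    n_species = integer())
  list(presence = m, species_counts = rowSums(m), ec_presence = ec_presence)
}

#' Per-map gene counts, exclusive and inclusive
#'
#' For every secondary-metabolism question two counts matter: the number of
#' genes annotated to a map that are *exclusively* secondary (none of their
#' maps is primary) and the inclusive count of all genes annotated to the
#' map regardless of additional primary annotation.
#'
#' @param genes annotation data.frame.
#' @param definitions data.frame from [pathway_definitions()].
#' @return data.frame `map_id`, `class_id`, `secondary`,
#'   `exclusive_secondary_count`, `inclusive_count`.
#' @export
pathway_gene_counts <- function(genes, definitions) {
  cls <- classify_gene_metabolism(genes$pathway_maps, definitions)
  out <- definitions
  out$exclusive_secondary_count <- 0L
  out$inclusive_count <- 0L
  for (i in seq_len(nrow(genes))) {
    maps <- intersect(genes$pathway_maps[[i]], definitions$map_id)
    if (length(maps) == 0L) next
    j <- match(maps, out$map_id)
    out$inclusive_count[j] <- out$inclusive_count[j] + 1L
    if (cls[i] == "secondary")
      out$exclusive_secondary_count[j] <- out$exclusive_secondary_count[j] + 1L
  }
  out
}

#' Per-species gene, family-member and singleton tallies
#'
#' For every species: how many genes it contributes, how many of them sit in
#' multi-member families and how many are singletons. The two parts always
#' sum to the species' gene count.
#'
#' @param partition a `gene_partition`.
#' @param genes annotation data.frame.
#' @param species a [species_set()].
#' @return data.frame `species_id`, `n_genes`, `n_in_families`,
#'   `n_singletons`.
#' @export
species_gene_tallies <- function(partition, genes, species) {
  sp <- genes$species[match(partition$gene_id, genes$gene_id)]
  out <- data.frame(species_id = species$species_ids,
                    stringsAsFactors = FALSE)
  out$n_genes <- vapply(out$species_id, function(s) sum(sp == s), 0L)
  out$n_singletons <- vapply(out$species_id, function(s)
    sum(sp == s & partition$singleton), 0L)
  out$n_in_families <- out$n_genes - out$n_singletons
  out[c("species_id", "n_genes", "n_in_families", "n_singletons")]
}

#' Resolve pathway memberships to gene objects
#'
#' For each pathway (map or class) collects the member genes and the set of
#' gene objects containing at least one member gene — the unit the
#' enrichment statistic operates on. For secondary-metabolism maps the
#' membership can be restricted to exclusively-secondary genes
#' (`secondary_exclusive = TRUE`, the default), so that dual-annotated
#' primary genes do not dilute secondary pathways.
#'
#' @param genes annotation data.frame.
#' @param partition a `gene_partition`.
#' @param definitions data.frame from [pathway_definitions()].
#' @param level `"map"` or `"class"`.
#' @param secondary_exclusive restrict secondary maps to exclusively
#'   secondary genes.
#' @return named list: pathway id -> character vector of member object ids.
#' @export
pathway_memberships <- function(genes, partition, definitions,
                                level = c("map", "class"),
                                secondary_exclusive = TRUE) {
  level <- match.arg(level)
  obj <- partition$object_id[match(genes$gene_id, partition$gene_id)]
  cls <- classify_gene_metabolism(genes$pathway_maps, definitions)
  sec <- definitions$secondary
  names(sec) <- definitions$map_id
  map2class <- definitions$class_id
  names(map2class) <- definitions$map_id
  ids <- if (level == "map") definitions$map_id else
    sort(unique(definitions$class_id))
  members <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_len(nrow(genes))) {
    maps <- intersect(genes$pathway_maps[[i]], definitions$map_id)
    if (length(maps) == 0L || is.na(obj[i])) next
    if (secondary_exclusive && level == "map") {
      drop <- sec[maps] & cls[i] != "secondary"
      maps <- maps[!drop]
    }
    if (length(maps) == 0L) next
    keys <- if (level == "map") maps else unique(map2class[maps])
    for (k in keys) members[[k]] <- c(members[[k]], obj[i])
  }
  lapply(members, function(v) sort(unique(v)))
}
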