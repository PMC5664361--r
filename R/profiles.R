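# Phylogenetic profiles: per-object presence/absence vectors over the
# ordered species set, identical-profile grouping, and the species dendrogram.

#' Build phylogenetic profiles for all gene objects
#'
#' A gene object is present in a species iff at least one member gene belongs
#' to that species (copy number is ignored — profiles are strictly binary).
#' The profile vector is aligned to the species-set order.
#'
#' @param partition a `gene_partition` from [build_families()].
#' @param genes annotation data.frame.
#' @param species a [species_set()].
#' @param kegg_annotated_only keep only objects with at least one member gene
#'   annotated to a pathway map (the subset used for enrichment); default
#'   `FALSE` returns the full universe.
#' @return integer 0/1 matrix, objects in rows (rownames = object ids),
#'   species in columns (colnames = species ids). Every row has at least one 1.
#' @export
build_profiles <- function(partition, genes, species,
                           kegg_annotated_only = FALSE) {
  idx <- match(partition$gene_id, genes$gene_id)
  if (anyNA(idx)) stop("partition contains genes absent from the annotation")
  sp <- genes$species[idx]
  unknown <- setdiff(unique(sp), species$species_ids)
  if (length(unknown))
    stop("member species outside the species set: ",
         paste(unknown, collapse = ", "))
  objs <- sort(unique(partition$object_id))
  m <- matrix(0L, nrow = length(objs), ncol = length(species$species_ids),
              dimnames = list(objs, species$species_ids))
  m[cbind(match(partition$object_id, objs),
          match(sp, species$species_ids))] <- 1L
  if (kegg_annotated_only) {
    has_map <- lengths(genes$pathway_maps[idx]) > 0L
    keep <- sort(unique(partition$object_id[has_map]))
    m <- m[keep, , drop = FALSE]
  }
  m
}

#' Profile of a single gene object
#'
#' @param member_species character vector of species the object's member
#'   genes occur in.
#' @param species a [species_set()].
#' @return integer 0/1 vector named by species id.
#' @export
build_profile <- function(member_species, species) {
  unknown <- setdiff(unique(member_species), species$species_ids)
  if (length(unknown))
    stop("member species outside the species set: ",
         paste(unknown, collapse = ", "))
  out <- as.integer(species$species_ids %in% member_species)
  names(out) <- species$species_ids
  out
}

#' Encode profile rows as strings
#'
#' Internal helper also useful in tests: identical profiles get identical
#' keys, so grouping and identity counting reduce to string equality.
#'
#' @param profiles 0/1 matrix (objects x species).
#' @return character vector of bit strings, named by object id.
#' @export
profile_keys <- function(profiles) {
  k <- apply(profiles, 1L, paste, collapse = "")
  names(k) <- rownames(profiles)
  k
}

#' Group gene objects with identical profiles
#'
#' Profiles are identical iff they share exactly the same bit vector. Returns
#' the groups and the occurrence histogram (number of objects per unique
#' profile, descending) — the survey statistic of profile reuse.
#'
#' @param profiles 0/1 matrix from [build_profiles()].
#' @return list with `groups` (data.frame `profile`, `occurrence`, list-column
#'   `object_ids`; sorted by descending occurrence, ties by profile string)
#'   and `histogram` (integer vector of occurrences, descending).
#' @export
group_identical_profiles <- function(profiles) {
  keys <- profile_keys(profiles)
  by_key <- split(names(keys), keys)
  occ <- lengths(by_key)
  ord <- order(-occ, names(by_key))
  groups <- data.frame(profile = names(by_key)[ord],
                       occurrence = unname(occ[ord]),
                       stringsAsFactors = FALSE)
  groups$object_ids <- I(lapply(by_key[ord], sort))
  list(groups = groups, histogram = groups$occurrence)
}

#' Hierarchical clustering of species by profile pattern
#'
#' Clusters the species (columns) of the profile matrix by complete linkage
#' on Euclidean distance, the standard agglomeration for binary survey
#' matrices. Merge heights are the maximum pairwise column distances; the
#' tree is returned as an `hclust` object plus a Newick string (branch
#' lengths derived from merge heights). Agglomeration ties are broken toward
#' the lowest-index pair for cross-platform determinism (stats::hclust does
#' this internally).
#'
#' @param profiles 0/1 matrix (objects x species), at least two species.
#' @return list with `hclust` and `newick`.
#' @export
cluster_species <- function(profiles) {
  if (ncol(profiles) < 2L)
    stop("species clustering needs at least 2 species")
  d <- stats::dist(t(profiles), method = "euclidean")
  hc <- stats::hclust(d, method = "complete")
  phy <- ape::as.phylo(hc)
  list(hclust = hc, newick = ape::write.tree(phy))
}

#' Write a profile matrix as TSV
#' @param profiles 0/1 matrix.
#' @param path output path.
#' @export
write_profiles <- function(profiles, path) {
  df <- data.frame(object_id = rownames(profiles), profiles,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a profile matrix written by [write_profiles()]
#' @param path file path.
#' @return integer 0/1 matrix.
#' @export
read_profiles <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[setdiff(names(df), "object_id")])
  storage.mode(m) <- "integer"
  rownames(m) <- df$object_id
  m
}
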