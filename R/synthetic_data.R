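# Synthetic input bundles with planted, tunable structure.
#
# The generator emulates the statistical shape of a multi-species enzyme
# annotation snapshot: an ordered species set (a subset pathway-annotated),
# multi-species gene families with high within-family identity, per-object
# binary profiles drawn from a reused archetype repertoire, a two-level
# pathway hierarchy with multi-label membership, correlated expression
# blocks, and interaction pairs whose probability rises with profile
# similarity. Profiles are generated directly (not by evolving gain/loss on
# a tree): every downstream statistic consumes the profile matrix only.
#
# Pathway coherence is planted through `pathway_coherence` (rho): that
# fraction of pathway maps is "coherent", and objects whose home map is
# coherent realise the map's archetype profile with per-bit flip probability
# `profile_flip_noise` (epsilon). All other family objects copy an archetype
# drawn from the repertoire with geometrically decaying reuse weights —
# mirroring the heavy profile reuse of real snapshots, where a handful of
# profiles (led by present-in-all) cover a large share of objects, and
# keeping identical-profile pairs observable at simulation scale. Singleton
# objects carry one gene, hence a single-species profile.

#' Simulation configuration
#'
#' Defaults describe a scaled-down but structurally faithful snapshot:
#' 39 species (24 pathway-annotated), 200 gene objects, a 5x10 class/map
#' hierarchy, moderate profile reuse and within-family identities well above
#' the 30 percent clustering threshold.
#'
#' @param n_species number of species (>= 2).
#' @param n_kegg_species how many species carry pathway annotation.
#' @param n_families multi-member family count.
#' @param n_singletons singleton object count.
#' @param genes_per_family_per_species Poisson mean lambda; a family carries
#'   `1 + Poisson(lambda)` genes in each species it is present in.
#' @param n_classes,maps_per_class two-level pathway hierarchy size.
#' @param n_secondary_classes trailing classes flagged secondary metabolism.
#' @param pathway_coherence rho in \[0,1\]: fraction of maps whose home
#'   objects share the map archetype.
#' @param profile_flip_noise epsilon in \[0,0.5\]: per-bit flip probability
#'   when a coherent object realises its archetype.
#' @param presence_prob per-species archetype presence probability (scalar
#'   or length `n_species`).
#' @param archetype_reuse_decay geometric decay of the repertoire reuse
#'   weights for non-coherent objects (smaller = stronger reuse).
#' @param extra_maps_lambda Poisson mean of extra pathway maps per object
#'   (capped at 2, so each object has 1-3 maps).
#' @param within_family_identity,cross_family_identity percent-identity
#'   ranges for within-family edges and cross-family decoy edges.
#' @param decoy_edge_rate decoy edges as a fraction of the object count.
#' @param expression_samples,block_correlation expression panel size and the
#'   squared loading of the shared per-profile latent factor.
#' @param ppi_beta logistic slope tying interaction probability to d_PP.
#' @param ppi_candidates candidate object pairs screened for interaction.
#' @param ppi_predicted_rate fraction of emitted pairs labelled `predicted`
#'   rather than `experimental` (exercises the evidence filter).
#' @param seed integer seed; the bundle is a pure function of the config.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_species = 39L, n_kegg_species = 24L,
                       n_families = 180L, n_singletons = 20L,
                       genes_per_family_per_species = 0.3,
                       n_classes = 5L, maps_per_class = 10L,
                       n_secondary_classes = 1L,
                       pathway_coherence = 0.5,
                       profile_flip_noise = 0.05,
                       presence_prob = 0.6,
                       archetype_reuse_decay = 0.8,
                       extra_maps_lambda = 1.2,
                       within_family_identity = c(60, 95),
                       cross_family_identity = c(5, 25),
                       decoy_edge_rate = 0.05,
                       expression_samples = 120L,
                       block_correlation = 0.7,
                       ppi_beta = 6,
                       ppi_candidates = 1000L,
                       ppi_predicted_rate = 0.05,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_species >= 2L, n_kegg_species <= n_species,
            pathway_coherence >= 0, pathway_coherence <= 1,
            profile_flip_noise >= 0, profile_flip_noise <= 0.5,
            all(presence_prob > 0), all(presence_prob <= 1),
            block_correlation >= 0, block_correlation <= 1)
  if (length(presence_prob) == 1L)
    cfg$presence_prob <- rep(presence_prob, n_species)
  else stopifnot(length(presence_prob) == n_species)
  if (all(within_family_identity < 30))
    warning("within-family identities all below the 30% threshold: ",
            "planted families will not be recoverable")
  class(cfg) <- "sim_config"
  cfg
}

.rbern_profile <- function(p) {
  repeat {
    bits <- as.integer(stats::runif(length(p)) < p)
    if (any(bits == 1L)) return(bits)
  }
}

.flip_bits <- function(bits, eps) {
  if (eps <= 0) return(bits)
  repeat {
    flip <- stats::runif(length(bits)) < eps
    out <- ifelse(flip, 1L - bits, bits)
    if (any(out == 1L)) return(as.integer(out))
  }
}

#' Generate a complete synthetic input bundle
#'
#' See the configuration documentation for the generative model. The bundle
#' holds both the in-memory objects consumed by the pipeline and a `truth`
#' record of every planted quantity; [write_bundle()] serialises it to the
#' interchange TSV formats.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_bundle` with elements `species`, `genes`,
#'   `homology`, `expression`, `ppi`, `definitions`, `truth`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old <- .save_rng(config$seed)
  on.exit(.restore_rng(old))
  ns <- config$n_species
  species <- species_set(sprintf("SP%02d", seq_len(ns)),
                         seq_len(ns) <= config$n_kegg_species)
  # hierarchy
  classes <- sprintf("C%02d", seq_len(config$n_classes))
  maps <- character(); map_class <- character()
  for (ci in seq_len(config$n_classes)) {
    m <- sprintf("M%02d%02d", ci, seq_len(config$maps_per_class))
    maps <- c(maps, m); map_class <- c(map_class, rep(classes[ci], length(m)))
  }
  secondary <- if (config$n_secondary_classes > 0L)
    classes[seq(config$n_classes - config$n_secondary_classes + 1L,
                config$n_classes)] else character()
  definitions <- pathway_definitions(
    data.frame(map_id = maps, class_id = map_class),
    secondary_classes = secondary)
  n_maps <- length(maps)
  # archetype per map (independent Bernoulli bits, non-zero)
  archetypes <- t(vapply(seq_len(n_maps), function(i)
    .rbern_profile(config$presence_prob), integer(ns)))
  rownames(archetypes) <- maps; colnames(archetypes) <- species$species_ids
  coherent <- sort(sample(maps, round(config$pathway_coherence * n_maps)))
  # repertoire reuse weights (geometric decay over map order)
  w <- config$archetype_reuse_decay ^ (seq_len(n_maps) - 1L)
  w <- w / sum(w)
  # objects
  n_fam <- config$n_families; n_single <- config$n_singletons
  n_obj <- n_fam + n_single
  obj_ids <- c(sprintf("F%03d", seq_len(n_fam)),
               sprintf("S%03d", seq_len(n_single)))
  home <- sample(maps, n_obj, replace = TRUE)
  extra <- pmin(2L, stats::rpois(n_obj, config$extra_maps_lambda))
  obj_maps <- vector("list", n_obj)
  for (i in seq_len(n_obj)) {
    pool <- setdiff(maps, home[i])
    obj_maps[[i]] <- sort(c(home[i],
                            if (extra[i] > 0L) sample(pool, extra[i])))
  }
  names(obj_maps) <- obj_ids
  is_singleton <- seq_len(n_obj) > n_fam
  profiles <- matrix(0L, n_obj, ns,
                     dimnames = list(obj_ids, species$species_ids))
  for (i in seq_len(n_obj)) {
    if (is_singleton[i]) {
      profiles[i, sample.int(ns, 1L)] <- 1L
    } else if (home[i] %in% coherent) {
      profiles[i, ] <- .flip_bits(archetypes[home[i], ],
                                  config$profile_flip_noise)
    } else {
      profiles[i, ] <- archetypes[sample.int(n_maps, 1L, prob = w), ]
    }
  }
  # genes: one or more per present species
  gene_id <- character(); gene_sp <- character(); gene_obj <- character()
  counter <- 0L
  for (i in seq_len(n_obj)) {
    present <- which(profiles[i, ] == 1L)
    for (s in present) {
      k <- if (is_singleton[i]) 1L
           else 1L + stats::rpois(1L, config$genes_per_family_per_species)
      ids <- sprintf("G%05d", counter + seq_len(k))
      counter <- counter + k
      gene_id <- c(gene_id, ids)
      gene_sp <- c(gene_sp, rep(species$species_ids[s], k))
      gene_obj <- c(gene_obj, rep(obj_ids[i], k))
    }
  }
  genes <- data.frame(gene_id = gene_id, species = gene_sp,
                      stringsAsFactors = FALSE)
  # one EC per planted object: family membership and function coincide
  ec_of_obj <- stats::setNames(sprintf("1.1.1.%d", seq_len(n_obj)), obj_ids)
  genes$ec_numbers <- lapply(gene_obj, function(o) ec_of_obj[[o]])
  genes$pathway_maps <- obj_maps[gene_obj]
  m2c <- stats::setNames(definitions$class_id, definitions$map_id)
  genes$pathway_classes <- lapply(genes$pathway_maps, function(v)
    sort(unique(unname(m2c[v]))))
  attr(genes, "hierarchy") <- definitions[c("map_id", "class_id")]
  # homology: all within-family pairs + decoy cross-family edges
  ga <- character(); gb <- character(); pid <- numeric(); rel <- character()
  for (i in which(!is_singleton)) {
    members <- gene_id[gene_obj == obj_ids[i]]
    if (length(members) < 2L) next
    prs <- utils::combn(members, 2L)
    np <- ncol(prs)
    ga <- c(ga, prs[1L, ]); gb <- c(gb, prs[2L, ])
    pid <- c(pid, stats::runif(np, config$within_family_identity[1L],
                               config$within_family_identity[2L]))
    spa <- gene_sp[match(prs[1L, ], gene_id)]
    spb <- gene_sp[match(prs[2L, ], gene_id)]
    rel <- c(rel, ifelse(spa == spb, "paralog", "ortholog"))
  }
  n_decoy <- round(config$decoy_edge_rate * n_obj)
  made <- 0L
  while (made < n_decoy) {
    cand <- sample.int(length(gene_id), 2L)
    if (gene_obj[cand[1L]] == gene_obj[cand[2L]]) next
    ga <- c(ga, gene_id[cand[1L]]); gb <- c(gb, gene_id[cand[2L]])
    pid <- c(pid, stats::runif(1L, config$cross_family_identity[1L],
                               config$cross_family_identity[2L]))
    rel <- c(rel, "ortholog")
    made <- made + 1L
  }
  homology <- validate_homology_edges(
    data.frame(gene_a = ga, gene_b = gb, pct_identity = pid,
               confidence = "high", relation = rel,
               stringsAsFactors = FALSE), source = "simulated homology")
  # expression: per-profile latent factor, sqrt(rho) loading, lognormal
  keys <- profile_keys(profiles)
  uk <- unique(keys)
  nsmp <- config$expression_samples
  factors <- matrix(stats::rnorm(length(uk) * nsmp), length(uk), nsmp,
                    dimnames = list(uk, NULL))
  loading <- sqrt(config$block_correlation)
  noise_sd <- sqrt(1 - config$block_correlation)
  z <- factors[keys[gene_obj], , drop = FALSE] * loading +
    matrix(stats::rnorm(length(gene_id) * nsmp, sd = noise_sd),
           length(gene_id), nsmp)
  expression <- exp(5 + z)
  rownames(expression) <- gene_id
  colnames(expression) <- sprintf("SMP%03d", seq_len(nsmp))
  # PPI: candidate object pairs, interaction logistic in d_PP
  cand_i <- sample.int(n_obj, config$ppi_candidates, replace = TRUE)
  cand_j <- sample.int(n_obj, config$ppi_candidates, replace = TRUE)
  ok <- cand_i != cand_j
  cand_i <- cand_i[ok]; cand_j <- cand_j[ok]
  pb <- profiles > 0
  dpp <- rowSums(pb[cand_i, , drop = FALSE] & pb[cand_j, , drop = FALSE]) /
    rowSums(pb[cand_i, , drop = FALSE] | pb[cand_j, , drop = FALSE])
  hit <- stats::runif(length(dpp)) < stats::plogis(config$ppi_beta *
                                                   (dpp - 0.5))
  pa <- character(); pbg <- character()
  for (k in which(hit)) {
    m1 <- gene_id[gene_obj == obj_ids[cand_i[k]]]
    m2 <- gene_id[gene_obj == obj_ids[cand_j[k]]]
    pa <- c(pa, if (length(m1) == 1L) m1 else sample(m1, 1L))
    pbg <- c(pbg, if (length(m2) == 1L) m2 else sample(m2, 1L))
  }
  evid <- ifelse(stats::runif(length(pa)) < config$ppi_predicted_rate,
                 "predicted", "experimental")
  ppi <- data.frame(gene_a = pmin(pa, pbg), gene_b = pmax(pa, pbg),
                    evidence = evid, stringsAsFactors = FALSE)
  ppi <- ppi[!duplicated(paste(ppi$gene_a, ppi$gene_b)), , drop = FALSE]
  ppi <- ppi[order(ppi$gene_a, ppi$gene_b), , drop = FALSE]
  rownames(ppi) <- NULL
  truth <- list(partition = stats::setNames(gene_obj, gene_id),
                profiles = profiles,
                archetypes = archetypes,
                coherent_maps = coherent,
                object_maps = obj_maps,
                home_map = stats::setNames(home, obj_ids),
                singleton = stats::setNames(is_singleton, obj_ids),
                interacting_object_pairs =
                  unique(data.frame(
                    a = pmin(obj_ids[cand_i[hit]], obj_ids[cand_j[hit]]),
                    b = pmax(obj_ids[cand_i[hit]], obj_ids[cand_j[hit]]),
                    stringsAsFactors = FALSE)))
  structure(list(species = species, genes = genes, homology = homology,
                 expression = expression, ppi = ppi,
                 definitions = definitions, truth = truth, config = config),
            class = "sim_bundle")
}

#' Write a simulated bundle to a directory
#'
#' Emits `species.tsv`, `annotation.tsv`, `homology.tsv`, `expression.tsv`,
#' `ppi.tsv`, `pathways.tsv` and `truth.json`.
#'
#' @param bundle a `sim_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_species_table(bundle$species, file.path(dir, "species.tsv"))
  write_annotation_table(bundle$genes, file.path(dir, "annotation.tsv"))
  utils::write.table(bundle$homology, file.path(dir, "homology.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_expression_matrix(bundle$expression, file.path(dir, "expression.tsv"))
  utils::write.table(bundle$ppi, file.path(dir, "ppi.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$definitions, file.path(dir, "pathways.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- bundle$truth
  truth$profiles <- cbind(object_id = rownames(truth$profiles),
                          as.data.frame(truth$profiles))
  truth$archetypes <- cbind(map_id = rownames(truth$archetypes),
                            as.data.frame(truth$archetypes))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load the shipped micro-fixture
#'
#' A deterministic, hand-checkable bundle (6 species, 12 families,
#' 4 singletons, 3 classes x 2 maps) stored as plain TSV under
#' `inst/extdata/fixture_small/`, together with oracle-computed expected
#' values (`expected.json`: the family partition, profile strings, and
#' per-pathway F_pw / F_all / E).
#'
#' @return list with the bundle tables plus `expected`.
#' @export
fixture_small <- function() {
  dir <- system.file("extdata", "fixture_small", package = "phyloprof",
                     mustWork = TRUE)
  species <- read_species_table(file.path(dir, "species.tsv"))
  definitions <- utils::read.delim(file.path(dir, "pathways.tsv"),
                                   colClasses = "character")
  definitions$secondary <- definitions$secondary == "TRUE"
  genes <- read_annotation_table(file.path(dir, "annotation.tsv"), species,
                                 hierarchy = definitions)
  list(species = species,
       genes = genes,
       homology = read_homology_table(file.path(dir, "homology.tsv")),
       expression = read_expression_matrix(file.path(dir, "expression.tsv")),
       ppi = read_ppi_table(file.path(dir, "ppi.tsv"),
                            experimental_only = FALSE),
       definitions = definitions,
       expected = jsonlite::read_json(file.path(dir, "expected.json"),
                                      simplifyVector = TRUE))
}
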