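# End-to-end orchestration: families -> profiles -> surveys -> enrichment ->
# pair similarity -> prediction -> associations, from one configuration,
# with deterministic seeding and a run manifest.

#' Build a run configuration
#'
#' Defaults equal the conventional analysis settings: 30 percent identity,
#' high-confidence edges only, 10,000 permutation draws, 100,000 sampled
#' pairs, 50 trees, 100 class-level and 20 map-level shuffles.
#'
#' @param species,annotation,homology paths to the three mandatory inputs.
#' @param expression,ppi optional input paths; their stage is skipped (and
#'   noted in the manifest) when `NULL`.
#' @param pathways optional explicit map/class table (TSV with `map_id`,
#'   `class_id`); inferred from the annotation when `NULL`.
#' @param out_dir output directory.
#' @param min_identity,high_confidence_only family network filters.
#' @param n_draws,n_pairs,n_trees,class_shuffles,map_shuffles stage sizes.
#' @param sample_keep_prob expression-sample subsampling probability passed
#'   to [preprocess_expression()].
#' @param secondary_classes class ids flagged secondary metabolism.
#' @param seed root seed; every stage derives its own via [derive_seed()].
#' @return list of class `run_config`.
#' @export
run_config <- function(species, annotation, homology,
                       expression = NULL, ppi = NULL, pathways = NULL,
                       out_dir = "phyloprof_out",
                       min_identity = 30, high_confidence_only = TRUE,
                       n_draws = 10000L, n_pairs = 100000L, n_trees = 50L,
                       class_shuffles = 100L, map_shuffles = 20L,
                       sample_keep_prob = 0.10,
                       secondary_classes = SECONDARY_CLASSES,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

.log_stage <- function(log, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  c(log, line)
}

#' Run the full pipeline
#'
#' Executes every stage in dependency order, writes each stage's outputs
#' under `config$out_dir`, and returns (and writes) a manifest recording
#' seeds, row counts and an md5 checksum per output file. Reruns with the
#' same config and inputs are byte-identical.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log <- character()
  outputs <- character()
  stage <- "load"
  res <- tryCatch({
    log <- .log_stage(log, stage, "reading inputs")
    species <- read_species_table(config$species)
    hier <- NULL
    if (!is.null(config$pathways)) {
      hier <- utils::read.delim(config$pathways, colClasses = "character")
    }
    genes <- read_annotation_table(config$annotation, species, hierarchy = hier)
    edges <- read_homology_table(config$homology)
    definitions <- pathway_definitions(attr(genes, "hierarchy"),
                                       secondary_classes =
                                         config$secondary_classes)

    stage <- "families"
    partition <- build_families(edges, genes,
                                min_identity = config$min_identity,
                                require_high_confidence =
                                  config$high_confidence_only)
    f <- file.path(out, "families.tsv")
    write_results(as.data.frame(partition), f)
    outputs <- c(outputs, f)
    log <- .log_stage(log, stage, sprintf("%d genes -> %d objects",
                                          nrow(partition),
                                          length(unique(partition$object_id))))

    stage <- "profiles"
    profiles <- build_profiles(partition, genes, species)
    kegg_profiles <- build_profiles(partition, genes, species,
                                    kegg_annotated_only = TRUE)
    f <- file.path(out, "profiles.tsv")
    write_profiles(profiles, f)
    outputs <- c(outputs, f)
    grp <- group_identical_profiles(kegg_profiles)
    f <- file.path(out, "profile_groups.tsv")
    write_results(grp$groups[c("profile", "occurrence")], f)
    outputs <- c(outputs, f)
    if (ncol(profiles) >= 2L) {
      tree <- cluster_species(kegg_profiles)
      f <- file.path(out, "species_tree.nwk")
      writeLines(tree$newick, f)
      outputs <- c(outputs, f)
    }
    log <- .log_stage(log, stage,
                      sprintf("%d objects, %d unique profiles",
                              nrow(profiles), nrow(grp$groups)))

    stage <- "survey"
    pres <- pathway_presence_matrix(genes, definitions, species)
    f <- file.path(out, "pathway_presence.tsv")
    write_results(data.frame(pathway = rownames(pres$presence),
                             pres$presence, check.names = FALSE), f)
    outputs <- c(outputs, f)
    counts <- pathway_gene_counts(genes, definitions)
    f <- file.path(out, "pathway_gene_counts.tsv")
    write_results(counts, f)
    outputs <- c(outputs, f)
    tal <- species_gene_tallies(partition, genes, species)
    f <- file.path(out, "species_tallies.tsv")
    write_results(tal, f)
    outputs <- c(outputs, f)
    log <- .log_stage(log, stage, sprintf("%d pathways surveyed", nrow(counts)))

    stage <- "enrichment"
    ari <- evaluate_partition(partition, genes)
    for (level in c("class", "map")) {
      mem <- pathway_memberships(genes, partition, definitions, level = level)
      scan <- enrichment_scan(mem, kegg_profiles, n_draws = config$n_draws,
                              seed = derive_seed(config$seed,
                                                 paste0("enrich_", level)))
      f <- file.path(out, sprintf("enrichment_%s.tsv", level))
      write_results(as.data.frame(scan), f)
      outputs <- c(outputs, f)
      log <- .log_stage(log, stage,
                        sprintf("%s level: %d pathways, %d testable",
                                level, nrow(scan), sum(scan$testable)))
    }

    stage <- "pairsim"
    obj_maps <- object_pathways(genes, partition)
    prs <- sample_pairs(kegg_profiles, obj_maps, n_pairs = config$n_pairs,
                        seed = derive_seed(config$seed, "pairsim"))
    f <- file.path(out, "pairs.tsv")
    write_results(prs, f)
    outputs <- c(outputs, f)
    fit <- fit_logistic(prs$d_pp, prs$a_pw)
    f <- file.path(out, "pair_fit.json")
    jsonlite::write_json(list(a = fit$a, b = fit$b, converged = fit$converged,
                              rss = fit$rss, n = fit$n),
                         f, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, f)
    log <- .log_stage(log, stage,
                      sprintf("%d pairs, logistic converged: %s",
                              nrow(prs), fit$converged))

    stage <- "predict"
    hierarchy <- label_hierarchy(definitions$map_id, definitions$class_id)
    labelled <- obj_maps[lengths(obj_maps) > 0L]
    pred_cmp <- list()
    for (level in c("class", "map")) {
      n_sh <- if (level == "class") config$class_shuffles else
        config$map_shuffles
      cmp <- compare_true_vs_random(
        kegg_profiles[intersect(rownames(kegg_profiles), names(labelled)), ,
                      drop = FALSE],
        labelled, hierarchy, level = level, n_shuffles = n_sh,
        n_trees = config$n_trees,
        seed = derive_seed(config$seed, paste0("predict_", level)))
      pred_cmp[[level]] <- list(mean_true = cmp$mean_true,
                                mean_random = cmp$mean_random,
                                wilcoxon_p = cmp$wilcoxon_p,
                                n_shuffles = cmp$n_shuffles)
      f <- file.path(out, sprintf("prediction_%s.tsv", level))
      write_results(cmp$true, f)
      outputs <- c(outputs, f)
      log <- .log_stage(log, stage,
                        sprintf("%s: mean true %.3f vs random %.3f (p=%.3g)",
                                level, cmp$mean_true, cmp$mean_random,
                                cmp$wilcoxon_p))
    }
    f <- file.path(out, "prediction_comparison.json")
    jsonlite::write_json(pred_cmp, f, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, f)

    skipped <- character()
    gene2object <- stats::setNames(partition$object_id, partition$gene_id)
    stage <- "assoc"
    if (!is.null(config$expression)) {
      expr <- read_expression_matrix(config$expression)
      expr <- preprocess_expression(expr,
                                    sample_keep_prob = config$sample_keep_prob,
                                    seed = derive_seed(config$seed, "exprsub"))
      cx <- coexpression_vs_profile(expr, gene2object, profiles,
                                    seed = derive_seed(config$seed, "coexpr"))
      f <- file.path(out, "coexpr.tsv")
      write_results(cx$records, f)
      outputs <- c(outputs, f)
      log <- .log_stage(log, stage,
                        sprintf("coexpression r = %.3f (p=%.3g)",
                                cx$correlation, cx$cor_p))
    } else skipped <- c(skipped, "coexpression")
    if (!is.null(config$ppi)) {
      ppi <- read_ppi_table(config$ppi)
      pc <- ppi_profile_comparison(ppi, gene2object, profiles,
                                   seed = derive_seed(config$seed, "ppibg"))
      f <- file.path(out, "ppi_comparison.json")
      jsonlite::write_json(list(median_interacting = pc$median_interacting,
                                median_noninteracting =
                                  pc$median_noninteracting,
                                p_value = pc$p_value,
                                n_interacting = pc$n_interacting,
                                n_noninteracting = pc$n_noninteracting),
                           f, auto_unbox = TRUE, digits = NA)
      outputs <- c(outputs, f)
      log <- .log_stage(log, stage,
                        sprintf("PPI medians %.3f vs %.3f (p=%.3g)",
                                pc$median_interacting,
                                pc$median_noninteracting, pc$p_value))
    } else skipped <- c(skipped, "ppi")
    list(ari = ari, skipped = skipped)
  }, error = function(e) {
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  manifest <- list(package_version = as.character(utils::packageVersion("phyloprof")),
                   seed = config$seed,
                   settings = config[c("min_identity", "high_confidence_only",
                                       "n_draws", "n_pairs", "n_trees",
                                       "class_shuffles", "map_shuffles")],
                   adjusted_rand_index = res$ari,
                   skipped_stages = res$skipped,
                   outputs = lapply(stats::setNames(outputs, basename(outputs)),
                                    function(f)
                                      list(md5 = unname(tools::md5sum(f)),
                                           bytes = file.size(f))),
                   log = log)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Pathway-map sets per gene object
#'
#' The union of the member genes' pathway maps, for every object in the
#' partition (possibly empty).
#'
#' @param genes annotation data.frame.
#' @param partition a `gene_partition`.
#' @return named list object id -> character vector of map ids.
#' @export
object_pathways <- function(genes, partition) {
  obj <- partition$object_id[match(genes$gene_id, partition$gene_id)]
  out <- lapply(split(genes$pathway_maps, obj), function(l)
    sort(unique(unlist(l, use.names = FALSE))))
  ids <- sort(unique(partition$object_id))
  res <- stats::setNames(vector("list", length(ids)), ids)
  for (i in names(out)) res[[i]] <- out[[i]]
  lapply(res, function(v) if (is.null(v)) character() else v)
}
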