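tiny_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_species = 8, n_kegg_species = 6, n_families = 30,
         n_singletons = 5, n_classes = 2, maps_per_class = 3,
         expression_samples = 10, ppi_candidates = 100),
    list(...))
  do.call(sim_config, args)
}

test_that("identical seeds give byte-identical bundles", {
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  write_bundle(simulate_dataset(tiny_cfg(seed = 99)), d1)
  write_bundle(simulate_dataset(tiny_cfg(seed = 99)), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  d3 <- file.path(tempdir(), "bundle_c")
  write_bundle(simulate_dataset(tiny_cfg(seed = 100)), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "homology.tsv"))),
                         unname(tools::md5sum(file.path(d3, "homology.tsv")))))
})

test_that("full coherence without noise gives F_pw = 1 on every pathway", {
  # exactness requires the world in which it is derivable: no singletons
  # (their profiles are single-species) and one map per object
  cfg <- tiny_cfg(pathway_coherence = 1, profile_flip_noise = 0,
                  n_singletons = 0, extra_maps_lambda = 0, seed = 17)
  b <- simulate_dataset(cfg)
  part <- build_families(b$homology, b$genes)
  prof <- build_profiles(part, b$genes, b$species)
  mem <- pathway_memberships(b$genes, part, b$definitions, level = "map",
                             secondary_exclusive = FALSE)
  for (m in names(mem)) {
    if (length(mem[[m]]) < 2) next
    expect_equal(fraction_identical_within(profile_keys(prof[mem[[m]], ])), 1,
                 label = m)
  }
})

test_that("planted families are recovered exactly and thresholds refine", {
  b <- simulate_dataset(tiny_cfg(seed = 41))
  part30 <- build_families(b$homology, b$genes, min_identity = 30)
  ari <- adjusted_rand_index(
    stats::setNames(part30$object_id, part30$gene_id), b$truth$partition)
  expect_equal(ari, 1)
  part70 <- build_families(b$homology, b$genes, min_identity = 70)
  nested <- tapply(part30$object_id[match(part70$gene_id, part30$gene_id)],
                   part70$object_id, function(v) length(unique(v)))
  expect_true(all(nested == 1L))
})

test_that("profile bit frequencies converge to the presence probability", {
  cfg <- sim_config(n_species = 10, n_kegg_species = 10, n_families = 400,
                    n_singletons = 0, n_classes = 2, maps_per_class = 30,
                    pathway_coherence = 0, presence_prob = 0.6,
                    archetype_reuse_decay = 1,  # equifrequent archetypes
                    expression_samples = 4, ppi_candidates = 10, seed = 8)
  b <- simulate_dataset(cfg)
  freq <- colMeans(b$truth$profiles)
  # per-species frequency converges to the mean over the 60 archetypes,
  # each bit Bernoulli(0.6): 4 sigma of that archetype mean is ~0.25
  expect_true(all(abs(freq - 0.6) < 4 * sqrt(0.6 * 0.4 / 60)))
})

test_that("pathway coherence raises enrichment monotonically in noise", {
  es <- vapply(c(0, 0.25), function(eps) {
    b <- simulate_dataset(tiny_cfg(pathway_coherence = 1,
                                   profile_flip_noise = eps,
                                   n_singletons = 0, extra_maps_lambda = 0,
                                   seed = 13))
    part <- build_families(b$homology, b$genes)
    prof <- build_profiles(part, b$genes, b$species)
    mem <- pathway_memberships(b$genes, part, b$definitions, level = "map",
                               secondary_exclusive = FALSE)
    mean(vapply(mem[lengths(mem) >= 2], function(ids) {
      f <- fraction_identical_within(profile_keys(prof[ids, ]))
      if (is.na(f)) 0 else f
    }, 0))
  }, 0)
  expect_gt(es[1], es[2])
})

test_that("infeasible identity ranges warn but still produce a bundle", {
  expect_warning(tiny_cfg(within_family_identity = c(5, 20)),
                 "not be recoverable")
})

test_that("the shipped fixture loads cleanly through every reader", {
  fx <- expect_silent(fixture_small())
  expect_s3_class(fx$species, "species_set")
  expect_equal(length(fx$species), 6L)
  expect_gt(nrow(fx$homology), 0L)
  expect_gt(nrow(fx$ppi), 0L)
  expect_true(all(c("families", "profiles", "enrichment_map") %in%
                    names(fx$expected)))
})

test_that("fixture families and profiles match the frozen oracle values", {
  fx <- fixture_small()
  part <- build_families(fx$homology, fx$genes)
  got <- unname(lapply(split(part$gene_id, part$object_id), sort))
  want <- lapply(fx$expected$families, sort)
  expect_setequal(got, want)
  prof <- build_profiles(part, fx$genes, fx$species)
  keys <- profile_keys(prof)
  # expected profiles indexed by lexicographically smallest member gene
  rep_gene <- vapply(split(part$gene_id, part$object_id), min, "")
  for (g in names(fx$expected$profiles)) {
    obj <- names(rep_gene)[rep_gene == g]
    expect_equal(unname(keys[obj]), fx$expected$profiles[[g]], label = g)
  }
})
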