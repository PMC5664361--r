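defs2 <- pathway_definitions(
  data.frame(map_id = c("00010", "00941", "00904"),
             class_id = c("Carbohydrate metabolism",
                          "Biosynthesis of other secondary metabolites",
                          "Metabolism of terpenoids and polyketides")))

ann_genes <- function(maps, species = "AA", ec = NULL) {
  g <- data.frame(gene_id = sprintf("g%02d", seq_along(maps)),
                  species = species, stringsAsFactors = FALSE)
  g$ec_numbers <- if (is.null(ec))
    replicate(length(maps), character(), simplify = FALSE) else ec
  g$pathway_maps <- maps
  g$pathway_classes <- replicate(length(maps), character(), simplify = FALSE)
  g
}

test_that("definitions flag secondary classes and reject split maps", {
  expect_equal(defs2$secondary[match(c("00010", "00941", "00904"),
                                     defs2$map_id)],
               c(FALSE, TRUE, TRUE))
  expect_error(pathway_definitions(
    data.frame(map_id = c("m", "m"), class_id = c("c1", "c2"))),
    "two classes")
  d <- pathway_definitions(
    data.frame(map_id = c("m1", "m2"), class_id = c("c1", "Overview")),
    exclude_classes = "Overview")
  expect_equal(d$map_id, "m1")
})

test_that("primary/secondary gene classification follows the all-maps rule", {
  expect_equal(classify_gene_metabolism(list("00941"), defs2), "secondary")
  expect_equal(classify_gene_metabolism(list(c("00941", "00010")), defs2),
               "primary")
  expect_equal(classify_gene_metabolism(list(character()), defs2), "none")
  expect_equal(classify_gene_metabolism(list(c("00941", "00904")), defs2),
               "secondary")
  expect_error(classify_gene_metabolism(list("99999"), defs2), "unknown")
})

test_that("presence matrix equals a brute-force recount", {
  sp <- species_set(c("AA", "BB", "CC", "DD"))
  g <- ann_genes(list("00010", c("00010", "00941"), "00904", character()),
                 species = c("AA", "BB", "BB", "CC"),
                 ec = list("1.1.1.1", c("1.1.1.1", "2.2.2.2"), "3.3.3.3",
                           character()))
  res <- pathway_presence_matrix(g, defs2, sp)
  for (m in rownames(res$presence)) for (s in sp$species_ids) {
    manual <- 0L
    for (i in seq_len(nrow(g)))
      if (m %in% g$pathway_maps[[i]] && g$species[i] == s) manual <- 1L
    expect_equal(res$presence[m, s], manual,
                 label = sprintf("presence[%s,%s]", m, s))
  }
  expect_equal(res$species_counts, rowSums(res$presence))
  expect_equal(unname(res$species_counts["00010"]), 2L)
  # EC presence: 1.1.1.1 on 00010 seen in AA and BB
  ecp <- res$ec_presence
  expect_equal(ecp$n_species[ecp$map_id == "00010" & ecp$ec == "1.1.1.1"], 2L)
  # class level row collapses its maps
  cl <- pathway_presence_matrix(g, defs2, sp, level = "class")
  expect_equal(unname(cl$presence["Carbohydrate metabolism", ]),
               c(1L, 1L, 0L, 0L))
})

test_that("exclusive vs inclusive gene counts", {
  g <- ann_genes(list("00941", "00941", c("00941", "00010"), "00010"))
  counts <- pathway_gene_counts(g, defs2)
  r <- counts[counts$map_id == "00941", ]
  expect_equal(r$exclusive_secondary_count, 2L)
  expect_equal(r$inclusive_count, 3L)
  expect_equal(counts$exclusive_secondary_count[counts$map_id == "00904"], 0L)
  expect_true(all(counts$exclusive_secondary_count <= counts$inclusive_count))
})

test_that("species tallies split into families plus singletons", {
  sp <- species_set(c("AA", "BB"))
  g <- ann_genes(list("00010", "00010", "00010"),
                 species = c("AA", "AA", "BB"))
  part <- data.frame(gene_id = g$gene_id,
                     object_id = c("o1", "o1", "o2"),
                     singleton = c(FALSE, FALSE, TRUE),
                     stringsAsFactors = FALSE)
  tal <- species_gene_tallies(part, g, sp)
  expect_equal(tal$n_in_families + tal$n_singletons, tal$n_genes)
  expect_equal(tal$n_genes, c(2L, 1L))
  expect_equal(tal$n_singletons, c(0L, 1L))
})

test_that("memberships resolve genes to objects with the secondary rule", {
  g <- ann_genes(list("00941", c("00941", "00010"), "00010"))
  part <- data.frame(gene_id = g$gene_id,
                     object_id = c("o1", "o2", "o3"),
                     singleton = TRUE, stringsAsFactors = FALSE)
  mem <- pathway_memberships(g, part, defs2, level = "map")
  # g02 is primary (dual annotation) so it leaves the secondary map 00941
  expect_equal(mem[["00941"]], "o1")
  expect_equal(mem[["00010"]], c("o2", "o3"))
  mem_all <- pathway_memberships(g, part, defs2, level = "map",
                                 secondary_exclusive = FALSE)
  expect_equal(mem_all[["00941"]], c("o1", "o2"))
  cl <- pathway_memberships(g, part, defs2, level = "class")
  expect_equal(cl[["Carbohydrate metabolism"]], c("o2", "o3"))
})
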