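make_genes <- function(ids, species = "AA", ec = NULL) {
  g <- data.frame(gene_id = ids, species = species, stringsAsFactors = FALSE)
  g$ec_numbers <- if (is.null(ec)) replicate(length(ids), character(),
                                             simplify = FALSE) else ec
  g$pathway_maps <- replicate(length(ids), character(), simplify = FALSE)
  g$pathway_classes <- replicate(length(ids), character(), simplify = FALSE)
  g
}

make_edges <- function(a, b, pct, conf = "high", rel = "ortholog") {
  validate_homology_edges(data.frame(
    gene_a = a, gene_b = b, pct_identity = pct,
    confidence = conf, relation = rel, stringsAsFactors = FALSE))
}

objects_of <- function(p) unname(lapply(split(p$gene_id, p$object_id), sort))

test_that("connected components obey the identity threshold", {
  genes <- make_genes(c("a", "b", "c", "d"))
  edges <- make_edges(c("a", "b"), c("b", "c"), c(80, 75))
  p30 <- build_families(edges, genes, min_identity = 30)
  expect_setequal(objects_of(p30), list(c("a", "b", "c"), "d"))
  expect_true(p30$singleton[p30$gene_id == "d"])
  expect_false(any(p30$singleton[p30$gene_id %in% c("a", "b", "c")]))
  p78 <- build_families(edges, genes, min_identity = 78)
  expect_setequal(objects_of(p78), list(c("a", "b"), "c", "d"))
})

test_that("transitive merging links chains without direct edges", {
  ids <- letters[1:5]
  genes <- make_genes(ids)
  edges <- make_edges(ids[1:4], ids[2:5], rep(31, 4))
  p <- build_families(edges, genes, min_identity = 30)
  expect_setequal(objects_of(p), list(ids))
})

test_that("confidence filtering and unknown endpoints behave per contract", {
  genes <- make_genes(c("a", "b", "c"))
  edges <- make_edges(c("a", "b"), c("b", "c"), c(50, 50),
                      conf = c("high", "low"), rel = c("ortholog", "paralog"))
  p <- build_families(edges, genes, require_high_confidence = TRUE)
  expect_setequal(objects_of(p), list(c("a", "b"), "c"))
  # orthologs-only scope keeps the low-confidence paralog edge
  p2 <- build_families(edges, genes, require_high_confidence = TRUE,
                       confidence_scope = "orthologs")
  expect_setequal(objects_of(p2), list(c("a", "b", "c")))
  bad <- make_edges("a", "zz", 90)
  expect_error(build_families(bad, genes), "unknown gene.*zz")
})

test_that("partitions are invariant to edge order and refine with threshold", {
  set.seed(7)
  for (trial in 1:10) {
    n <- 25
    ids <- sprintf("g%02d", 1:n)
    genes <- make_genes(ids)
    k <- 40
    i <- sample(n, k, replace = TRUE); j <- sample(n, k, replace = TRUE)
    keep <- i != j
    edges <- make_edges(ids[i[keep]], ids[j[keep]],
                        runif(sum(keep), 0, 100))
    p1 <- build_families(edges, genes, min_identity = 30)
    shuf <- edges[sample(nrow(edges)), , drop = FALSE]
    expect_equal(build_families(shuf, genes, min_identity = 30), p1)
    # refinement: every object at the higher threshold sits inside one
    # object of the lower threshold
    p2 <- build_families(edges, genes, min_identity = 70)
    parent <- tapply(p1$object_id[match(p2$gene_id, p1$gene_id)],
                     p2$object_id, function(v) length(unique(v)))
    expect_true(all(parent == 1L))
  }
})

test_that("function labels canonicalise EC sets", {
  expect_equal(function_label(c("2.3.1.12", "1.1.1.1")), "1.1.1.1;2.3.1.12")
  expect_equal(function_label(character()), "none")
  expect_false(function_label("1.1.1.1") ==
                 function_label(c("1.1.1.1", "9.9.9.9")))
  expect_equal(function_label(list(c("b", "a"), character(), "a")),
               c("a;b", "none", "a"))
})

test_that("adjusted Rand index matches hand-derived and oracle values", {
  expect_equal(adjusted_rand_index(c(1, 1, 2), c(1, 1, 2)), 1.0)
  # the classic 3-element disagreement
  expect_equal(adjusted_rand_index(c(1, 1, 2), c(1, 2, 2)), -0.5)
  set.seed(11)
  for (trial in 1:200) {
    n <- sample(5:30, 1)
    a <- sample(1:sample(2:6, 1), n, replace = TRUE)
    b <- sample(1:sample(2:6, 1), n, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), oracle_ari(a, b))
    expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a))
  }
})

test_that("label-shuffled ARI is centred on zero", {
  set.seed(3)
  a <- sample(1:8, 60, replace = TRUE)
  vals <- replicate(100, adjusted_rand_index(a, sample(a)))
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("evaluate_partition aligns universes and honours the EC filter", {
  genes <- make_genes(c("a", "b", "c", "d"),
                      ec = list("1.1.1.1", "1.1.1.1", character(), "2.2.2.2"))
  edges <- make_edges("a", "b", 90)
  p <- build_families(edges, genes)
  expect_equal(evaluate_partition(p, genes), 1.0)  # families == EC sets
  expect_equal(evaluate_partition(p, genes, include_unlabelled = FALSE), 1.0)
  expect_error(adjusted_rand_index(stats::setNames(1:3, c("a", "b", "c")),
                                   stats::setNames(1:3, c("a", "b", "x"))),
               "universe")
})
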