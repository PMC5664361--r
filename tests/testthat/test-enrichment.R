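test_that("identical-pair fractions reproduce the worked toy example", {
  expect_equal(fraction_identical_within(c("A", "A", "A", "B")), 0.5)
  expect_equal(fraction_identical_overall(c("A", "A", "A", "B"),
                                          c("B", "C")), 2 / 7)
  expect_equal(enrichment_score(0.5, 2 / 7), 1.75)
  expect_equal(fraction_identical_overall("A", c("A", "B", "C")), 1 / 3)
})

test_that("degenerate inputs yield undefined flags, not zeros", {
  expect_true(is.na(fraction_identical_within("A")))
  expect_true(is.na(fraction_identical_overall(character(), character())))
  expect_true(is.na(fraction_identical_overall("A", character())))
  expect_true(is.na(enrichment_score(0.5, 0)))
  expect_equal(enrichment_score(0, 0.3), 0)
  expect_equal(enrichment_score(0.3, 0.3), 1)
})

test_that("fractions equal the brute-force all-pairs oracle", {
  set.seed(21)
  for (trial in 1:200) {
    pool <- sample(LETTERS[1:8], sample(3:60, 1), replace = TRUE)
    n_f <- sample(2:min(20, length(pool) - 1), 1)
    kin <- pool[seq_len(n_f)]
    kout <- pool[-seq_len(n_f)]
    expect_equal(fraction_identical_within(kin),
                 oracle_fraction_within(kin))
    expect_equal(fraction_identical_overall(kin, kout),
                 oracle_fraction_overall(kin, kout))
  }
  # empty outside set degenerates to the within fraction
  kin <- c("A", "A", "B")
  expect_equal(fraction_identical_overall(kin, character()),
               fraction_identical_within(kin))
})

test_that("an unmatched profile never increases F_pw", {
  set.seed(4)
  for (trial in 1:50) {
    kin <- sample(LETTERS[1:4], sample(2:10, 1), replace = TRUE)
    before <- fraction_identical_within(kin)
    after <- fraction_identical_within(c(kin, "zz_unique"))
    expect_lte(after, before)
  }
})

test_that("permutation p-values behave at the boundaries", {
  uniform_pool <- rep("P", 30)
  r <- permutation_pvalue(1, uniform_pool, 5, n_draws = 100, seed = 1)
  expect_equal(r$p_empirical, 1)          # every draw ties
  expect_false(r$p_floored)
  # planted coherence: 10 objects sharing a profile in a 200-object pool
  set.seed(8)
  pool <- c(rep("sig", 10), sample(paste0("p", 1:50), 190, replace = TRUE))
  obs_E <- enrichment_score(fraction_identical_within(pool[1:10]),
                            fraction_identical_overall(pool[1:10],
                                                       pool[-(1:10)]))
  r2 <- permutation_pvalue(obs_E, pool, 10, n_draws = 1000, seed = 2)
  expect_lt(r2$p_empirical, 0.05)
  # undefined observed E propagates as untestable
  r3 <- permutation_pvalue(NA_real_, pool, 10, n_draws = 10, seed = 1)
  expect_true(is.na(r3$p_empirical))
  expect_error(permutation_pvalue(1, pool, 500, n_draws = 10), "exceeds")
})

test_that("permutation draws are deterministic under a seed", {
  pool <- c(rep("a", 8), rep("b", 12), paste0("u", 1:20))
  r1 <- permutation_pvalue(2, pool, 6, n_draws = 500, seed = 33)
  r2 <- permutation_pvalue(2, pool, 6, n_draws = 500, seed = 33)
  expect_equal(r1, r2)
  r3 <- permutation_pvalue(2, pool, 6, n_draws = 500, seed = 34)
  expect_false(identical(r1$mean_E_r, r3$mean_E_r))
})

test_that("BH adjustment applies the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  set.seed(13)
  for (trial in 1:20) {
    p <- runif(sample(2:30, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, stats::p.adjust(p, "BH"))  # independent reference
    expect_true(all(adj >= p))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), adj[perm])
  }
  # NAs pass through without joining the family
  p <- c(0.01, NA, 0.04)
  expect_equal(bh_adjust(p), c(0.02, NA, 0.04))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("enrichment scan flags untestable pathways and sorts stably", {
  set.seed(30)
  prof <- random_profiles(40, 5, p = 0.4)
  mem <- list(big = rownames(prof)[1:8],
              tiny = rownames(prof)[9],
              other = rownames(prof)[10:15])
  sc <- enrichment_scan(mem, prof, n_draws = 200, seed = 6)
  expect_s3_class(sc, "enrichment_scan")
  expect_equal(nrow(sc), 3L)
  tiny <- sc[sc$pathway == "tiny", ]
  expect_false(tiny$testable)
  expect_true(is.na(tiny$p_adjusted))
  expect_equal(sc$n_f[sc$pathway == "big"], 8L)
  # single testable pathway: adjusted equals raw
  sc1 <- enrichment_scan(mem["big"], prof, n_draws = 100, seed = 6)
  expect_equal(sc1$p_adjusted, sc1$p_empirical)
})

test_that("null scan p-values are valid (super-uniform at 5 percent)", {
  # profiles assigned independently of membership: empirical p is a valid,
  # conservative test statistic, so P(p <= 0.05) must not exceed ~0.05
  set.seed(77)
  prof <- random_profiles(120, 30)
  keys <- sample(paste0("arch", 1:20), 120, replace = TRUE)
  prof <- do.call(rbind, lapply(keys, function(k) {
    set.seed(sum(utf8ToInt(k))); rbinom(30, 1, 0.5)
  }))
  rownames(prof) <- sprintf("O%03d", 1:120)
  mem <- lapply(1:40, function(i) sample(rownames(prof), 8))
  names(mem) <- sprintf("pw%02d", 1:40)
  sc <- enrichment_scan(mem, prof, n_draws = 400, seed = 5)
  frac <- mean(sc$p_empirical[sc$testable] <= 0.05)
  expect_lte(frac, 0.125)  # 0.05 + 3 binomial SE at n = 40
})

test_that("derived seeds are stable, order-free and within integer range", {
  expect_identical(derive_seed(17, "path_a"), derive_seed(17, "path_a"))
  expect_false(derive_seed(17, "path_a") == derive_seed(17, "path_b"))
  expect_false(derive_seed(17, "x") == derive_seed(18, "x"))
  expect_true(all(vapply(letters, function(ch)
    derive_seed(2147483647, strrep(ch, 50)), 0) < 2^31))
})
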