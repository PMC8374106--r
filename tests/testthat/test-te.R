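test_that("superfamily enrichment reproduces the published labels", {
  tab <- te_superfamily_table()
  for (sp in unique(tab$species)) {
    d <- tab[tab$species == sp, ]
    k <- round(d$n * d$proportion)
    # reconstruct the per-gene records behind the printed counts
    superfamily <- rep(d$superfamily, d$n)
    has_island <- unlist(mapply(function(n, k) rep(c(TRUE, FALSE), c(k, n - k)),
                                d$n, k, SIMPLIFY = FALSE))
    res <- superfamily_enrichment(superfamily, has_island)
    res <- res[match(d$superfamily, res$superfamily), ]
    expect_equal(res$label, d$label, info = sp)
    # pooled-mean identity: count-weighted proportions equal p0 exactly
    expect_equal(sum(res$n * res$proportion) / sum(res$n), res$p0[1])
  }
})

test_that("a superfamily at exactly the pooled proportion is NS", {
  superfamily <- rep(c("DTT", "RLC"), each = 100)
  has_island <- rep(rep(c(TRUE, FALSE), 2), c(30, 70, 30, 70))
  res <- superfamily_enrichment(superfamily, has_island)
  expect_equal(res$p0[1], 0.3)
  expect_true(all(res$p_value == 1))
  expect_true(all(res$label == "NS"))
})

test_that("the CV-equality statistic is zero for identical groups", {
  g <- rexp(50) + 1
  res <- feltz_miller_cv_test(list(g, g))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$df, 1)
  expect_error(feltz_miller_cv_test(list(g, -g)), "positive mean")
  expect_error(feltz_miller_cv_test(list(g, g[1])), "at least 2")
})

test_that("the CV-equality statistic is scale invariant", {
  set.seed(13)
  a <- rnorm(100, 10, 2)
  b <- rnorm(100, 5, 2)
  base <- feltz_miller_cv_test(list(a, b))
  scaled <- feltz_miller_cv_test(list(7 * a, 7 * b))
  expect_equal(base$statistic, scaled$statistic, tolerance = 1e-12)
  expect_gt(base$statistic, 0)
})

test_that("strongly different CVs are detected", {
  set.seed(14)
  hits <- 0
  for (r in 1:50) {
    a <- rnorm(200, 10, 2)   # CV 0.2
    b <- rnorm(200, 10, 8)   # CV 0.8
    if (feltz_miller_cv_test(list(a, b))$p_value < 0.001) hits <- hits + 1
  }
  expect_gte(hits, 48)
})

test_that("coincidence classification follows the lineage-specific rule", {
  res <- classify_coincidence(
    island_a = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
    island_b = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE),
    te_a = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE),
    te_b = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  cls <- res$records$class
  expect_equal(cls[1], "coincident")   # island in a, TE in a
  expect_equal(cls[2], "dissonant")    # island in a, TE in b
  expect_equal(cls[3], "excluded")     # island in both
  expect_equal(cls[4], "excluded")     # island in neither
  expect_equal(cls[5], "excluded")     # no TE in either
  expect_equal(cls[6], "dissonant")    # island in b, TE in a
  expect_equal(res$n_coincident, 1)
  expect_equal(res$n_dissonant, 2)
})

test_that("swapping the species pair preserves the classified total", {
  set.seed(15)
  n <- 400
  ia <- runif(n) < 0.4; ib <- runif(n) < 0.4
  ta <- runif(n) < 0.5; tb <- runif(n) < 0.5
  ab <- classify_coincidence(ia, ib, ta, tb)
  ba <- classify_coincidence(ib, ia, tb, ta)
  expect_equal(ab$n_coincident + ab$n_dissonant,
               ba$n_coincident + ba$n_dissonant)
  expect_equal(ab$n_coincident, ba$n_coincident)  # coincidence is pair-symmetric
  expect_equal(ab$statistic, ba$statistic)
})

test_that("an excess of coincident events is called significant", {
  # 80 coincident vs 20 dissonant, with superfamily breakdown
  ia <- rep(TRUE, 100); ib <- rep(FALSE, 100)
  ta <- rep(c(TRUE, FALSE), c(80, 20)); tb <- !ta
  sf <- rep(c("DTH", "RLC"), 50)
  res <- classify_coincidence(ia, ib, ta, tb, superfamily = sf)
  expect_equal(res$n_coincident, 80)
  expect_lt(res$p_value, 0.006)
  expect_equal(nrow(res$superfamily_table), 2)
})

test_that("BLAST summaries assign e-value 1 to hitless queries", {
  hits <- data.frame(query_id = c("w1", "w1", "w2"),
                     subject_id = "te", evalue = c(1e-10, 1e-3, 1e-45),
                     stringsAsFactors = FALSE)
  res <- blast_evalue_summary(hits, c("w1", "w2", "w3"))
  expect_equal(unname(res$best), c(1e-10, 1e-45, 1.0))
  expect_equal(res$fraction_below_1e5, 2 / 3)
  expect_equal(res$fraction_below_1e40, 1 / 3)
  expect_error(blast_evalue_summary(hits, "w1"), "unknown query")
  # all queries hitless
  res0 <- blast_evalue_summary(hits[0, ], c("a", "b"))
  expect_equal(res0$fraction_below_1e5, 0)
  expect_true(all(res0$best == 1.0))
})

test_that("control windows are sampled among non-islands, seeded", {
  len <- 30000L
  hot <- data.frame(start = c(7000L, 7100L), end = c(7100L, 7200L))
  m <- dense_chh(len, by = 10L, m = 1L, t = 20L, hot = hot, hot_m = 15L)
  g <- toy_genes(8000L, 12000L, "+")
  calls <- call_islands(m, g, toy_background(chh = 0.05))
  ctrl <- sample_control_windows(calls, seed = 5)
  expect_equal(nrow(ctrl), sum(calls$windows$is_island))
  isl_key <- with(calls$windows[calls$windows$is_island, ],
                  paste(chrom, start))
  expect_false(any(paste(ctrl$chrom, ctrl$start) %in% isl_key))
  expect_identical(ctrl, sample_control_windows(calls, seed = 5))
})

test_that("islands pinned to the TSS but loose in the TE have smaller TSS CV", {
  # islands planted at a fixed TSS offset but at variable TE-edge offsets
  set.seed(16)
  n <- 30
  len <- n * 20000L
  gene_starts <- seq(10000L, len - 4000L, by = 20000L)[1:n]
  g <- toy_genes(gene_starts, gene_starts + 3000L, "+")
  isl_start <- gene_starts - 800L        # fixed 800 bp upstream
  te_start <- isl_start - sample(200:1800, n, replace = TRUE)
  te_start[1] <- isl_start[1] + 50L      # one TE starting at an island center
  tes <- data.frame(chrom = "chr1", start = te_start,
                    end = isl_start + sample(300:1900, n, replace = TRUE) + 2000L,
                    superfamily = "DTT", stringsAsFactors = FALSE)
  hot <- data.frame(start = isl_start, end = isl_start + 100L)
  m <- dense_chh(len, by = 10L, m = 1L, t = 20L, hot = hot, hot_m = 15L)
  calls <- call_islands(m, g, toy_background(chh = 0.05))
  res <- island_te_distances(calls, tes, g)
  cv_tss <- res$cv$cv[res$cv$group == "dist_tss"]
  cv_te <- res$cv$cv[res$cv$group == "dist_te_edge"]
  expect_lt(cv_tss, cv_te)
  expect_lt(res$test$p_value, 0.01)
  # the island whose center sits exactly at a TE start has edge distance 0
  d1 <- res$distances[res$distances$center == isl_start[1] + 50L, ]
  expect_equal(d1$dist_te_edge, 0)
  expect_equal(d1$dist_tss, 750)
})
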