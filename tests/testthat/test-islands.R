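# Brute-force binomial upper tail, independent of the pbinom route.
tail_oracle <- function(m, n, p) {
  if (m <= 0) return(1)
  sum(choose(n, m:n) * p^(m:n) * (1 - p)^(n - (m:n)))
}

# Literal O(m^2) step-up formula for the BY adjustment.
by_oracle <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  q_sorted <- vapply(seq_len(m), function(i)
    min(1, min(p[o][i:m] * m * cm / (i:m))), numeric(1))
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

test_that("window test equals the exact binomial tail", {
  expect_equal(test_window(0, 10, 0.1), 1)
  expect_equal(test_window(10, 10, 0.5), 2^-10)
  expect_equal(test_window(20, 50, 0.10), tail_oracle(20, 50, 0.10))
  expect_equal(test_window(0, 0, 0.3), 1)  # empty window
  for (n in 1:20)
    for (m in c(0L, 1L, n %/% 2L, n))
      for (p0 in c(0.05, 0.3, 0.747))
        expect_equal(test_window(m, n, p0), tail_oracle(m, n, p0),
                     tolerance = 1e-12)
  expect_error(test_window(1, 2, 0), "p0")
  expect_error(test_window(1, 2, 1), "p0")
})

test_that("window test p-value is monotone in the methylated count", {
  for (n in c(5L, 17L)) {
    p <- test_window(0:n, rep(n, n + 1L), 0.2)
    expect_true(all(diff(p) <= 0))
  }
})

test_that("BY adjustment matches hand computations and the step-up oracle", {
  expect_equal(by_adjust(0.02), 0.02)
  expect_equal(by_adjust(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.01 * 4 * (25 / 12), 4))
  expect_equal(by_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(by_adjust(numeric(0)), numeric(0))
  set.seed(42)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(by_adjust(p), by_oracle(p), tolerance = 1e-12)
    expect_equal(by_adjust(p), p.adjust(p, "BY"), tolerance = 1e-12)
    # BY is uniformly more conservative than BH
    expect_true(all(by_adjust(p) >= p.adjust(p, "BH") - 1e-12))
  }
})

test_that("island calls obey the site-count, FDR and flank rules", {
  len <- 20000L
  hot <- data.frame(start = c(7000L, 900L), end = c(7100L, 1000L))
  m <- dense_chh(len, by = 10L, m = 1L, t = 20L, hot = hot, hot_m = 15L)
  # gene at 8000: 5' flank [6000,8000) holds the first hot window; the
  # second hot window [900,1000) sits 7000+ bp away -> never an island
  g <- toy_genes(8000L, 12000L, "+")
  calls <- call_islands(m, g, toy_background(chh = 0.05))
  w <- calls$windows
  isl <- w[w$is_island, ]
  expect_equal(nrow(isl), 1)
  expect_equal(isl$start, 7000L)
  far <- w[w$start == 900L, ]
  expect_lt(far$q_value, 0.01)     # significant ...
  expect_false(far$is_island)      # ... but outside every flank
})

test_that("a window with exactly five covered CHH sites is never tested", {
  # 5 sites in [0,100), 7 sites in [100,200), all highly methylated
  pos <- c(seq(0L, 40L, 10L), seq(100L, 160L, 10L))
  m <- toy_methylome(pos, rep(18L, length(pos)), rep(20L, length(pos)))
  g <- toy_genes(1000L, 2000L, "+")
  calls <- call_islands(m, g, toy_background(chh = 0.05))
  w <- calls$windows
  expect_false(w$tested[w$start == 0])
  expect_true(w$tested[w$start == 100])
  expect_true(is.na(w$p_value[w$start == 0]))
})

test_that("a window 2,050 bp upstream of the only TSS is not an island", {
  len <- 20000L
  # gene TSS at 3050; flank [1050,3050); hot window [900,1000) ends 2050 bp
  # upstream, hot window [1000,1100) overlaps the flank by 50 bp
  hot <- data.frame(start = c(900L, 1000L), end = c(1000L, 1100L))
  m <- dense_chh(len, by = 10L, m = 1L, t = 20L, hot = hot, hot_m = 15L)
  g <- toy_genes(3050L, 7050L, "+")
  calls <- call_islands(m, g, toy_background(chh = 0.05))
  w <- calls$windows
  expect_false(w$is_island[w$start == 900])
  expect_true(w$is_island[w$start == 1000])  # any-overlap rule
})

test_that("minus-strand genes find their 5' islands to their right", {
  len <- 20000L
  hot <- data.frame(start = c(8500L, 900L), end = c(8600L, 1000L))
  m <- dense_chh(len, by = 10L, m = 1L, t = 20L, hot = hot, hot_m = 15L)
  # minus-strand gene [4000,8000): TSS at 7999, 5' flank [8000,10000),
  # 3' flank [2000,4000)
  g <- toy_genes(4000L, 8000L, "-")
  calls <- call_islands(m, g, toy_background(chh = 0.05))
  st <- associate_genes(calls)
  expect_true(st$has_5p_island)
  expect_false(st$has_3p_island)
  expect_equal(st$nearest_island_distance, 8500 - 7999)
})

test_that("coverage filter needs depth above 2x over half the 5' region", {
  g <- toy_genes(2000L, 5000L, "+")
  mk <- function(n_deep) {
    depth <- c(rep(3L, n_deep), rep(2L, 100L - n_deep))
    toy_methylome(seq(0L, 1990L, length.out = 100L), 0L, depth)
  }
  expect_false(coverage_filter(g, mk(49))[["g1"]])
  expect_true(coverage_filter(g, mk(51))[["g1"]])
  all_zero <- toy_methylome(seq(0L, 1990L, 20L), 0L, 0L)
  expect_false(coverage_filter(g, all_zero)[["g1"]])
  # genes failing coverage get NA island status
  m <- dense_chh(20000L, m = 1L, t = 20L)
  calls <- call_islands(m, g, toy_background(chh = 0.05))
  st <- associate_genes(calls, coverage_ok = c(g1 = FALSE))
  expect_true(is.na(st$has_5p_island))
})

test_that("the empirical cutoff is a closed bound at 25%", {
  # two flank windows at levels 0.24 and 0.25
  pos <- c(seq(6000L, 6090L, 10L), seq(6100L, 6190L, 10L))
  m <- toy_methylome(pos, rep(c(24L, 25L), each = 10L), rep(100L, 20L))
  g <- toy_genes(8000L, 12000L, "+")
  calls <- empirical_cutoff_call(m, g, cutoff = 0.25)
  w <- calls$windows
  expect_false(w$is_island[w$start == 6000])
  expect_true(w$is_island[w$start == 6100])
  # an all-unmethylated methylome yields no islands
  m0 <- dense_chh(20000L, m = 0L, t = 20L)
  calls0 <- empirical_cutoff_call(m0, g)
  expect_equal(sum(calls0$windows$is_island), 0)
})

test_that("method agreement compares 5' status over a shared gene universe", {
  st <- function(ids, has) data.frame(gene_id = ids, coverage_ok = TRUE,
                                      has_5p_island = has,
                                      has_3p_island = FALSE,
                                      nearest_island_distance = NA_real_)
  a <- st(c("g1", "g2", "g3", "g4"), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(method_agreement(a, a), 1.0)
  b <- st(c("g1", "g2", "g3", "g4"), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(method_agreement(a, b), 0.0)
  expect_equal(method_agreement(a, st(c("g2", "g1", "g3", "g4"),
                                      c(TRUE, TRUE, FALSE, TRUE))), 0.75)
  expect_error(method_agreement(a, st("g9", TRUE)), "universe")
})

test_that("calling is invariant under chromosome relabeling and mirroring", {
  len <- 30000L
  hot <- data.frame(start = 7000L, end = 7200L)
  m <- dense_chh(len, by = 10L, m = 1L, t = 20L, hot = hot, hot_m = 15L)
  g <- toy_genes(8000L, 12000L, "+")
  base <- call_islands(m, g, toy_background(chh = 0.05))
  # relabel the chromosome
  m2 <- m; m2$chrom <- "scaffold_9"
  g2 <- g; g2$chrom <- "scaffold_9"
  alt <- call_islands(m2, gene_models(g2[, c("gene_id", "chrom", "start",
                                             "end", "strand")]),
                      toy_background(chh = 0.05))
  expect_equal(sum(alt$windows$is_island), sum(base$windows$is_island))
  expect_equal(alt$windows$start[alt$windows$is_island],
               base$windows$start[base$windows$is_island])
  # mirror coordinates and flip strand
  m3 <- m; m3$pos <- len - 1L - m$pos
  g3 <- toy_genes(len - 12000L, len - 8000L, "-")
  mir <- call_islands(m3, g3, toy_background(chh = 0.05))
  mstart <- sort(len - mir$windows$end[mir$windows$is_island])
  # mirrored site positions land on a shifted window lattice (sites at
  # multiples of 10 map to ...9), so compare the covered island spans
  expect_equal(length(mstart), sum(base$windows$is_island))
  expect_true(all(abs(mstart - sort(base$windows$start[base$windows$is_island])) < 10))
  st_m <- associate_genes(mir)
  expect_equal(st_m$has_5p_island, associate_genes(base)$has_5p_island)
})
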