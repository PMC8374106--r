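test_that("TE distance measures TSS to nearest repeat edge, 0 on overlap", {
  g <- toy_genes(10000L, 14000L, "+")
  reps <- data.frame(chrom = "chr1", start = c(8000L, 20000L),
                     end = c(8500L, 21000L),
                     superfamily = c("DTH", "RLG"), stringsAsFactors = FALSE)
  expect_equal(unname(te_distance(g, reps)), 1500)
  # overlapping repeat -> 0
  reps2 <- rbind(reps, data.frame(chrom = "chr1", start = 13000L,
                                  end = 15000L, superfamily = "DTT"))
  expect_equal(unname(te_distance(g, reps2)), 0)
  # no repeat on the scaffold -> missing
  g2 <- toy_genes(100L, 500L, "+", chrom = "scaffold_7")
  expect_true(is.na(te_distance(g2, reps)))
  # mirrored chromosome gives mirrored-equal distances
  len <- 30000L
  gm <- toy_genes(len - 14000L, len - 10000L, "-")
  rm_ <- data.frame(chrom = "chr1", start = len - rev(c(8000L, 20000L) + c(500L, 1000L)),
                    end = len - rev(c(8000L, 20000L)),
                    superfamily = c("RLG", "DTH"), stringsAsFactors = FALSE)
  # mirror symmetry holds up to the 1 bp half-open edge convention
  expect_lte(abs(unname(te_distance(gm, rm_)) - unname(te_distance(g, reps))), 1)
})

test_that("expression quartiles use log2 RPKM with quartile 0 for absences", {
  g <- toy_genes(seq(0, 90000, 10000), seq(1000, 91000, 10000),
                 gene_id = paste0("g", 1:10))
  expr <- data.frame(gene_id = paste0("g", 1:8), rpkm = 2^(1:8))
  q <- expression_quartiles(expr, g)
  # eight expressed genes with distinct values -> exactly two per quartile
  expect_equal(as.vector(table(q[1:8])), rep(2L, 4))
  expect_equal(unname(q[c("g9", "g10")]), c(0L, 0L))
  # rpkm = 0 is "not expressed" by default
  expr0 <- data.frame(gene_id = paste0("g", 1:8),
                      rpkm = c(0, 2^(2:8)))
  expect_equal(unname(expression_quartiles(expr0, g)["g1"]), 0L)
  # fully tied expressed set degenerates to quartile 1
  exprt <- data.frame(gene_id = paste0("g", 1:8), rpkm = rep(4, 8))
  expect_equal(unname(expression_quartiles(exprt, g)[1:8]), rep(1L, 8))
  expect_error(expression_quartiles(expr[1:3, ], g), "fewer than 4")
})

test_that("quartile sizes differ only by boundary ties", {
  set.seed(5)
  g <- toy_genes(seq(0, 99) * 5000L, seq(0, 99) * 5000L + 1000L,
                 gene_id = paste0("g", 1:100))
  expr <- data.frame(gene_id = paste0("g", 1:100),
                     rpkm = 2^rnorm(100, 3, 2))
  q <- expression_quartiles(expr, g)
  expect_true(max(table(q)) - min(table(q)) <= 1)
})

test_that("gbM classification tests exonic CG against the genome background", {
  # one gene, exons = span, 10 CG sites at 80/100 each vs p0 = 0.5
  g <- toy_genes(1000L, 2000L, "+")
  cg <- toy_methylome(seq(1000L, 1900L, 100L), 80L, 100L, context = "CG")
  bg <- toy_background(cg = 0.5, chg = 0.3, chh = 0.05)
  res <- gbm_classify(g, cg, bg)
  expect_equal(res$exonic_mcg, 0.8)
  expect_true(res$gbm_binary)
  # exact pooled tail: 800 of 1000 reads at p0 = 0.5
  expect_equal(res$q_cg, pbinom(799, 1000, 0.5, lower.tail = FALSE))
  # fully unmethylated exons -> not gbM
  cg0 <- toy_methylome(seq(1000L, 1900L, 100L), 0L, 100L, context = "CG")
  expect_false(gbm_classify(g, cg0, bg)$gbm_binary)
  # CG- and CHH-hypermethylated -> excluded by the classic definition
  both <- rbind(cg, toy_methylome(seq(1010L, 1910L, 100L), 60L, 100L,
                                  context = "CHH"))
  expect_false(gbm_classify(g, both, bg)$gbm_binary)
  expect_true(gbm_classify(g, both, bg, cg_only = TRUE)$gbm_binary)
  # no exonic CG coverage -> NA and excluded
  chh_only <- toy_methylome(1500L, 1L, 10L, context = "CHH")
  res_na <- gbm_classify(g, chh_only, bg)
  expect_true(is.na(res_na$exonic_mcg))
  expect_true(is.na(res_na$gbm_binary))
})

test_that("0-1 standardization spans the unit interval and is idempotent", {
  expect_equal(standardize01(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(standardize01(c(0, 1)), c(0, 1))
  expect_error(standardize01(c(5, 5, 5)), "distinct")
  x <- c(0.1, 0.7, NA, 1.3)
  s <- standardize01(x)
  expect_true(is.na(s[3]))
  expect_equal(standardize01(s), s)
})

test_that("gene length is the annotated span, with exon length secondary", {
  g <- gene_models(
    data.frame(gene_id = c("a", "b"), chrom = "chr1",
               start = c(1000L, 5000L), end = c(3500L, 7500L),
               strand = "+", stringsAsFactors = FALSE),
    data.frame(gene_id = c("a", "b", "b"),
               start = c(1000L, 5000L, 7000L),
               end = c(3500L, 5600L, 7500L), stringsAsFactors = FALSE))
  gl <- gene_length(g)
  expect_equal(gl$length, c(2500L, 2500L))     # equal spans
  expect_equal(gl$exon_length, c(2500L, 1100L))
})

test_that("planted gbM genes are recovered from a simulated methylome", {
  cfg <- sim_config(seed = 31, chrom_length = 6e5L, n_genes = 60L,
                    island_fraction = 0)
  sim <- simulate_species(cfg)
  bg <- genome_background(sim$methylome)
  res <- gbm_classify(sim$genes, sim$methylome, bg)
  truth <- sim$truth$genes$gbm_planted
  called <- res$gbm_binary %in% TRUE
  sens <- sum(called & truth) / sum(truth)
  fdr <- if (sum(called)) sum(called & !truth) / sum(called) else 0
  expect_gte(sens, 0.9)
  expect_lte(fdr, 0.1)
})

test_that("the assembled feature table lines up response and predictors", {
  cfg <- sim_config(seed = 8, chrom_length = 4e5L, n_genes = 40L)
  sim <- simulate_species(cfg)
  calls <- call_islands(sim$methylome, sim$genes)
  st <- associate_genes(calls)
  feats <- gene_features(sim$genes, st, sim$methylome, sim$repeats,
                         sim$expression, genome_background(sim$methylome))
  expect_equal(nrow(feats), 40)
  expect_equal(feats$gene_id, sim$genes$gene_id)
  expect_true(all(feats$expression_quartile[is.na(feats$rpkm)] == 0))
  expect_true(all(feats$te_distance >= 0, na.rm = TRUE))
  # genes with a planted TE have one within 2 kb + TE length
  planted <- sim$truth$genes$te_planted
  expect_true(all(feats$te_distance[planted] <= 1500, na.rm = TRUE))
})
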