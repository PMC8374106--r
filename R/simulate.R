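#' Simulation configuration
#'
#' Defines the study conditions a synthetic species is generated under. The
#' defaults emulate a grass methylome: CG/CHG/CHH backgrounds 0.60/0.40/0.05
#' (low genome-wide CHH), Poisson read depth of mean 10, beta-binomial
#' counts with concentration 50, islands planted as 100-300 bp tracts
#' starting 0-1500 bp upstream of the TSS with methylation elevated in all
#' three contexts (CHH 0.40; CG and CHG 0.2 above background), gbM genes
#' with exonic CG at 0.8 versus 0.05 in unmethylated gene bodies, and TEs
#' whose nearer edge falls within 2 kb upstream of a subset of genes.
#'
#' @param seed RNG seed (mandatory; all randomness flows from it).
#' @param n_chromosomes,chrom_length genome shape.
#' @param n_genes number of genes (non-overlapping, full 2 kb flanks).
#' @param gene_length_range,n_exons_range gene geometry.
#' @param coverage_mean Poisson mean read depth per cytosine.
#' @param background per-context genome background levels (named CG/CHG/CHH).
#' @param genic per-context levels inside gene bodies (non-gbM exonic CG
#'   included).
#' @param island_levels absolute per-context levels inside island tracts.
#' @param island_fraction fraction of genes given a 5' island tract.
#' @param island_offset_range uniform TSS-offset range (bp) of the tract.
#' @param island_length_range uniform tract length range (bp).
#' @param gbm_fraction,gbm_level fraction of gbM genes and their exonic CG
#'   level.
#' @param te_fraction fraction of genes with a planted upstream TE.
#' @param te_superfamily_probs named sampling weights over Wicker codes.
#' @param te_length_range,te_offset_range TE geometry (edge offset from TSS).
#' @param expressed_fraction fraction of genes present in the expression
#'   table (the rest emulate genes absent from RNA-seq, quartile 0).
#' @param log2_rpkm_mean,log2_rpkm_sd log2-normal expression model.
#' @param overdispersion beta-binomial concentration (larger = closer to
#'   binomial); `Inf` gives exact binomial counts.
#' @param n_species,rho,p_island,n_orthologs multi-species panel shape:
#'   species count, cross-species island correlation (Gaussian copula) and
#'   per-species marginal island probabilities.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_chromosomes = 1L, chrom_length = 2e6L,
                       n_genes = 200L,
                       gene_length_range = c(1000L, 4000L),
                       n_exons_range = c(1L, 3L),
                       coverage_mean = 10,
                       background = c(CG = 0.60, CHG = 0.40, CHH = 0.05),
                       genic = c(CG = 0.05, CHG = 0.02, CHH = 0.02),
                       island_levels = c(CG = 0.80, CHG = 0.60, CHH = 0.40),
                       island_fraction = 0.4,
                       island_offset_range = c(0L, 1500L),
                       island_length_range = c(100L, 300L),
                       gbm_fraction = 0.3, gbm_level = 0.8,
                       te_fraction = 0.5,
                       te_superfamily_probs = c(DTA = 1, DTC = 1, DTH = 2,
                                                DTM = 1, DTT = 2, RLC = 1,
                                                RLG = 1),
                       te_length_range = c(500L, 3000L),
                       te_offset_range = c(0L, 1500L),
                       expressed_fraction = 0.8,
                       log2_rpkm_mean = 3, log2_rpkm_sd = 2,
                       overdispersion = 50,
                       n_species = 1L, rho = 0, p_island = NULL,
                       n_orthologs = 2720L) {
  if (missing(seed)) stop("a seed is mandatory")
  levels <- c(background, genic, island_levels, gbm_level)
  stopifnot(all(levels > 0 & levels < 1),
            all(c(island_fraction, gbm_fraction, te_fraction,
                  expressed_fraction) >= 0),
            all(c(island_fraction, gbm_fraction, te_fraction,
                  expressed_fraction) <= 1),
            rho >= 0, rho <= 1, coverage_mean > 0)
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

# Cytosine positions, strands and contexts of a base vector (both strands).
derive_cytosines <- function(b) {
  L <- length(b)
  i <- which(b == "C")
  i <- i[i <= L - 2]
  ctx_p <- rep("CHH", length(i))
  ctx_p[b[i + 2] == "G"] <- "CHG"
  ctx_p[b[i + 1] == "G"] <- "CG"
  j <- which(b == "G")
  j <- j[j >= 3]
  ctx_m <- rep("CHH", length(j))
  ctx_m[b[j - 2] == "C"] <- "CHG"
  ctx_m[b[j - 1] == "C"] <- "CG"
  d <- data.frame(pos = c(i, j) - 1L,
                  strand = rep(c("+", "-"), c(length(i), length(j))),
                  context = c(ctx_p, ctx_m), stringsAsFactors = FALSE)
  d[order(d$pos), , drop = FALSE]
}

runif_int <- function(n, range) {
  as.integer(floor(runif(n, range[1], range[2] + 1)))
}

# Draw methylated counts given per-site true rates and depths.
draw_counts <- function(depth, rate, concentration) {
  p <- rate
  if (is.finite(concentration)) {
    v <- rate > 0 & rate < 1
    p[v] <- rbeta(sum(v), rate[v] * concentration,
                  (1 - rate[v]) * concentration)
  }
  rbinom(length(depth), depth, p)
}

#' Simulate one species' methylome and annotations
#'
#' Generates a random genome sequence, derives cytosine contexts from it on
#' both strands, places non-overlapping genes with full 2 kb flanks, plants
#' island tracts, gbM exons and upstream TEs per the configuration, draws
#' per-site read depths and beta-binomial methylated counts, and emits the
#' ground truth alongside.
#'
#' @param config a [sim_config()].
#' @return object of class `mchh_sim`: `methylome` (cytosine records),
#'   `genes` ([gene_models()]), `repeats`, `expression`, `chrom_lengths`,
#'   `truth` (per-gene planted labels, island tracts, per-site true rates),
#'   `config`.
#' @export
simulate_species <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_species_impl(config))
}

simulate_species_impl <- function(config, gene_labels = NULL) {
  flank <- 2000L
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  chrom_lengths <- setNames(rep(as.integer(config$chrom_length),
                                config$n_chromosomes), chroms)
  # assign genes round-robin to chromosomes
  gene_chrom <- chroms[(seq_len(config$n_genes) - 1L) %% config$n_chromosomes + 1L]
  gene_len <- runif_int(config$n_genes, config$gene_length_range)
  genes_list <- list()
  for (ch in chroms) {
    idx <- which(gene_chrom == ch)
    if (!length(idx)) next
    need <- gene_len[idx] + 2L * flank
    slack <- chrom_lengths[[ch]] - sum(need)
    if (slack < 0)
      stop("infeasible packing: ", length(idx), " genes do not fit on ", ch)
    gaps <- runif(length(idx) + 1L)
    gaps <- floor(gaps / sum(gaps) * slack)
    cur <- 0L
    st <- integer(length(idx))
    for (k in seq_along(idx)) {
      cur <- cur + gaps[k] + flank
      st[k] <- cur
      cur <- cur + gene_len[idx[k]] + flank
    }
    genes_list[[ch]] <- data.frame(i = idx, chrom = ch, start = st,
                                   end = st + gene_len[idx],
                                   stringsAsFactors = FALSE)
  }
  gdf <- do.call(rbind, genes_list)
  if (is.null(gdf))
    gdf <- data.frame(i = integer(), chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  gdf <- gdf[order(gdf$i), , drop = FALSE]
  gdf$gene_id <- sprintf("g%04d", gdf$i)
  gdf$strand <- sample(c("+", "-"), nrow(gdf), replace = TRUE)

  # exons: odd-numbered segments of a random partition of the span
  exons <- list()
  n_ex <- runif_int(nrow(gdf), config$n_exons_range)
  for (k in seq_len(nrow(gdf))) {
    L <- gdf$end[k] - gdf$start[k]
    ne <- min(n_ex[k], max(1L, L %/% 200L))
    if (ne == 1L) {
      exons[[k]] <- data.frame(gene_id = gdf$gene_id[k], start = gdf$start[k],
                               end = gdf$end[k], stringsAsFactors = FALSE)
    } else {
      cuts <- sort(sample.int(L - 1L, 2L * ne - 2L))
      bounds <- c(0L, cuts, L)
      s <- bounds[seq(1, 2 * ne - 1, by = 2)]
      e <- bounds[seq(2, 2 * ne, by = 2)]
      exons[[k]] <- data.frame(gene_id = gdf$gene_id[k],
                               start = gdf$start[k] + s,
                               end = gdf$start[k] + e, stringsAsFactors = FALSE)
    }
  }
  genes <- gene_models(gdf[, c("gene_id", "chrom", "start", "end", "strand")],
                       do.call(rbind, exons))

  # planted labels (may be supplied by the panel generator)
  n <- nrow(genes)
  if (is.null(gene_labels)) {
    gene_labels <- data.frame(
      gene_id = genes$gene_id,
      island_planted = runif(n) < config$island_fraction,
      gbm_planted = runif(n) < config$gbm_fraction,
      te_planted = runif(n) < config$te_fraction,
      expressed = runif(n) < config$expressed_fraction,
      stringsAsFactors = FALSE)
  }
  lab <- gene_labels

  # island tracts upstream of the TSS
  upstream_interval <- function(tss, strand, offset, len) {
    if (strand == "+") c(max(0L, tss - offset - len), max(0L, tss - offset))
    else c(tss + 1L + offset, tss + 1L + offset + len)
  }
  tracts <- NULL
  isl <- which(lab$island_planted)
  if (length(isl)) {
    off <- runif_int(length(isl), config$island_offset_range)
    tl <- runif_int(length(isl), config$island_length_range)
    tr <- t(vapply(seq_along(isl), function(k)
      upstream_interval(genes$tss[isl[k]], genes$strand[isl[k]], off[k], tl[k]),
      integer(2)))
    tracts <- data.frame(gene_id = genes$gene_id[isl],
                         chrom = genes$chrom[isl], start = tr[, 1],
                         end = tr[, 2], stringsAsFactors = FALSE)
    tracts <- tracts[tracts$end > tracts$start, , drop = FALSE]
  }

  # TEs with the nearer edge within the upstream window
  repeats <- NULL
  tei <- which(lab$te_planted)
  if (length(tei)) {
    off <- runif_int(length(tei), config$te_offset_range)
    tl <- runif_int(length(tei), config$te_length_range)
    tr <- t(vapply(seq_along(tei), function(k)
      upstream_interval(genes$tss[tei[k]], genes$strand[tei[k]], off[k], tl[k]),
      integer(2)))
    sf <- sample(names(config$te_superfamily_probs), length(tei),
                 replace = TRUE, prob = config$te_superfamily_probs)
    repeats <- data.frame(chrom = genes$chrom[tei], start = tr[, 1],
                          end = tr[, 2], superfamily = sf,
                          stringsAsFactors = FALSE)
    repeats <- repeats[repeats$end > repeats$start, , drop = FALSE]
  }
  if (is.null(repeats))
    repeats <- data.frame(chrom = character(), start = integer(),
                          end = integer(), superfamily = character(),
                          stringsAsFactors = FALSE)
  lab$te_superfamily <- rep(NA_character_, nrow(lab))
  lab$te_superfamily[tei] <- repeats$superfamily[seq_along(tei)]

  # genome sequence, cytosines, true rates, counts
  meth_list <- list()
  rate_list <- list()
  for (ch in chroms) {
    b <- sample(c("A", "C", "G", "T"), chrom_lengths[[ch]], replace = TRUE)
    cy <- derive_cytosines(b)
    rate <- unname(config$background[cy$context])
    # sites are sorted by pos: locate interval members by binary search
    site_range <- function(lo, hi) {
      a <- findInterval(lo - 0.5, cy$pos) + 1L
      z <- findInterval(hi - 0.5, cy$pos)
      if (a > z) integer(0) else a:z
    }
    set_rate <- function(rate, lo, hi, levels) {
      sel <- site_range(lo, hi)
      rate[sel] <- unname(levels[cy$context[sel]])
      rate
    }
    gsel <- which(genes$chrom == ch)
    for (k in gsel)
      rate <- set_rate(rate, genes$start[k], genes$end[k], config$genic)
    ex <- gene_exons(genes)
    gbm_genes <- lab$gene_id[lab$gbm_planted]
    exg <- ex[ex$gene_id %in% gbm_genes &
                ex$gene_id %in% genes$gene_id[gsel], , drop = FALSE]
    for (k in seq_len(nrow(exg))) {
      sel <- site_range(exg$start[k], exg$end[k])
      sel <- sel[cy$context[sel] == "CG"]
      rate[sel] <- config$gbm_level
    }
    if (!is.null(tracts)) {
      tch <- tracts[tracts$chrom == ch, , drop = FALSE]
      for (k in seq_len(nrow(tch)))
        rate <- set_rate(rate, tch$start[k], tch$end[k], config$island_levels)
    }
    depth <- rpois(nrow(cy), config$coverage_mean)
    m <- draw_counts(depth, rate, config$overdispersion)
    meth_list[[ch]] <- data.frame(chrom = ch, pos = cy$pos,
                                  strand = cy$strand, context = cy$context,
                                  n_meth = m, n_total = depth,
                                  stringsAsFactors = FALSE)
    rate_list[[ch]] <- rate
  }
  methylome <- do.call(rbind, meth_list)
  rownames(methylome) <- NULL

  # expression
  lab$rpkm <- rep(NA_real_, nrow(lab))
  ne <- sum(lab$expressed)
  lab$rpkm[lab$expressed] <- 2^rnorm(ne, config$log2_rpkm_mean,
                                     config$log2_rpkm_sd)
  expression <- data.frame(gene_id = lab$gene_id[lab$expressed],
                           rpkm = lab$rpkm[lab$expressed],
                           stringsAsFactors = FALSE)

  structure(list(methylome = methylome, genes = genes, repeats = repeats,
                 expression = expression, chrom_lengths = chrom_lengths,
                 truth = list(genes = lab, tracts = tracts,
                              site_rate = unlist(rate_list, use.names = FALSE)),
                 config = config),
            class = "mchh_sim")
}

#' @export
print.mchh_sim <- function(x, ...) {
  cat("Synthetic methylome:", sum(x$chrom_lengths), "bp,",
      nrow(x$methylome), "cytosines,", nrow(x$genes), "genes\n")
  cat("planted: ", sum(x$truth$genes$island_planted), " island genes, ",
      sum(x$truth$genes$gbm_planted), " gbM genes, ",
      sum(x$truth$genes$te_planted), " TE genes\n", sep = "")
  invisible(x)
}

#' Simulate a multi-species ortholog panel
#'
#' Ortholog island indicators are drawn per species with marginal
#' probabilities `p_island` and exchangeable cross-species correlation
#' `rho` by thresholding a Gaussian copula
#' (`z_s = sqrt(rho) u + sqrt(1-rho) e_s`). `rho = 0` is the fully random
#' regime; `rho > 0` produces detectable conservation. A random coalescent
#' tree over the species is emitted for downstream PGLS.
#'
#' @param config a [sim_config()] with `n_species >= 2`; `p_island` defaults
#'   to `island_fraction` for every species.
#' @return list with `panel` (an [ortholog_panel()]), `tree` (`phylo`),
#'   `orthologs` (id table), `truth` (the latent draw parameters).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"), config$n_species >= 2)
  p <- config$p_island
  if (is.null(p)) p <- rep(config$island_fraction, config$n_species)
  stopifnot(length(p) == config$n_species, all(p > 0 & p < 1))
  species <- paste0("sp", seq_len(config$n_species))
  with_seed(config$seed, {
    n <- config$n_orthologs
    u <- rnorm(n)
    island <- matrix(NA, n, config$n_species,
                     dimnames = list(sprintf("og%05d", seq_len(n)), species))
    for (s in seq_len(config$n_species)) {
      z <- sqrt(config$rho) * u + sqrt(1 - config$rho) * rnorm(n)
      island[, s] <- z < qnorm(p[s])
    }
    tree <- ape::rcoal(config$n_species, tip.label = species)
    orthologs <- data.frame(ortholog_id = rownames(island),
                            stringsAsFactors = FALSE)
    for (s in species)
      orthologs[[s]] <- paste0(s, "_", rownames(island))
    list(panel = ortholog_panel(island), tree = tree, orthologs = orthologs,
         truth = list(p_island = p, rho = config$rho, seed = config$seed))
  })
}

#' Simulate a gene-feature panel with planted predictor effects
#'
#' Draws the four genic predictors and a 5' island response from a logistic
#' model with known coefficients (on 0-1 standardized predictors), for
#' testing sign and importance recovery of the regression module.
#'
#' @param n_genes panel size.
#' @param beta named coefficients on the standardized scale; names among
#'   `intercept`, `te_distance`, `gene_length`, `expression`, `gbm`.
#' @param seed RNG seed.
#' @return `data.frame` with the predictors, the linear predictor and the
#'   binary `has_5p_island` response.
#' @export
simulate_feature_panel <- function(n_genes, beta = c(intercept = -0.5,
                                                     te_distance = -2,
                                                     gene_length = 1.5,
                                                     expression = 0.5,
                                                     gbm = -1.5),
                                   seed = 1L) {
  with_seed(seed, {
    d <- data.frame(
      te_distance = runif(n_genes),
      gene_length = runif(n_genes),
      expression = runif(n_genes),
      gbm = as.numeric(runif(n_genes) < 0.4))
    eta <- beta[["intercept"]] +
      as.matrix(d) %*% beta[c("te_distance", "gene_length", "expression", "gbm")]
    d$has_5p_island <- runif(n_genes) < stats::plogis(drop(eta))
    d$gene_id <- sprintf("g%05d", seq_len(n_genes))
    d
  })
}

#' Write a simulated species to disk in the pipeline's input formats
#'
#' Emits a Bismark-style cytosine report (1-based), a GFF3 gene annotation,
#' a TSV repeat annotation, an expression TSV and a truth TSV, all readable
#' by the package's own readers.
#'
#' @param sim a [simulate_species()] result.
#' @param dir output directory (created if needed).
#' @return named vector of the written paths, invisibly.
#' @export
write_species <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(report = file.path(dir, "cytosine_report.tsv"),
             genes = file.path(dir, "genes.gff3"),
             repeats = file.path(dir, "repeats.tsv"),
             expression = file.path(dir, "expression.tsv"),
             truth = file.path(dir, "truth.tsv"))
  m <- sim$methylome
  rep_df <- data.frame(m$chrom, m$pos + 1L, m$strand, m$n_meth,
                       m$n_total - m$n_meth, m$context)
  write.table(rep_df, paths["report"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  g <- sim$genes
  ex <- gene_exons(g)
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    lines <- c(lines,
               paste(g$chrom[i], "sim", "gene", g$start[i] + 1L, g$end[i], ".",
                     g$strand[i], ".", paste0("ID=", gid), sep = "\t"),
               paste(g$chrom[i], "sim", "mRNA", g$start[i] + 1L, g$end[i], ".",
                     g$strand[i], ".", paste0("ID=", gid, ".t1;Parent=", gid),
                     sep = "\t"))
    exg <- ex[ex$gene_id == gid, , drop = FALSE]
    for (j in seq_len(nrow(exg)))
      lines <- c(lines,
                 paste(g$chrom[i], "sim", "exon", exg$start[j] + 1L, exg$end[j],
                       ".", g$strand[i], ".",
                       paste0("ID=", gid, ".t1.e", j, ";Parent=", gid, ".t1"),
                       sep = "\t"))
  }
  writeLines(lines, paths["genes"])
  write.table(sim$repeats, paths["repeats"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$expression, paths["expression"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$truth$genes, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
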