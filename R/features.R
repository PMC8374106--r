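#' Distance from each gene's TSS to the nearest repeat edge
#'
#' For each gene, the minimum over repeats on its chromosome of the distance
#' from the TSS to the repeat's nearer edge (strand-indiscriminate). The
#' distance is 0 when a repeat overlaps the gene span. Genes on scaffolds
#' with no annotated repeat get `NA` and are dropped from TE analyses.
#'
#' @param genes a [gene_models()] object.
#' @param repeats repeat table from [read_repeat_annotation()].
#' @return named numeric vector (`gene_id` -> bp or `NA`).
#' @export
te_distance <- function(genes, repeats) {
  out <- rep(NA_real_, nrow(genes))
  for (i in seq_len(nrow(genes))) {
    r <- repeats[repeats$chrom == genes$chrom[i], , drop = FALSE]
    if (nrow(r) == 0) next
    overlap <- r$start < genes$end[i] & genes$start[i] < r$end
    if (any(overlap)) { out[i] <- 0; next }
    out[i] <- min(pmin(abs(genes$tss[i] - r$start), abs(genes$tss[i] - r$end)))
  }
  setNames(out, genes$gene_id)
}

#' Expression quartiles on log2 RPKM
#'
#' Expressed genes (present in the table with RPKM > 0) are split into
#' quartiles 1-4 at the 25/50/75% empirical quantiles of log2 RPKM
#' (linear-interpolation quantiles); values equal to a boundary fall in the
#' lower quartile, so a fully tied expressed set degenerates to quartile 1.
#' Genes absent from the table -- and, by default, genes present with RPKM
#' 0, where log2 is undefined -- are assigned quartile 0.
#'
#' @param expr expression table (`gene_id`, `rpkm`).
#' @param genes a [gene_models()] object (defines the gene universe).
#' @param zero_as_expressed treat RPKM = 0 rows as expressed (they then join
#'   quartile 1); default `FALSE`.
#' @return named integer vector (`gene_id` -> quartile 0..4).
#' @export
expression_quartiles <- function(expr, genes, zero_as_expressed = FALSE) {
  rpkm <- setNames(expr$rpkm, expr$gene_id)[genes$gene_id]
  expressed <- !is.na(rpkm) & (rpkm > 0 | (zero_as_expressed & rpkm >= 0))
  if (sum(expressed) < 4) stop("fewer than 4 expressed genes")
  lx <- log2(rpkm[expressed])
  br <- quantile(lx[is.finite(lx)], c(0.25, 0.5, 0.75), type = 7)
  q <- integer(nrow(genes))
  q[expressed] <- 1L + (lx > br[1]) + (lx > br[2]) + (lx > br[3])
  setNames(q, genes$gene_id)
}

#' Gene-body methylation classification
#'
#' Computes the weighted exonic CG level over the exons of each gene's
#' representative (longest) transcript and classifies genes as gene-body
#' methylated (gbM) by a one-sided binomial test of CG hypermethylation
#' against the genome-wide CG background, Benjamini-Hochberg corrected
#' across genes. Under the classic definition (default) a gbM gene must
#' additionally *not* be CHG- or CHH-hypermethylated at the same threshold;
#' set `cg_only = TRUE` for the CG-only variant. Genes with no covered
#' exonic CG site are `NA` throughout and excluded from gbM analyses.
#'
#' @param genes a [gene_models()] object.
#' @param methylome cytosine record `data.frame`.
#' @param background a [genome_background()] result.
#' @param alpha FDR threshold (default 0.05).
#' @param cg_only drop the CHG/CHH exclusion rule.
#' @param min_coverage minimum reads per site.
#' @return `data.frame` with columns `gene_id`, `exonic_mcg`, `gbm_binary`,
#'   `q_cg`, `q_chg`, `q_chh`.
#' @export
gbm_classify <- function(genes, methylome, background, alpha = 0.05,
                         cg_only = FALSE, min_coverage = 1L) {
  exons <- gene_exons(genes)
  meth <- methylome[methylome$n_total >= min_coverage, , drop = FALSE]
  sums <- matrix(0, nrow(genes), 6,
                 dimnames = list(genes$gene_id,
                                 c("m_CG", "t_CG", "m_CHG", "t_CHG",
                                   "m_CHH", "t_CHH")))
  for (i in seq_len(nrow(genes))) {
    ex <- exons[exons$gene_id == genes$gene_id[i], , drop = FALSE]
    ch <- meth[meth$chrom == genes$chrom[i], , drop = FALSE]
    if (nrow(ch) == 0 || nrow(ex) == 0) next
    inex <- rep(FALSE, nrow(ch))
    for (j in seq_len(nrow(ex)))
      inex <- inex | (ch$pos >= ex$start[j] & ch$pos < ex$end[j])
    sel <- ch[inex, , drop = FALSE]
    for (cx in CONTEXTS) {
      s <- sel[sel$context == cx, , drop = FALSE]
      sums[i, paste0("m_", cx)] <- sum(s$n_meth)
      sums[i, paste0("t_", cx)] <- sum(s$n_total)
    }
  }
  q <- matrix(NA_real_, nrow(genes), length(CONTEXTS),
              dimnames = list(NULL, CONTEXTS))
  for (cx in CONTEXTS) {
    p0 <- background_level(background, cx)
    t <- sums[, paste0("t_", cx)]
    p <- rep(NA_real_, nrow(genes))
    if (!is.na(p0) && any(t > 0))
      p[t > 0] <- test_window(sums[t > 0, paste0("m_", cx)], t[t > 0], p0)
    q[!is.na(p), cx] <- p.adjust(p[!is.na(p)], "BH")
  }
  exonic_mcg <- ifelse(sums[, "t_CG"] > 0, sums[, "m_CG"] / sums[, "t_CG"], NA)
  hyper <- q < alpha
  gbm <- hyper[, "CG"]
  if (!cg_only) {
    not_non_cg <- !(hyper[, "CHG"] %in% TRUE) & !(hyper[, "CHH"] %in% TRUE)
    gbm <- gbm & not_non_cg
  }
  gbm[is.na(exonic_mcg)] <- NA
  data.frame(gene_id = genes$gene_id, exonic_mcg = unname(exonic_mcg),
             gbm_binary = unname(gbm), q_cg = unname(q[, "CG"]),
             q_chg = unname(q[, "CHG"]), q_chh = unname(q[, "CHH"]),
             stringsAsFactors = FALSE)
}

#' Rescale a variable to the 0-1 interval
#'
#' `x -> (x - min) / (max - min)`; missing values propagate. Used to put the
#' logistic-regression predictors on a common scale.
#'
#' @param values numeric vector with at least two distinct finite values.
#' @return rescaled vector in `[0,1]`.
#' @export
standardize01 <- function(values) {
  v <- values[is.finite(values)]
  if (length(unique(v)) < 2)
    stop("standardize01 needs at least two distinct values")
  (values - min(v)) / (max(v) - min(v))
}

#' Gene lengths
#'
#' Primary length is the full annotated span (max minus min position,
#' introns included); the exon-summed length of the representative
#' transcript is returned alongside.
#'
#' @param genes a [gene_models()] object.
#' @return `data.frame` with columns `gene_id`, `length`, `exon_length`.
#' @export
gene_length <- function(genes) {
  exons <- gene_exons(genes)
  exlen <- tapply(exons$end - exons$start, exons$gene_id, sum)
  data.frame(gene_id = genes$gene_id,
             length = genes$end - genes$start,
             exon_length = as.integer(exlen[genes$gene_id]),
             stringsAsFactors = FALSE)
}

#' Assemble the per-gene feature table for island modelling
#'
#' One row per gene: the 5' island response plus the four genic predictors
#' (TE distance, span length, expression quartile and RPKM, gbM binary and
#' quantitative exonic mCG).
#'
#' @param genes a [gene_models()] object.
#' @param island_status [associate_genes()] output.
#' @param methylome cytosine record `data.frame`.
#' @param repeats repeat table.
#' @param expr expression table.
#' @param background [genome_background()] result.
#' @param gbm optional precomputed [gbm_classify()] table.
#' @return `data.frame` with columns `gene_id`, `has_5p_island`,
#'   `te_distance`, `gene_length`, `rpkm`, `expression_quartile`,
#'   `gbm_binary`, `exonic_mcg`.
#' @export
gene_features <- function(genes, island_status, methylome, repeats, expr,
                          background, gbm = NULL) {
  if (is.null(gbm)) gbm <- gbm_classify(genes, methylome, background)
  td <- te_distance(genes, repeats)
  gl <- gene_length(genes)
  quart <- expression_quartiles(expr, genes)
  rpkm <- setNames(expr$rpkm, expr$gene_id)[genes$gene_id]
  st <- island_status[match(genes$gene_id, island_status$gene_id), ]
  data.frame(gene_id = genes$gene_id,
             has_5p_island = st$has_5p_island,
             te_distance = unname(td),
             gene_length = gl$length,
             rpkm = unname(rpkm),
             expression_quartile = unname(quart),
             gbm_binary = gbm$gbm_binary[match(genes$gene_id, gbm$gene_id)],
             exonic_mcg = gbm$exonic_mcg[match(genes$gene_id, gbm$gene_id)],
             stringsAsFactors = FALSE)
}
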