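#' One-sided binomial window test for CHH hypermethylation
#'
#' Exact upper-tail probability `P[X >= n_meth]` for
#' `X ~ Binomial(n_total, p0)`, where `p0` is the genome-wide background
#' CHH level. A window with no reads gets p = 1.
#'
#' @param n_meth methylated read count(s).
#' @param n_total total read count(s).
#' @param p0 background methylation level, strictly inside (0,1).
#' @return vector of p-values.
#' @export
test_window <- function(n_meth, n_total, p0) {
  if (!is.numeric(p0) || length(p0) != 1 || p0 <= 0 || p0 >= 1)
    stop("background level p0 must lie strictly between 0 and 1")
  stopifnot(all(n_total >= 0), all(n_meth >= 0), all(n_meth <= n_total))
  p <- pbinom(n_meth - 1, n_total, p0, lower.tail = FALSE)
  p[n_total == 0] <- 1
  p
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up adjustment valid under arbitrary dependence:
#' `q_(i) = min_{j>=i} p_(j) * m * c(m) / j` capped at 1, with
#' `c(m) = sum_{k=1..m} 1/k`, returned in input order.
#'
#' @param p p-values in `[0,1]`.
#' @return adjusted q-values, same order as `p`.
#' @export
by_adjust <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1))
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  scaled <- p[o] * m * cm / seq_len(m)
  q <- rev(cummin(rev(scaled)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Strand-aware 2 kb flank intervals, one row per gene per side.
gene_flanks <- function(genes, flank = 2000L) {
  plus <- genes$strand == "+"
  f5 <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom, side = "5p",
                   start = ifelse(plus, genes$start - flank, genes$end),
                   end = ifelse(plus, genes$start, genes$end + flank),
                   anchor = genes$tss, stringsAsFactors = FALSE)
  f3 <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom, side = "3p",
                   start = ifelse(plus, genes$end, genes$start - flank),
                   end = ifelse(plus, genes$end + flank, genes$start),
                   anchor = genes$tts, stringsAsFactors = FALSE)
  fl <- rbind(f5, f3)
  fl$start <- pmax(fl$start, 0L)
  fl[fl$end > fl$start, , drop = FALSE]
}

# Window-flank overlap (any shared base). Returns data.frame window (row
# index into wdf), gene_id, side, distance (bp from anchor to the nearest
# window edge, 0 when the anchor lies inside the window).
overlap_flanks <- function(wdf, flanks, size) {
  if (nrow(flanks) == 0 || nrow(wdf) == 0)
    return(data.frame(window = integer(), gene_id = character(),
                      side = character(), distance = numeric(),
                      stringsAsFactors = FALSE))
  key <- paste(wdf$chrom, wdf$start %/% size)
  res <- vector("list", nrow(flanks))
  for (i in seq_len(nrow(flanks))) {
    w_lo <- flanks$start[i] %/% size
    w_hi <- (flanks$end[i] - 1L) %/% size
    hit <- match(paste(flanks$chrom[i], w_lo:w_hi), key)
    hit <- hit[!is.na(hit)]
    if (!length(hit)) next
    a <- flanks$anchor[i]
    d <- ifelse(a >= wdf$start[hit] & a < wdf$end[hit], 0,
                pmin(abs(a - wdf$start[hit]), abs(a - (wdf$end[hit] - 1L))))
    res[[i]] <- data.frame(window = hit, gene_id = flanks$gene_id[i],
                           side = flanks$side[i], distance = d,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(window = integer(), gene_id = character(),
                      side = character(), distance = numeric(),
                      stringsAsFactors = FALSE)
  out
}

build_call_object <- function(wdf, genes, mode, params) {
  flanks <- gene_flanks(genes, params$flank)
  assoc <- overlap_flanks(wdf, flanks, params$size)
  wdf$in_flank <- seq_len(nrow(wdf)) %in% assoc$window
  structure(list(windows = wdf, associations = assoc, genes = genes,
                 mode = mode, params = params),
            class = "mchh_islands")
}

#' Call mCHH islands by binomial test against the genome background
#'
#' Tiles each chromosome into non-overlapping `size`-bp windows, tests every
#' window containing more than `min_sites` covered CHH cytosines for CHH
#' hypermethylation against the genome-wide background with a one-sided
#' binomial test, adjusts the p-values with Benjamini-Yekutieli across all
#' tested windows genome-wide, and marks as islands the windows with
#' `q < alpha` that overlap (by any base) the strand-aware 5' or 3' `flank`
#' of at least one gene. Terminal partial windows are tested when they meet
#' the site rule.
#'
#' @param methylome cytosine record `data.frame` for the genome.
#' @param genes a [gene_models()] object.
#' @param background a [genome_background()] result, or `NULL` to compute it
#'   from `methylome`.
#' @param size window size (default 100 bp).
#' @param min_sites a window is tested only when it has strictly more than
#'   this many covered CHH cytosines (default 5).
#' @param flank gene flank width (default 2000 bp).
#' @param alpha FDR threshold on the adjusted q-value (default 0.01).
#' @param min_coverage minimum reads for a cytosine to count as covered.
#' @return an object of class `mchh_islands` with elements `windows` (one
#'   row per window with covered CHH sites: counts, `level`, `p_value`,
#'   `q_value`, `tested`, `in_flank`, `is_island`), `associations`
#'   (window-gene-side links with anchor distances), `genes`, `mode` and
#'   `params`.
#' @export
call_islands <- function(methylome, genes, background = NULL, size = 100L,
                         min_sites = 5L, flank = 2000L, alpha = 0.01,
                         min_coverage = 1L) {
  if (is.null(genes) || nrow(genes) == 0) stop("no genes supplied")
  if (is.null(background)) background <- genome_background(methylome, min_coverage)
  p0 <- background_level(background, "CHH")
  if (is.na(p0)) stop("CHH background undefined")
  wc <- window_counts(methylome, "CHH", size, min_coverage)
  wdf <- data.frame(chrom = wc$chrom, start = wc$win * size,
                    end = wc$win * size + size, n_chh_sites = wc$n_sites,
                    n_meth = wc$n_meth, n_total = wc$n_total,
                    level = ifelse(wc$n_total > 0, wc$n_meth / wc$n_total, NA),
                    stringsAsFactors = FALSE)
  wdf$tested <- wdf$n_chh_sites > min_sites
  if (!any(wdf$tested)) stop("no window passes the site-count rule")
  wdf$p_value <- NA_real_
  wdf$q_value <- NA_real_
  wdf$p_value[wdf$tested] <- test_window(wdf$n_meth[wdf$tested],
                                         wdf$n_total[wdf$tested], p0)
  wdf$q_value[wdf$tested] <- by_adjust(wdf$p_value[wdf$tested])
  params <- list(size = size, min_sites = min_sites, flank = flank,
                 alpha = alpha, min_coverage = min_coverage, p0 = p0)
  obj <- build_call_object(wdf, genes, "binomial", params)
  obj$windows$is_island <- obj$windows$tested &
    !is.na(obj$windows$q_value) & obj$windows$q_value < alpha &
    obj$windows$in_flank
  obj$background <- background
  obj
}

#' Call mCHH islands by the empirical 25% cutoff
#'
#' Alternative calling mode: a window is an island when its weighted CHH
#' level is at least `cutoff` (closed bound), it satisfies the site-count
#' rule and it overlaps a gene flank. No p-values are produced.
#'
#' @inheritParams call_islands
#' @param cutoff weighted-level threshold (default 0.25, inclusive).
#' @return an `mchh_islands` object (see [call_islands()]), `mode = "cutoff"`.
#' @export
empirical_cutoff_call <- function(methylome, genes, cutoff = 0.25,
                                  size = 100L, min_sites = 5L, flank = 2000L,
                                  min_coverage = 1L) {
  if (is.null(genes) || nrow(genes) == 0) stop("no genes supplied")
  wc <- window_counts(methylome, "CHH", size, min_coverage)
  wdf <- data.frame(chrom = wc$chrom, start = wc$win * size,
                    end = wc$win * size + size, n_chh_sites = wc$n_sites,
                    n_meth = wc$n_meth, n_total = wc$n_total,
                    level = ifelse(wc$n_total > 0, wc$n_meth / wc$n_total, NA),
                    stringsAsFactors = FALSE)
  wdf$tested <- wdf$n_chh_sites > min_sites
  if (!any(wdf$tested)) stop("no window passes the site-count rule")
  wdf$p_value <- NA_real_
  wdf$q_value <- NA_real_
  params <- list(size = size, min_sites = min_sites, flank = flank,
                 cutoff = cutoff, min_coverage = min_coverage)
  obj <- build_call_object(wdf, genes, "cutoff", params)
  obj$windows$is_island <- obj$windows$tested & !is.na(obj$windows$level) &
    obj$windows$level >= cutoff & obj$windows$in_flank
  obj
}

#' @export
print.mchh_islands <- function(x, ...) {
  cat("mCHH island calls (", x$mode, " mode)\n", sep = "")
  cat("  windows with covered CHH sites:", nrow(x$windows), "\n")
  cat("  tested windows:", sum(x$windows$tested), "\n")
  cat("  island windows:", sum(x$windows$is_island), "\n")
  cat("  genes:", nrow(x$genes), "\n")
  invisible(x)
}

#' @export
summary.mchh_islands <- function(object, ...) {
  st <- associate_genes(object)
  cat("mCHH island calls (", object$mode, " mode)\n", sep = "")
  if (object$mode == "binomial")
    cat("  CHH background p0:", signif(object$params$p0, 4), "\n")
  cat("  island windows:", sum(object$windows$is_island), "of",
      sum(object$windows$tested), "tested\n")
  cat("  genes with a 5' island:", sum(st$has_5p_island, na.rm = TRUE),
      "/", nrow(st), "\n")
  cat("  genes with a 3' island:", sum(st$has_3p_island, na.rm = TRUE),
      "/", nrow(st), "\n")
  med <- stats::median(object$windows$level[object$windows$is_island])
  cat("  median island mCHH level:", signif(med, 4), "\n")
  invisible(st)
}

#' Near-gene coverage filter
#'
#' A gene passes when, among CHH-context cytosines in its strand-aware 5'
#' `flank`, the fraction with read depth strictly greater than `depth` is at
#' least `frac`. Genes with no CHH site in the flank fail.
#'
#' @param genes a [gene_models()] object.
#' @param methylome cytosine record `data.frame`.
#' @param flank 5' region width (default 2000 bp).
#' @param depth depth that must be exceeded (default 2, i.e. >2x).
#' @param frac minimum passing fraction (default 0.5).
#' @return named logical vector (`gene_id` -> coverage_ok).
#' @export
coverage_filter <- function(genes, methylome, flank = 2000L, depth = 2L,
                            frac = 0.5) {
  chh <- methylome[methylome$context == "CHH", , drop = FALSE]
  ok <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    if (genes$strand[i] == "+") {
      lo <- genes$start[i] - flank; hi <- genes$start[i]
    } else {
      lo <- genes$end[i]; hi <- genes$end[i] + flank
    }
    sel <- chh$chrom == genes$chrom[i] & chh$pos >= lo & chh$pos < hi
    n <- sum(sel)
    ok[i] <- n > 0 && mean(chh$n_total[sel] > depth) >= frac
  }
  setNames(ok, genes$gene_id)
}

#' Per-gene island status
#'
#' A gene has a 5' (3') island when at least one island window overlaps its
#' strand-aware 2 kb upstream (downstream) flank. Genes failing the coverage
#' filter get `NA` status and are excluded from downstream tallies.
#'
#' @param calls an `mchh_islands` object.
#' @param coverage_ok optional named logical vector from
#'   [coverage_filter()]; genes absent or `FALSE` are marked not covered.
#'   Default: all genes pass.
#' @return `data.frame` with columns `gene_id`, `coverage_ok`,
#'   `has_5p_island`, `has_3p_island`, `nearest_island_distance` (bp from
#'   the TSS to the nearest 5' island window edge, `NA` when none).
#' @export
associate_genes <- function(calls, coverage_ok = NULL) {
  genes <- calls$genes
  if (is.null(coverage_ok))
    coverage_ok <- setNames(rep(TRUE, nrow(genes)), genes$gene_id)
  cov <- coverage_ok[genes$gene_id]
  cov[is.na(cov)] <- FALSE
  assoc <- calls$associations
  isl <- assoc[calls$windows$is_island[assoc$window], , drop = FALSE]
  has5 <- genes$gene_id %in% isl$gene_id[isl$side == "5p"]
  has3 <- genes$gene_id %in% isl$gene_id[isl$side == "3p"]
  d5 <- isl[isl$side == "5p", , drop = FALSE]
  nearest <- tapply(d5$distance, d5$gene_id, min)
  out <- data.frame(gene_id = genes$gene_id, coverage_ok = unname(cov),
                    has_5p_island = has5, has_3p_island = has3,
                    nearest_island_distance =
                      as.numeric(nearest[genes$gene_id]),
                    stringsAsFactors = FALSE)
  out$has_5p_island[!out$coverage_ok] <- NA
  out$has_3p_island[!out$coverage_ok] <- NA
  rownames(out) <- NULL
  out
}

#' Agreement between two island-calling modes
#'
#' Fraction of genes with identical 5' island status under two calling
#' modes, over the genes with defined status in both.
#'
#' @param status_a,status_b [associate_genes()] results on the same gene
#'   universe.
#' @return fraction in `[0,1]`.
#' @export
method_agreement <- function(status_a, status_b) {
  if (!setequal(status_a$gene_id, status_b$gene_id))
    stop("the two status tables cover different gene universes")
  b <- status_b[match(status_a$gene_id, status_b$gene_id), ]
  ok <- !is.na(status_a$has_5p_island) & !is.na(b$has_5p_island)
  if (!any(ok)) stop("no gene has defined status in both modes")
  mean(status_a$has_5p_island[ok] == b$has_5p_island[ok])
}
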