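#' Weighted methylation level of a set of cytosines
#'
#' The weighted level of a region is the summed methylated read count
#' divided by the summed total read count over the region's cytosines of one
#' context. A region with zero total reads has an undefined level (flagged,
#' never reported as 0/0).
#'
#' @param records cytosine record `data.frame`.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param min_coverage drop sites with `n_total` below this before pooling.
#' @return a list with fields `context`, `level`, `n_sites`,
#'   `n_meth_reads`, `n_total_reads`, `defined`.
#' @export
weighted_level <- function(records, context = "CHH", min_coverage = 1L) {
  stopifnot(context %in% CONTEXTS)
  r <- records[records$context == context & records$n_total >= min_coverage, ,
               drop = FALSE]
  tot <- sum(r$n_total)
  list(context = context,
       level = if (tot > 0) sum(r$n_meth) / tot else NA_real_,
       n_sites = nrow(r), n_meth_reads = sum(r$n_meth), n_total_reads = tot,
       defined = tot > 0)
}

#' Per-site methylation calls by binomial test
#'
#' Each covered cytosine is called methylated when the one-sided binomial
#' tail probability of its methylated count under the bisulfite
#' non-conversion (error) rate falls below `alpha` after Benjamini-Hochberg
#' adjustment across the sites tested. Sites with fewer than two reads get
#' no call.
#'
#' @param records cytosine record `data.frame`.
#' @param error_rate bisulfite non-conversion rate in (0,1); must be
#'   supplied by the user (it is a property of the experiment).
#' @param alpha significance level after adjustment (default 0.05).
#' @param adjust multiple-testing method passed to [stats::p.adjust()]
#'   (default `"BH"`).
#' @return character vector (`"methylated"`, `"unmethylated"`, `"no_call"`)
#'   aligned with the rows of `records`.
#' @export
call_site_methylation <- function(records, error_rate, alpha = 0.05,
                                  adjust = "BH") {
  if (!is.numeric(error_rate) || error_rate <= 0 || error_rate >= 1)
    stop("error_rate must lie strictly between 0 and 1")
  call <- rep("no_call", nrow(records))
  testable <- records$n_total >= 2
  if (any(testable)) {
    p <- pbinom(records$n_meth[testable] - 1L, records$n_total[testable],
                error_rate, lower.tail = FALSE)
    q <- p.adjust(p, method = adjust)
    call[testable] <- ifelse(q < alpha, "methylated", "unmethylated")
  }
  call
}

#' Genome-wide background methylation levels
#'
#' Weighted level per context over every covered cytosine in the methylome;
#' the CHH value is the null rate of the island binomial test.
#'
#' @param methylome cytosine record `data.frame` for the full genome.
#' @param min_coverage minimum reads for a site to contribute (default 1).
#' @return a `methylation_background` object: `data.frame` with one row per
#'   context and columns `context`, `level`, `n_sites`, `n_meth_reads`,
#'   `n_total_reads`.
#' @export
genome_background <- function(methylome, min_coverage = 1L) {
  rows <- lapply(CONTEXTS, function(cx) {
    wl <- weighted_level(methylome, cx, min_coverage)
    if (!wl$defined)
      warning("no covered ", cx, " sites: background undefined for this context")
    data.frame(context = cx, level = wl$level, n_sites = wl$n_sites,
               n_meth_reads = wl$n_meth_reads, n_total_reads = wl$n_total_reads,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("methylation_background", "data.frame"))
}

#' Extract one context's background level
#' @param background a [genome_background()] result.
#' @param context context name.
#' @return numeric level (possibly `NA`).
#' @export
background_level <- function(background, context = "CHH") {
  background$level[match(context, background$context)]
}

#' Tile chromosomes into non-overlapping windows
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param size window size in bp (default 100).
#' @return `data.frame` with columns `chrom`, `start`, `end`, `partial`
#'   (TRUE for a terminal window shorter than `size`).
#' @export
tile_windows <- function(chrom_lengths, size = 100L) {
  stopifnot(size > 0)
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    if (len <= 0) return(NULL)
    starts <- seq.int(0L, len - 1L, by = size)
    ends <- pmin(starts + size, len)
    data.frame(chrom = ch, start = as.integer(starts), end = as.integer(ends),
               partial = ends - starts < size, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      partial = logical(), stringsAsFactors = FALSE)
  out
}

# Per-window per-context count sums for one context, keyed by chrom and
# window index. Returns a data.frame chrom, win, n_sites, n_meth, n_total.
window_counts <- function(methylome, context, size = 100L, min_coverage = 1L) {
  r <- methylome[methylome$context == context &
                   methylome$n_total >= min_coverage, , drop = FALSE]
  if (nrow(r) == 0)
    return(data.frame(chrom = character(), win = integer(), n_sites = integer(),
                      n_meth = integer(), n_total = integer(),
                      stringsAsFactors = FALSE))
  win <- r$pos %/% size
  key <- paste(r$chrom, win, sep = "\r")
  sums <- rowsum(cbind(sites = 1L, m = r$n_meth, t = r$n_total), key)
  parts <- strsplit(rownames(sums), "\r", fixed = TRUE)
  data.frame(chrom = vapply(parts, `[`, "", 1L),
             win = as.integer(vapply(parts, `[`, "", 2L)),
             n_sites = as.integer(sums[, "sites"]),
             n_meth = as.integer(sums[, "m"]),
             n_total = as.integer(sums[, "t"]), stringsAsFactors = FALSE)
}

# Map positions onto the 5'->3' gene axis used by metaprofiles: a in
# [0, flank) upstream, [flank, flank+L) body, [flank+L, flank+2*flank) down.
gene_axis_position <- function(pos, start, end, strand, flank) {
  if (strand == "+") pos - (start - flank) else (end - 1L + flank) - pos
}

#' Metagene methylation profile
#'
#' Averages weighted methylation per context over 10 upstream 200 bp bins,
#' 20 proportional gene-body bins and 10 downstream 200 bp bins (40 bins, 5'
#' to 3'; minus-strand genes are mirrored). Genes shorter than `body_bins`
#' bases, or whose flanks run off the chromosome (when `chrom_lengths` is
#' given), are excluded. A gene contributes to a bin's average only where it
#' has covered sites.
#'
#' @param genes a [gene_models()] object.
#' @param methylome cytosine record `data.frame`.
#' @param flank flank width in bp (default 2000).
#' @param flank_bin flank bin width in bp (default 200).
#' @param body_bins number of gene-body bins (default 20).
#' @param contexts contexts to profile.
#' @param chrom_lengths optional named lengths for flank checks.
#' @param min_coverage minimum site coverage.
#' @return `data.frame` with columns `bin` (1..40), `region`, `context`,
#'   `mean_level`, `n_genes`.
#' @export
metaprofile <- function(genes, methylome, flank = 2000L, flank_bin = 200L,
                        body_bins = 20L, contexts = CONTEXTS,
                        chrom_lengths = NULL, min_coverage = 1L) {
  n_flank_bins <- flank %/% flank_bin
  keep <- (genes$end - genes$start) >= body_bins
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[genes$chrom]
    keep <- keep & genes$start - flank >= 0 & genes$end + flank <= len
  } else {
    keep <- keep & genes$start - flank >= 0
  }
  g <- genes[keep, , drop = FALSE]
  if (nrow(g) == 0) stop("no genes qualify for the metaprofile")
  n_bins <- 2L * n_flank_bins + body_bins
  meth <- methylome[methylome$n_total >= min_coverage, , drop = FALSE]
  meth <- meth[order(meth$chrom, meth$pos), , drop = FALSE]
  out <- list()
  for (cx in contexts) {
    mc <- meth[meth$context == cx, , drop = FALSE]
    sum_m <- matrix(0, nrow(g), n_bins)
    sum_t <- matrix(0, nrow(g), n_bins)
    for (i in seq_len(nrow(g))) {
      ch <- mc[mc$chrom == g$chrom[i], , drop = FALSE]
      if (nrow(ch) == 0) next
      lo <- g$start[i] - flank
      hi <- g$end[i] + flank
      sel <- ch[ch$pos >= lo & ch$pos < hi, , drop = FALSE]
      if (nrow(sel) == 0) next
      a <- gene_axis_position(sel$pos, g$start[i], g$end[i], g$strand[i], flank)
      L <- g$end[i] - g$start[i]
      bin <- integer(length(a))
      up <- a < flank
      body <- a >= flank & a < flank + L
      dn <- a >= flank + L
      bin[up] <- a[up] %/% flank_bin + 1L
      bin[body] <- n_flank_bins +
        pmin(body_bins, floor((a[body] - flank) / L * body_bins) + 1L)
      bin[dn] <- n_flank_bins + body_bins +
        pmin(n_flank_bins, (a[dn] - flank - L) %/% flank_bin + 1L)
      sum_m[i, ] <- sum_m[i, ] + rowsum_vec(sel$n_meth, bin, n_bins)
      sum_t[i, ] <- sum_t[i, ] + rowsum_vec(sel$n_total, bin, n_bins)
    }
    lev <- sum_m / sum_t
    lev[sum_t == 0] <- NA
    region <- c(rep("upstream", n_flank_bins), rep("body", body_bins),
                rep("downstream", n_flank_bins))
    out[[cx]] <- data.frame(bin = seq_len(n_bins), region = region,
                            context = cx,
                            mean_level = colMeans(lev, na.rm = TRUE),
                            n_genes = colSums(!is.na(lev)),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

rowsum_vec <- function(x, bin, n_bins) {
  v <- numeric(n_bins)
  s <- rowsum(x, bin)
  v[as.integer(rownames(s))] <- s[, 1]
  v
}

#' Near-gene CHH enrichment ratio
#'
#' Mean weighted mCHH in the 1 kb regions immediately upstream of gene TSSs,
#' divided by the mean weighted mCHH of an equal number of 1 kb windows
#' sampled uniformly (without replacement, seeded) from the genome-wide
#' tiling, keeping only windows with at least one covered CHH site.
#'
#' @param genes a [gene_models()] object.
#' @param methylome cytosine record `data.frame`.
#' @param chrom_lengths named chromosome lengths.
#' @param region upstream region width (default 1000).
#' @param seed RNG seed for the random window draw.
#' @param min_coverage minimum site coverage.
#' @return list with `ratio`, `upstream_mean`, `random_mean`, `n_genes`,
#'   `n_random`, `seed`.
#' @export
near_gene_enrichment <- function(genes, methylome, chrom_lengths,
                                 region = 1000L, seed = 1L,
                                 min_coverage = 1L) {
  len <- chrom_lengths[genes$chrom]
  ok <- genes$start - region >= 0 & genes$end + region <= len
  g <- genes[ok, , drop = FALSE]
  if (nrow(g) == 0) stop("no gene with a full upstream region")
  meth <- methylome[methylome$context == "CHH" &
                      methylome$n_total >= min_coverage, , drop = FALSE]
  meth <- meth[order(meth$chrom, meth$pos), , drop = FALSE]
  up_level <- vapply(seq_len(nrow(g)), function(i) {
    if (g$strand[i] == "+") {
      lo <- g$start[i] - region; hi <- g$start[i]
    } else {
      lo <- g$end[i]; hi <- g$end[i] + region
    }
    sel <- meth$chrom == g$chrom[i] & meth$pos >= lo & meth$pos < hi
    t <- sum(meth$n_total[sel])
    if (t > 0) sum(meth$n_meth[sel]) / t else NA_real_
  }, numeric(1))
  up_mean <- mean(up_level, na.rm = TRUE)
  tiles <- tile_windows(chrom_lengths, size = region)
  tiles <- tiles[!tiles$partial, , drop = FALSE]
  wc <- window_counts(meth, "CHH", size = region, min_coverage = min_coverage)
  key_t <- paste(tiles$chrom, tiles$start %/% region)
  key_w <- paste(wc$chrom, wc$win)
  covered <- tiles[key_t %in% key_w, , drop = FALSE]
  n_draw <- min(sum(!is.na(up_level)), nrow(covered))
  if (n_draw == 0) stop("no covered random windows to sample")
  res <- with_seed(seed, {
    idx <- sample.int(nrow(covered), n_draw)
    covered[idx, , drop = FALSE]
  })
  m <- wc[match(paste(res$chrom, res$start %/% region), key_w), , drop = FALSE]
  rand_level <- m$n_meth / m$n_total
  rand_mean <- mean(rand_level)
  if (!is.finite(rand_mean) || rand_mean == 0)
    stop("random-window mean methylation is zero; enrichment undefined")
  list(ratio = up_mean / rand_mean, upstream_mean = up_mean,
       random_mean = rand_mean, n_genes = sum(!is.na(up_level)),
       n_random = n_draw, seed = seed)
}

#' Methylation profile centered on 5' island windows
#'
#' For each island-associated gene, takes the significant window nearest the
#' TSS on the 5' side, and averages weighted methylation per context in
#' `bin`-bp windows from `-span` to `+span` around that window's center.
#'
#' @param calls an [call_islands()] (or [empirical_cutoff_call()]) result.
#' @param methylome cytosine record `data.frame`.
#' @param span half-width of the profiled region (default 2000).
#' @param bin bin width (default 100).
#' @param contexts contexts to profile.
#' @param min_coverage minimum site coverage.
#' @return `data.frame` with columns `offset` (bin center relative to the
#'   island center), `context`, `mean_level`, `n_islands`.
#' @export
island_centered_profile <- function(calls, methylome, span = 2000L,
                                    bin = 100L, contexts = CONTEXTS,
                                    min_coverage = 1L) {
  assoc <- calls$associations
  assoc <- assoc[assoc$side == "5p" &
                   calls$windows$is_island[assoc$window], , drop = FALSE]
  if (nrow(assoc) == 0) stop("no 5' islands to center on")
  w <- calls$windows
  assoc$center <- (w$start[assoc$window] + w$end[assoc$window]) %/% 2L
  assoc$chrom <- w$chrom[assoc$window]
  # nearest significant window per gene
  assoc <- assoc[order(assoc$gene_id, assoc$distance), , drop = FALSE]
  assoc <- assoc[!duplicated(assoc$gene_id), , drop = FALSE]
  n_bins <- 2L * (span %/% bin)
  meth <- methylome[methylome$n_total >= min_coverage, , drop = FALSE]
  out <- list()
  for (cx in contexts) {
    mc <- meth[meth$context == cx, , drop = FALSE]
    sum_m <- matrix(0, nrow(assoc), n_bins)
    sum_t <- matrix(0, nrow(assoc), n_bins)
    for (i in seq_len(nrow(assoc))) {
      lo <- assoc$center[i] - span
      sel <- mc[mc$chrom == assoc$chrom[i] & mc$pos >= lo &
                  mc$pos < assoc$center[i] + span, , drop = FALSE]
      if (nrow(sel) == 0) next
      b <- (sel$pos - lo) %/% bin + 1L
      sum_m[i, ] <- rowsum_vec(sel$n_meth, b, n_bins)
      sum_t[i, ] <- rowsum_vec(sel$n_total, b, n_bins)
    }
    lev <- sum_m / sum_t
    lev[sum_t == 0] <- NA
    out[[cx]] <- data.frame(
      offset = seq_len(n_bins) * bin - span - bin %/% 2L, context = cx,
      mean_level = colMeans(lev, na.rm = TRUE),
      n_islands = colSums(!is.na(lev)), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Evaluate `expr` under a local, seeded RNG state, restoring the caller's.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
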