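# Small hand-built fixtures shared across test files.

toy_methylome <- function(pos, n_meth, n_total, context = "CHH",
                          chrom = "chr1", strand = "+") {
  cytosine_records(chrom = rep(chrom, length.out = length(pos)), pos = pos,
                   strand = rep(strand, length.out = length(pos)),
                   context = rep(context, length.out = length(pos)),
                   n_meth = n_meth, n_total = n_total)
}

toy_background <- function(cg = 0.5, chg = 0.3, chh = 0.05) {
  structure(data.frame(context = c("CG", "CHG", "CHH"),
                       level = c(cg, chg, chh), n_sites = 1000L,
                       n_meth_reads = NA_integer_, n_total_reads = NA_integer_,
                       stringsAsFactors = FALSE),
            class = c("methylation_background", "data.frame"))
}

toy_genes <- function(start, end, strand = "+", chrom = "chr1",
                      gene_id = NULL) {
  n <- length(start)
  if (is.null(gene_id)) gene_id <- paste0("g", seq_len(n))
  gene_models(data.frame(gene_id = gene_id,
                         chrom = rep(chrom, length.out = n),
                         start = start, end = end,
                         strand = rep(strand, length.out = n),
                         stringsAsFactors = FALSE))
}

# A dense CHH methylome: one site every `by` bp with constant counts,
# optionally overridden on given intervals.
dense_chh <- function(len, by = 10L, m = 2L, t = 40L, chrom = "chr1",
                      hot = NULL, hot_m = 20L) {
  pos <- seq(0L, len - 1L, by = by)
  n_meth <- rep(m, length(pos))
  if (!is.null(hot)) {
    for (k in seq_len(nrow(hot))) {
      sel <- pos >= hot$start[k] & pos < hot$end[k]
      n_meth[sel] <- hot_m
    }
  }
  toy_methylome(pos, n_meth, rep(t, length(pos)), chrom = chrom)
}
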