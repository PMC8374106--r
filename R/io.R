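#' @importFrom stats pbinom pchisq pnorm qnorm quantile rbeta rbinom rnorm
#'   rpois runif median sd var coef glm lm binomial p.adjust binom.test
#'   logLik pt setNames complete.cases rexp chisq.test aggregate
#' @importFrom utils read.delim write.table head
NULL

# Wicker three-letter superfamily vocabulary used throughout the package.
WICKER_CODES <- c("DHH", "DTA", "DTC", "DTH", "DTM", "DTT", "DTX",
                  "RIX", "RLC", "RLG", "RLX", "RSX")

CONTEXTS <- c("CG", "CHG", "CHH")

#' Construct a table of per-cytosine methylation observations
#'
#' The atomic observation of the package: one cytosine's position, strand,
#' trinucleotide context and read counts. All internal coordinates are
#' 0-based half-open.
#'
#' @param chrom chromosome identifiers (character).
#' @param pos 0-based positions (integer).
#' @param strand `"+"` or `"-"`.
#' @param context one of `"CG"`, `"CHG"`, `"CHH"`.
#' @param n_meth methylated read counts.
#' @param n_total total read counts (`>= n_meth`).
#' @return A `data.frame` with one row per cytosine and columns
#'   `chrom`, `pos`, `strand`, `context`, `n_meth`, `n_total`.
#' @export
cytosine_records <- function(chrom, pos, strand, context, n_meth, n_total) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   strand = as.character(strand),
                   context = as.character(context),
                   n_meth = as.integer(n_meth), n_total = as.integer(n_total),
                   stringsAsFactors = FALSE)
  validate_cytosine_records(df)
  df
}

validate_cytosine_records <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "pos", "strand", "context", "n_meth", "n_total")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("methylome table lacks columns: ", paste(missing_cols, collapse = ", "))
  bad <- which(!df$context %in% CONTEXTS)
  if (length(bad))
    stop("unknown cytosine context '", df$context[bad[1]], "' at row ", bad[1])
  bad <- which(df$n_meth > df$n_total | df$n_meth < 0)
  if (length(bad))
    stop("methylated count exceeds total (or is negative) at row ", bad[1])
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad))
    stop("strand must be '+' or '-' at row ", bad[1])
  invisible(df)
}

#' Read a Bismark-style cytosine report
#'
#' Expects a headerless TSV with columns chromosome, 1-based position,
#' strand, methylated count, unmethylated count, context (a seventh
#' trinucleotide column, if present, is ignored). Positions are shifted to
#' the package's 0-based convention, and `n_total` is the sum of methylated
#' and unmethylated counts. Records below `min_reads` are retained but
#' flagged in the `low_coverage` column; filtering is the consumer's call.
#'
#' @param path path to the report.
#' @param min_reads coverage below which a record is flagged (default 1,
#'   i.e. only zero-coverage sites are flagged).
#' @return a cytosine record `data.frame` (see [cytosine_records()]) with an
#'   extra logical column `low_coverage`.
#' @export
read_cytosine_report <- function(path, min_reads = 1L) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (ncol(df) < 6)
    stop("cytosine report needs >= 6 tab-separated columns, found ", ncol(df))
  pos <- suppressWarnings(as.integer(df[[2]]))
  n_meth <- suppressWarnings(as.integer(df[[4]]))
  n_unmeth <- suppressWarnings(as.integer(df[[5]]))
  bad <- which(is.na(pos) | is.na(n_meth) | is.na(n_unmeth) |
                 n_meth < 0 | n_unmeth < 0)
  if (length(bad))
    stop("malformed cytosine report row at line ", bad[1], " of ", path)
  bad <- which(!df[[6]] %in% CONTEXTS)
  if (length(bad))
    stop("unknown context '", df[[6]][bad[1]], "' at line ", bad[1], " of ", path)
  bad <- which(!df[[3]] %in% c("+", "-"))
  if (length(bad))
    stop("bad strand at line ", bad[1], " of ", path)
  out <- data.frame(chrom = df[[1]], pos = pos - 1L, strand = df[[3]],
                    context = df[[6]], n_meth = n_meth,
                    n_total = n_meth + n_unmeth, stringsAsFactors = FALSE)
  out$low_coverage <- out$n_total < min_reads
  out
}

#' Construct a gene-model table
#'
#' @param genes `data.frame` with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @param exons `data.frame` with columns `gene_id`, `start`, `end`
#'   (0-based half-open); the exons of the representative (longest)
#'   transcript. Defaults to one exon spanning each gene.
#' @return A `gene_models` object: the gene table with derived strand-aware
#'   `tss` and `tts` columns and the exon table attached as attribute
#'   `"exons"`.
#' @export
gene_models <- function(genes, exons = NULL) {
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(genes)))
    stop("gene table needs columns: ", paste(need, collapse = ", "))
  genes <- genes[, need]
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (any(genes$start >= genes$end)) stop("gene with start >= end")
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene without strand: ",
         genes$gene_id[which(!genes$strand %in% c("+", "-"))[1]])
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id: ", genes$gene_id[duplicated(genes$gene_id)][1])
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes$tts <- ifelse(genes$strand == "+", genes$end - 1L, genes$start)
  if (is.null(exons)) {
    exons <- data.frame(gene_id = genes$gene_id, start = genes$start,
                        end = genes$end, stringsAsFactors = FALSE)
  } else {
    exons <- data.frame(gene_id = as.character(exons$gene_id),
                        start = as.integer(exons$start),
                        end = as.integer(exons$end), stringsAsFactors = FALSE)
    span <- merge(exons, genes[, c("gene_id", "start", "end")],
                  by = "gene_id", suffixes = c("", ".gene"))
    if (any(span$start < span$start.gene | span$end > span$end.gene))
      stop("exon outside its gene span")
  }
  rownames(genes) <- NULL
  structure(genes, exons = exons, class = c("gene_models", "data.frame"))
}

#' Exons of the representative transcript
#' @param genes a `gene_models` object.
#' @return `data.frame` with columns `gene_id`, `start`, `end`.
#' @export
gene_exons <- function(genes) attr(genes, "exons")

#' Read gene annotations from GFF3 or BED
#'
#' GFF3 coordinates (1-based inclusive) are converted to the internal 0-based
#' half-open convention; BED is consumed natively. When a gene carries
#' multiple transcripts, the exons of the longest transcript (by exon-summed
#' length, ties broken by lexicographically smallest transcript id) define
#' the gene's exon set.
#'
#' @param path annotation file.
#' @param format `"gff3"` or `"bed"`.
#' @return a [gene_models()] object.
#' @export
read_gene_annotation <- function(path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 6) stop("BED gene annotation needs 6 columns (strand required)")
    genes <- data.frame(gene_id = as.character(df[[4]]), chrom = df[[1]],
                        start = df[[2]], end = df[[3]], strand = df[[6]],
                        stringsAsFactors = FALSE)
    return(gene_models(genes))
  }
  gr <- rtracklayer::import(path)
  d <- as.data.frame(gr)
  d$type <- as.character(d$type)
  d$seqnames <- as.character(d$seqnames)
  d$strand <- as.character(d$strand)
  parent1 <- vapply(d$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                    character(1))
  is_gene <- d$type == "gene"
  if (!any(is_gene)) stop("no gene features in ", path)
  genes <- data.frame(gene_id = d$ID[is_gene], chrom = d$seqnames[is_gene],
                      start = d$start[is_gene] - 1L, end = d$end[is_gene],
                      strand = d$strand[is_gene], stringsAsFactors = FALSE)
  if (any(!genes$strand %in% c("+", "-")))
    stop("gene without strand: ", genes$gene_id[!genes$strand %in% c("+", "-")][1])
  tx <- d[d$type %in% c("mRNA", "transcript"), , drop = FALSE]
  ex <- d[d$type == "exon", , drop = FALSE]
  ex$parent <- parent1[d$type == "exon"]
  exons <- NULL
  if (nrow(tx) && nrow(ex)) {
    tx$gene <- parent1[d$type %in% c("mRNA", "transcript")]
    exlen <- tapply(ex$end - ex$start + 1L, ex$parent, sum)
    tx$exlen <- as.numeric(exlen[tx$ID])
    tx <- tx[!is.na(tx$exlen), , drop = FALSE]
    # longest transcript per gene; ties -> smallest transcript id
    tx <- tx[order(tx$gene, -tx$exlen, tx$ID), , drop = FALSE]
    keep_tx <- tx$ID[!duplicated(tx$gene)]
    ex <- ex[ex$parent %in% keep_tx, , drop = FALSE]
    gene_of_tx <- setNames(tx$gene, tx$ID)
    exons <- data.frame(gene_id = unname(gene_of_tx[ex$parent]),
                        start = ex$start - 1L, end = ex$end,
                        stringsAsFactors = FALSE)
  }
  gene_models(genes, exons)
}

#' Read repeat / transposable-element annotations
#'
#' Superfamilies use the three-letter Wicker codes (`DHH`, `DTA`, `DTC`,
#' `DTH`, `DTM`, `DTT`, `DTX`, `RIX`, `RLC`, `RLG`, `RLX`, `RSX`); anything
#' else is mapped to `"unknown"`.
#'
#' @param path annotation file.
#' @param format `"gff3"`, `"bed"` or `"tsv"` (columns chrom, start, end,
#'   superfamily; 0-based half-open).
#' @return `data.frame` with columns `chrom`, `start`, `end`, `superfamily`.
#' @export
read_repeat_annotation <- function(path, format = c("gff3", "bed", "tsv")) {
  format <- match.arg(format)
  if (format == "gff3") {
    gr <- rtracklayer::import(path)
    d <- as.data.frame(gr)
    sf <- if ("superfamily" %in% names(d)) as.character(d$superfamily)
          else as.character(d$type)
    out <- data.frame(chrom = as.character(d$seqnames), start = d$start - 1L,
                      end = d$end, superfamily = sf, stringsAsFactors = FALSE)
  } else {
    df <- read.delim(path, header = (format == "tsv"), stringsAsFactors = FALSE)
    if (format == "tsv" && !all(c("chrom", "start", "end", "superfamily") %in% names(df)))
      stop("repeat TSV needs columns chrom, start, end, superfamily")
    if (format == "bed") {
      out <- data.frame(chrom = as.character(df[[1]]), start = df[[2]],
                        end = df[[3]],
                        superfamily = if (ncol(df) >= 4) as.character(df[[4]]) else "unknown",
                        stringsAsFactors = FALSE)
    } else {
      out <- df[, c("chrom", "start", "end", "superfamily")]
    }
  }
  out$superfamily[!out$superfamily %in% WICKER_CODES] <- "unknown"
  if (any(out$start >= out$end)) stop("repeat with start >= end in ", path)
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  out
}

#' Read a gene-expression table (gene id, RPKM)
#'
#' Genes absent from the table are representable (and distinct from RPKM 0):
#' downstream quartile assignment puts them in quartile 0.
#'
#' @param path TSV with header columns `gene_id` and `rpkm`.
#' @return `data.frame` with columns `gene_id`, `rpkm`.
#' @export
read_expression_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "rpkm") %in% names(df)))
    stop("expression table needs columns gene_id, rpkm")
  if (any(is.na(df$rpkm)) || any(df$rpkm < 0))
    stop("rpkm must be a non-negative number for every row")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in expression table")
  df[, c("gene_id", "rpkm")]
}

#' Read a one-to-one ortholog table
#'
#' @param path TSV with header: `ortholog_id` then one column per species,
#'   each holding that species' gene id.
#' @return `data.frame`, first column `ortholog_id`, species columns after.
#' @export
read_ortholog_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (names(df)[1] != "ortholog_id" || ncol(df) < 3)
    stop("ortholog table needs an ortholog_id column plus >= 2 species columns")
  if (anyDuplicated(df$ortholog_id)) stop("duplicate ortholog_id")
  for (sp in names(df)[-1]) {
    if (anyDuplicated(df[[sp]]))
      stop("ortholog table is not 1-to-1: duplicate gene in species ", sp)
  }
  df
}

#' Read BLAST tabular output (12-column outfmt 6)
#'
#' @param path tabular hits file, one row per HSP.
#' @return `data.frame` with the standard columns `query_id`, `subject_id`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`,
#'   `send`, `evalue`, `bitscore`.
#' @export
read_blast_tab <- function(path) {
  cols <- c("query_id", "subject_id", "pident", "length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (file.size(path) == 0)
    return(stats::setNames(
      as.data.frame(c(rep(list(character()), 2), rep(list(numeric()), 10))), cols))
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 12) stop("BLAST tabular file needs 12 columns, found ", ncol(df))
  names(df) <- cols
  if (any(df$evalue < 0)) stop("negative e-value in ", path)
  df
}

#' Read a newick phylogeny
#' @param path newick file.
#' @return an `ape` `phylo` object.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Write island calls as BED6
#'
#' Emits one line per island window, sorted by chromosome then start, with
#' `name = win_<chrom>_<start>` and `score = -10 log10(q)` capped at 1000
#' (0 when no q-value is available, e.g. for empirical-cutoff calls).
#'
#' @param islands `data.frame` with columns `chrom`, `start`, `end` and
#'   optionally `q_value`, or an [call_islands()] result (its island windows
#'   are written).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_island_bed <- function(islands, path) {
  if (inherits(islands, "mchh_islands"))
    islands <- islands$windows[islands$windows$is_island, , drop = FALSE]
  if (nrow(islands) == 0) {
    file.create(path)
    return(invisible(path))
  }
  q <- if ("q_value" %in% names(islands)) islands$q_value else rep(NA_real_, nrow(islands))
  score <- ifelse(is.na(q), 0, pmin(1000, round(-10 * log10(pmax(q, 1e-100)))))
  score[!is.na(q) & q >= 1] <- 0
  bed <- data.frame(chrom = islands$chrom, start = islands$start,
                    end = islands$end,
                    name = paste0("win_", islands$chrom, "_", islands$start),
                    score = score, strand = ".", stringsAsFactors = FALSE)
  bed <- bed[order(bed$chrom, bed$start), ]
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED6 island file written by [write_island_bed()]
#' @param path BED file.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `name`, `score`.
#' @export
read_island_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(chrom = as.character(df[[1]]), start = as.integer(df[[2]]),
             end = as.integer(df[[3]]), name = as.character(df[[4]]),
             score = as.numeric(df[[5]]), stringsAsFactors = FALSE)
}
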