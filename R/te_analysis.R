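#' TE-superfamily enrichment for mCHH islands
#'
#' For genes whose nearest upstream TE (within 2 kb) is annotated, tests
#' each superfamily's island proportion `k/n` against the pooled proportion
#' across all superfamilies with an exact binomial test (two-sided by
#' default), Benjamini-Hochberg corrected across the tested superfamilies.
#' Labels: `Enriched` when `q < alpha` and the proportion exceeds the pooled
#' one, `Under` when below, `NS` otherwise.
#'
#' @param superfamily per-gene superfamily code of the nearest upstream TE.
#' @param has_island per-gene logical 5' island status.
#' @param alpha FDR threshold (default 0.05).
#' @param alternative sidedness of the binomial test (default
#'   `"two.sided"`; `"greater"`/`"less"` available).
#' @return `data.frame` of class `superfamily_enrichment` with columns
#'   `superfamily`, `n`, `k`, `proportion`, `p0`, `p_value`, `q_value`,
#'   `label`.
#' @export
superfamily_enrichment <- function(superfamily, has_island, alpha = 0.05,
                                   alternative = "two.sided") {
  stopifnot(length(superfamily) == length(has_island))
  keep <- !is.na(superfamily) & !is.na(has_island)
  superfamily <- superfamily[keep]; has_island <- has_island[keep]
  n <- table(superfamily)
  k <- tapply(as.logical(has_island), superfamily, sum)
  sf <- names(n)
  n <- as.integer(n); k <- as.integer(k[sf])
  p0 <- sum(k) / sum(n)
  p <- vapply(seq_along(sf), function(i)
    binom.test(k[i], n[i], p0, alternative = alternative)$p.value, numeric(1))
  q <- p.adjust(p, "BH")
  prop <- k / n
  label <- ifelse(q < alpha & prop > p0, "Enriched",
                  ifelse(q < alpha & prop < p0, "Under", "NS"))
  structure(data.frame(superfamily = sf, n = n, k = k, proportion = prop,
                       p0 = p0, p_value = p, q_value = q, label = label,
                       stringsAsFactors = FALSE),
            class = c("superfamily_enrichment", "data.frame"))
}

#' Feltz-Miller asymptotic test for equality of coefficients of variation
#'
#' For k groups with sample CVs `c_i` and sizes `n_i`, the pooled CV is
#' `c = sum((n_i - 1) c_i) / sum(n_i - 1)` and the statistic
#' `sum((n_i - 1)(c_i - c)^2) / (c^2 (0.5 + c^2))` is referred to a
#' chi-squared distribution with k - 1 degrees of freedom.
#'
#' @param samples list of numeric vectors (each `n >= 2`, positive mean).
#' @return list with `statistic`, `df`, `p_value`, and a `groups` table
#'   (`n`, `mean`, `sd`, `cv`).
#' @export
feltz_miller_cv_test <- function(samples) {
  stopifnot(is.list(samples), length(samples) >= 2)
  n <- vapply(samples, length, integer(1))
  if (any(n < 2)) stop("each group needs at least 2 observations")
  mu <- vapply(samples, mean, numeric(1))
  if (any(mu <= 0)) stop("each group needs a positive mean")
  s <- vapply(samples, sd, numeric(1))
  cv <- s / mu
  w <- n - 1
  c_pool <- sum(w * cv) / sum(w)
  stat <- sum(w * (cv - c_pool)^2) / (c_pool^2 * (0.5 + c_pool^2))
  df <- length(samples) - 1
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE),
       groups = data.frame(n = n, mean = mu, sd = s, cv = cv))
}

#' Coincident vs dissonant lineage-specific islands
#'
#' For orthologs of a species pair, considers those with an island in
#' exactly one species ("lineage-specific"). When such an ortholog also has
#' a TE within 2 kb in exactly one species, it is *coincident* if the TE is
#' in the island-bearing species and *dissonant* if in the other; orthologs
#' with TEs in both or neither species retain their TE pattern but do not
#' enter the test. The counts are compared against a 50:50 expectation with
#' a 1-df chi-squared goodness-of-fit test. When the lineage-specific TE's
#' superfamily is given, each superfamily's coincident/dissonant split is
#' also tested against the rest (2x2 chi-squared, BH-corrected).
#'
#' @param island_a,island_b per-ortholog island status in species a and b.
#' @param te_a,te_b per-ortholog TE-within-2kb status.
#' @param superfamily optional per-ortholog superfamily of the
#'   lineage-specific TE.
#' @return list with `records` (per-ortholog `island_pattern`,
#'   `te_pattern`, `class`), `n_coincident`, `n_dissonant`, `statistic`,
#'   `p_value`, and `superfamily_table` when codes were given.
#' @export
classify_coincidence <- function(island_a, island_b, te_a, te_b,
                                 superfamily = NULL) {
  stopifnot(length(island_a) == length(island_b),
            length(te_a) == length(island_a),
            length(te_b) == length(island_a))
  island_pattern <- ifelse(island_a & island_b, "both",
                           ifelse(island_a, "a",
                                  ifelse(island_b, "b", "neither")))
  te_pattern <- ifelse(te_a & te_b, "both",
                       ifelse(te_a, "a", ifelse(te_b, "b", "neither")))
  single <- island_pattern %in% c("a", "b")
  cls <- rep("excluded", length(island_a))
  single_te <- single & te_pattern %in% c("a", "b")
  cls[single_te] <- ifelse(
    island_pattern[single_te] == te_pattern[single_te],
    "coincident", "dissonant")
  n_c <- sum(cls == "coincident")
  n_d <- sum(cls == "dissonant")
  if (n_c + n_d == 0) stop("no classifiable ortholog (no single-lineage TE)")
  ct <- suppressWarnings(chisq.test(c(n_c, n_d), p = c(0.5, 0.5)))
  out <- list(records = data.frame(island_pattern = island_pattern,
                                   te_pattern = te_pattern, class = cls,
                                   stringsAsFactors = FALSE),
              n_coincident = n_c, n_dissonant = n_d,
              statistic = unname(ct$statistic), p_value = unname(ct$p.value))
  if (!is.null(superfamily)) {
    sf <- superfamily[single_te]
    cl <- cls[single_te]
    tab <- table(sf, factor(cl, levels = c("coincident", "dissonant")))
    res <- lapply(rownames(tab), function(s) {
      in_sf <- tab[s, ]
      rest <- colSums(tab) - in_sf
      m <- rbind(in_sf, rest)
      p <- if (any(m == 0) || nrow(tab) < 2) NA_real_
           else suppressWarnings(chisq.test(m)$p.value)
      data.frame(superfamily = s, coincident = in_sf[1], dissonant = in_sf[2],
                 p_value = p, stringsAsFactors = FALSE)
    })
    sft <- do.call(rbind, res)
    sft$q_value <- p.adjust(sft$p_value, "BH")
    rownames(sft) <- NULL
    out$superfamily_table <- sft
  }
  out
}

#' Best-hit e-value summary of island (or control) sequences
#'
#' Per query window, the minimum e-value over its BLAST hits; queries with
#' no hit are assigned e-value 1.0. Reports the fractions of queries below
#' 1e-5 and 1e-40 and a log10-binned histogram.
#'
#' @param hits `data.frame` from [read_blast_tab()].
#' @param query_ids every query window id (islands, or the sampled control
#'   windows); hits for ids outside this set are an error.
#' @return list with `best` (named per-query best e-value),
#'   `fraction_below_1e5`, `fraction_below_1e40`, `histogram`.
#' @export
blast_evalue_summary <- function(hits, query_ids) {
  stray <- setdiff(unique(hits$query_id), query_ids)
  if (length(stray))
    stop("hit for unknown query id: ", stray[1])
  best <- setNames(rep(1.0, length(query_ids)), query_ids)
  if (nrow(hits)) {
    mins <- tapply(hits$evalue, hits$query_id, min)
    best[names(mins)] <- mins
  }
  breaks <- c(0, 10^seq(-50, 0, by = 10), Inf)
  list(best = best,
       fraction_below_1e5 = mean(best < 1e-5),
       fraction_below_1e40 = mean(best < 1e-40),
       histogram = table(cut(best, breaks, include.lowest = TRUE)))
}

#' Sample control (non-island) windows for the BLAST comparison
#'
#' Draws, with a seed, as many non-island windows with covered CHH sites as
#' there are island windows, mirroring the island/control design.
#'
#' @param calls an `mchh_islands` object.
#' @param seed RNG seed.
#' @return `data.frame` of control windows (`chrom`, `start`, `end`).
#' @export
sample_control_windows <- function(calls, seed = 1L) {
  w <- calls$windows
  n_isl <- sum(w$is_island)
  pool <- which(!w$is_island)
  if (n_isl == 0) stop("no island windows")
  if (length(pool) < n_isl) stop("not enough non-island windows to sample")
  idx <- with_seed(seed, sample(pool, n_isl))
  w[idx, c("chrom", "start", "end")]
}

#' Island-to-TE-edge and island-to-TSS distances
#'
#' For each island window whose midpoint lies within an annotated TE,
#' measures (from the midpoint) the distance to the closer TE end and the
#' distance to the nearest gene TSS, then compares the dispersion of the two
#' distance sets with the Feltz-Miller CV test (pooled, and per superfamily
#' when at least two groups have data).
#'
#' @param calls an `mchh_islands` object.
#' @param tes repeat table with `superfamily`.
#' @param genes a [gene_models()] object.
#' @return list with `distances` (`chrom`, `center`, `superfamily`,
#'   `dist_te_edge`, `dist_tss`), `cv` (per-group n/mean/sd/cv), `test`
#'   (pooled Feltz-Miller result).
#' @export
island_te_distances <- function(calls, tes, genes) {
  w <- calls$windows[calls$windows$is_island, , drop = FALSE]
  if (nrow(w) == 0) stop("no island windows")
  center <- (w$start + w$end) %/% 2L
  rows <- list()
  for (i in seq_len(nrow(w))) {
    te <- tes[tes$chrom == w$chrom[i] & tes$start <= center[i] &
                tes$end > center[i], , drop = FALSE]
    if (nrow(te) == 0) next
    te <- te[1, ]
    g <- genes[genes$chrom == w$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) next
    rows[[length(rows) + 1]] <- data.frame(
      chrom = w$chrom[i], center = center[i], superfamily = te$superfamily,
      dist_te_edge = min(center[i] - te$start, te$end - center[i]),
      dist_tss = min(abs(center[i] - g$tss)), stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no island midpoint lies within an annotated TE")
  d <- do.call(rbind, rows)
  test <- feltz_miller_cv_test(list(tss = d$dist_tss, te_edge = d$dist_te_edge))
  cv <- test$groups
  cv$group <- c("dist_tss", "dist_te_edge")
  list(distances = d, cv = cv, test = test)
}
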