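#' Published per-species mCHH-island summary for eight grasses
#'
#' The printed per-species summary the cross-species arithmetic operates
#' on: genome size, genes analysed, the percentage of genes with an mCHH
#' island within the flanking 2 kb, the median island mCHH level, and the
#' percentage (of 2,720 one-to-one orthologs) island-associated in each
#' species, with the ortholog-island median level.
#'
#' @return `data.frame` with columns `species`, `genome_size_mb`,
#'   `n_genes`, `pct_island_genes`, `median_island_mchh`,
#'   `pct_island_orthologs`, `median_ortholog_island_mchh`.
#' @export
grass_island_summary <- function() {
  data.frame(
    species = c("Brachypodium distachyon", "Hordeum vulgare",
                "Oryza sativa", "Phyllostachys heterocycla",
                "Setaria italica", "Sorghum bicolor", "Triticum urartu",
                "Zea mays"),
    genome_size_mb = c(355, 5428, 489, 2075, 513, 734, 4817, 2655),
    n_genes = c(34257, 35200, 41806, 30946, 34170, 33972, 33612, 37534),
    pct_island_genes = c(55.16, 28.22, 71.85, 17.27, 29.80, 54.01, 22.94,
                         30.85),
    median_island_mchh = c(31.49, 34.19, 41.80, 29.03, 38.89, 46.05, 34.78,
                           53.85),
    pct_island_orthologs = c(58.20, 41.34, 76.61, 18.51, 34.31, 59.91,
                             28.29, 38.73),
    median_ortholog_island_mchh = c(32.76, 34.64, 49.19, 28.57, 41.00,
                                    49.06, 35.71, 53.80),
    stringsAsFactors = FALSE)
}

#' Published TE-superfamily island counts for barley, rice and maize
#'
#' For each Wicker superfamily present in all three species: the number of
#' genes whose closest upstream TE (within 2 kb) belongs to the
#' superfamily, the proportion of those genes with a 5' mCHH island, and
#' the printed enrichment label relative to the pooled proportion. The
#' printed per-species pooled totals are 0.285 (barley), 0.747 (rice) and
#' 0.333 (maize).
#'
#' @return `data.frame` with columns `species`, `superfamily`, `n`,
#'   `proportion`, `label`.
#' @export
te_superfamily_table <- function() {
  sf <- c("DHH", "DTA", "DTC", "DTH", "DTM", "DTT", "DTX", "RIX", "RLC",
          "RLG", "RLX", "RSX")
  data.frame(
    species = rep(c("Hordeum vulgare", "Oryza sativa", "Zea mays"),
                  each = 12),
    superfamily = rep(sf, 3),
    n = c(69, 21, 3480, 478, 654, 474, 332, 880, 4896, 4413, 11356, 76,
          132, 517, 1243, 40, 1106, 2143, 6476, 551, 1433, 2230, 10753, 796,
          5235, 653, 184, 2677, 122, 2307, 299, 87, 3148, 3891, 2632, 43),
    proportion = c(0.174, 0.095, 0.280, 0.460, 0.378, 0.430, 0.497, 0.227,
                   0.239, 0.213, 0.315, 0.316,
                   0.417, 0.768, 0.474, 0.700, 0.806, 0.898, 0.882, 0.611,
                   0.651, 0.580, 0.704, 0.932,
                   0.283, 0.542, 0.429, 0.536, 0.623, 0.389, 0.408, 0.253,
                   0.280, 0.292, 0.224, 0.302),
    label = c("NS", "NS", "NS", "Enriched", "Enriched", "Enriched",
              "Enriched", "Under", "Under", "Under", "Enriched", "NS",
              "Under", "NS", "Under", "NS", "Enriched", "Enriched",
              "Enriched", "Under", "Under", "Under", "Under", "Enriched",
              "Under", "Enriched", "Enriched", "Enriched", "Enriched",
              "Enriched", "Enriched", "NS", "Under", "Under", "Under", "NS"),
    stringsAsFactors = FALSE)
}
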