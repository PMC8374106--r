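#' Build an ortholog panel
#'
#' The unit of conservation analysis: a matrix of island status (orthologs
#' by species, `NA` where an ortholog fails the coverage filter in a
#' species), with optional parallel gbM matrix and per-variable matrices.
#'
#' @param island logical matrix, orthologs x species (dimnames required on
#'   columns).
#' @param gbm optional parallel logical matrix.
#' @param variables optional named list of parallel numeric matrices
#'   (expression, gene length, TE distance, exonic mCG, ...).
#' @return object of class `ortholog_panel` with element `p_species`, the
#'   per-species island proportions over scored orthologs.
#' @export
ortholog_panel <- function(island, gbm = NULL, variables = list()) {
  island <- as.matrix(island)
  if (is.null(colnames(island))) stop("island matrix needs species column names")
  storage.mode(island) <- "logical"
  if (!is.null(gbm)) {
    gbm <- as.matrix(gbm)
    stopifnot(identical(dim(gbm), dim(island)))
  }
  for (v in variables) stopifnot(identical(dim(as.matrix(v)), dim(island)))
  structure(list(island = island, gbm = gbm, variables = variables,
                 species = colnames(island),
                 p_species = colMeans(island, na.rm = TRUE)),
            class = "ortholog_panel")
}

#' @export
print.ortholog_panel <- function(x, ...) {
  cat("Ortholog panel:", nrow(x$island), "orthologs x",
      length(x$species), "species\n")
  cat("island proportions:\n")
  print(round(x$p_species, 4))
  invisible(x)
}

#' Expected count of doubly island-associated orthologs under independence
#' @param n orthologs scored in both species.
#' @param p_i,p_j per-species island proportions.
#' @return `n * p_i * p_j`.
#' @export
expected_pair_count <- function(n, p_i, p_j) n * p_i * p_j

#' Pairwise conservation enrichment between two species
#'
#' Observed number of orthologs island-associated in both species divided by
#' the random expectation `N * p_i * p_j`, where `N` and the proportions are
#' computed over the orthologs scored in both species. Also works on the gbM
#' matrix via `trait = "gbm"`.
#'
#' @param panel an [ortholog_panel()].
#' @param species_i,species_j species (column) names.
#' @param trait `"island"` (default) or `"gbm"`.
#' @return list with `species_i`, `species_j`, `n`, `p_i`, `p_j`,
#'   `observed`, `expected`, `enrichment`.
#' @export
pairwise_enrichment <- function(panel, species_i, species_j,
                                trait = c("island", "gbm")) {
  trait <- match.arg(trait)
  m <- if (trait == "island") panel$island else panel$gbm
  if (is.null(m)) stop("panel has no ", trait, " matrix")
  stopifnot(species_i %in% colnames(m), species_j %in% colnames(m))
  a <- m[, species_i]; b <- m[, species_j]
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  p_i <- mean(a[ok]); p_j <- mean(b[ok])
  if (p_i == 0 || p_j == 0)
    stop("island proportion zero in ", if (p_i == 0) species_i else species_j,
         "; enrichment undefined")
  observed <- sum(a[ok] & b[ok])
  expected <- expected_pair_count(n, p_i, p_j)
  list(species_i = species_i, species_j = species_j, n = n,
       p_i = p_i, p_j = p_j, observed = observed, expected = expected,
       enrichment = observed / expected)
}

#' Permutation test of pairwise conservation
#'
#' Shuffles one species' island labels across orthologs `n_perm` times and
#' reports `p = (1 + #{perm observed >= real observed}) / (n_perm + 1)`.
#'
#' @inheritParams pairwise_enrichment
#' @param n_perm number of permutations (default 10000; a value below 100
#'   triggers a warning).
#' @param seed RNG seed.
#' @return list with `observed`, `expected`, `p_value`, `n_perm`, `seed`.
#' @export
permutation_test <- function(panel, species_i, species_j, n_perm = 10000L,
                             seed = 1L, trait = c("island", "gbm")) {
  trait <- match.arg(trait)
  if (n_perm < 100) warning("fewer than 100 permutations; p-value is coarse")
  m <- if (trait == "island") panel$island else panel$gbm
  a <- m[, species_i]; b <- m[, species_j]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  observed <- sum(a & b)
  exceed <- with_seed(seed, {
    count <- 0L
    for (i in seq_len(n_perm)) {
      if (sum(a & sample(b)) >= observed) count <- count + 1L
    }
    count
  })
  list(observed = observed,
       expected = expected_pair_count(length(a), mean(a), mean(b)),
       p_value = (1 + exceed) / (n_perm + 1), n_perm = n_perm, seed = seed)
}

#' Expected per-ortholog species count under the random model
#'
#' Under independent island gain/loss, the number of species (out of S) in
#' which a random ortholog carries an island is a sum of independent
#' Bernoulli draws; its mean is the sum of the per-species proportions.
#'
#' @param p_by_species per-species island proportions in `[0,1]`.
#' @return the analytic expectation `sum(p_by_species)`.
#' @export
random_model_mean <- function(p_by_species) {
  stopifnot(all(p_by_species >= 0 & p_by_species <= 1))
  sum(p_by_species)
}

#' Monte-Carlo random-model simulation
#'
#' Simulates panels of independent Bernoulli draws and, when an observed
#' mean species count is supplied, returns a p-value for it against the
#' simulated distribution of mean counts (two-sided by default).
#'
#' @param p_by_species per-species island proportions.
#' @param n_orthologs orthologs per simulated panel.
#' @param n_sim number of simulated panels (default 1000).
#' @param observed_mean optional observed mean count to test.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @param seed RNG seed.
#' @return list with `mean` (Monte-Carlo mean of means), `se`, `p_value`
#'   (`NA` when no observed mean given), `n_sim`, `seed`.
#' @export
random_model_sim <- function(p_by_species, n_orthologs, n_sim = 1000L,
                             observed_mean = NULL,
                             alternative = c("two.sided", "greater"),
                             seed = 1L) {
  alternative <- match.arg(alternative)
  S <- length(p_by_species)
  means <- with_seed(seed, {
    vapply(seq_len(n_sim), function(i) {
      counts <- rbinom(S, n_orthologs, p_by_species)
      sum(counts) / n_orthologs
    }, numeric(1))
  })
  p <- NA_real_
  if (!is.null(observed_mean)) {
    mu <- random_model_mean(p_by_species)
    if (alternative == "greater") {
      p <- (1 + sum(means >= observed_mean)) / (n_sim + 1)
    } else {
      dev <- abs(means - mu)
      p <- (1 + sum(dev >= abs(observed_mean - mu))) / (n_sim + 1)
    }
  }
  list(mean = mean(means), se = sd(means) / sqrt(n_sim), p_value = p,
       n_sim = n_sim, seed = seed)
}

#' Distribution of per-ortholog island counts
#'
#' @param panel an [ortholog_panel()].
#' @return list with `histogram` (named counts for 0..S species), `mean`,
#'   `median`, `counts` (the per-ortholog vector).
#' @export
count_distribution <- function(panel) {
  counts <- rowSums(panel$island, na.rm = TRUE)
  S <- ncol(panel$island)
  hist <- table(factor(counts, levels = 0:S))
  list(histogram = hist, mean = mean(counts), median = median(counts),
       counts = counts)
}

#' Linear model of island conservation on an averaged genic variable
#'
#' Averages a panel variable per ortholog across the species with data and
#' regresses the per-ortholog island count (0..S) on it with [ols_fit()].
#'
#' @param panel an [ortholog_panel()] carrying the variable.
#' @param variable name of the variable in `panel$variables`.
#' @return an [ols_fit()] result.
#' @export
conservation_lm <- function(panel, variable) {
  if (!variable %in% names(panel$variables))
    stop("panel has no variable '", variable, "'")
  v <- rowMeans(as.matrix(panel$variables[[variable]]), na.rm = TRUE)
  counts <- rowSums(panel$island, na.rm = TRUE)
  ols_fit(counts, v)
}
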