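#' Logistic regression of island presence on genic predictors
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares via
#' [stats::glm()], convergence tolerance 1e-8 on the deviance, at most 100
#' iterations) of a binary response on predictors rescaled to the 0-1
#' interval. Rows with any missing value are dropped listwise (the count is
#' recorded). Complete or quasi-complete separation is detected and flagged
#' rather than silently reported.
#'
#' @param data `data.frame` holding response and predictors (e.g.
#'   [gene_features()] output).
#' @param response name of the logical/binary response column (default
#'   `"has_5p_island"`).
#' @param predictors character vector of predictor column names.
#' @param standardize rescale each predictor with [standardize01()]
#'   (default `TRUE`; logical predictors are coerced to 0/1 first).
#' @return object of class `logistic_fit`: `coefficients`, `se`, `z`,
#'   `p_value`, `log_lik`, `null_log_lik`, `n`, `n_dropped`, `converged`,
#'   `separation`, `collinear`, and the underlying `glm` fit.
#' @export
logistic_fit <- function(data, response = "has_5p_island", predictors,
                         standardize = TRUE) {
  stopifnot(response %in% names(data), all(predictors %in% names(data)))
  d <- data[, c(response, predictors)]
  d[[response]] <- as.integer(d[[response]])
  for (p in predictors) d[[p]] <- as.numeric(d[[p]])
  keep <- complete.cases(d)
  d <- d[keep, , drop = FALSE]
  if (length(unique(d[[response]])) < 2)
    stop("response has no variation (need at least one event and one non-event)")
  if (standardize)
    for (p in predictors) d[[p]] <- standardize01(d[[p]])
  fml <- stats::as.formula(paste(response, "~",
                                 paste(predictors, collapse = " + ")))
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(fml, data = d, family = binomial(),
        control = list(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  cf <- coef(fit)
  collinear <- anyNA(cf)
  # complete/quasi-complete separation drives fitted probabilities to the
  # boundary (glm may still report convergence with huge coefficients)
  fp <- fitted(fit)
  separation <- sep_warn || !fit$converged || any(fp < 1e-10 | fp > 1 - 1e-10)
  res <- structure(list(
    coefficients = cf,
    se = setNames(rep(NA_real_, length(cf)), names(cf)),
    z = setNames(rep(NA_real_, length(cf)), names(cf)),
    p_value = setNames(rep(NA_real_, length(cf)), names(cf)),
    log_lik = as.numeric(logLik(fit)),
    null_log_lik = -fit$null.deviance / 2,
    n = nrow(d), n_dropped = sum(!keep),
    converged = fit$converged, separation = separation,
    collinear = collinear, predictors = predictors, glm = fit),
    class = "logistic_fit")
  est <- rownames(sm)
  res$se[est] <- sm[, "Std. Error"]
  res$z[est] <- sm[, "z value"]
  res$p_value[est] <- sm[, "Pr(>|z|)"]
  res
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic island model (n =", x$n, ", dropped", x$n_dropped, ")\n")
  tab <- data.frame(estimate = x$coefficients, se = x$se, z = x$z,
                    p = x$p_value)
  print(signif(as.matrix(tab), 4))
  if (x$separation) cat("warning: separation detected; estimates unreliable\n")
  if (x$collinear) cat("warning: collinear predictors (aliased coefficients)\n")
  invisible(x)
}

#' Variable importance of a logistic fit
#'
#' Importance of each predictor is the absolute Wald z-statistic of its
#' coefficient; the signed variant carries the direction of association for
#' display (negative = predictor disfavours an island).
#'
#' @param fit a converged [logistic_fit()].
#' @return `data.frame` with columns `predictor`, `importance` (`|z|`),
#'   `signed_importance` (`z`), sorted by decreasing importance.
#' @export
variable_importance <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!fit$converged) stop("fit did not converge; importance undefined")
  if (fit$collinear)
    stop("collinear predictors (aliased coefficients); importance undefined")
  z <- fit$z[fit$predictors]
  out <- data.frame(predictor = fit$predictors, importance = abs(unname(z)),
                    signed_importance = unname(z), stringsAsFactors = FALSE)
  out[order(-out$importance), ]
}

#' Phylogenetic generalized least squares under Brownian motion
#'
#' GLS fit of `y ~ x` across species with error covariance `V` equal to the
#' shared root-to-tip path length between each pair of tips (the Brownian
#' expectation, no lambda estimation):
#' `beta = (X' V^-1 X)^-1 X' V^-1 y`, with t-tests on `n - p` degrees of
#' freedom.
#'
#' @param y,x named per-species vectors; names must match tree tip labels.
#' @param tree an `ape` `phylo` with positive branch lengths.
#' @return object of class `pgls_fit`: `coefficients`, `se`, `t`,
#'   `p_value`, `sigma2`, `V`, `n`, `df_residual`.
#' @export
pgls_fit <- function(y, x, tree) {
  species <- names(y)
  if (is.null(species) || is.null(names(x)))
    stop("y and x must be named by species")
  missing_tips <- setdiff(species, tree$tip.label)
  if (length(missing_tips))
    stop("species not in tree: ", paste(missing_tips, collapse = ", "))
  x <- x[species]
  V <- ape::vcv.phylo(tree)[species, species]
  n <- length(y)
  X <- cbind(`(Intercept)` = 1, x = as.numeric(x))
  p <- ncol(X)
  if (n <= p) stop("need more species than coefficients (n > ", p, ")")
  Vi <- solve(V)
  XtVi <- crossprod(X, Vi)
  cov_unscaled <- solve(XtVi %*% X)
  beta <- drop(cov_unscaled %*% (XtVi %*% y))
  resid <- y - drop(X %*% beta)
  sigma2 <- drop(crossprod(resid, Vi %*% resid)) / (n - p)
  se <- sqrt(diag(cov_unscaled) * sigma2)
  tstat <- beta / se
  pv <- 2 * pt(abs(tstat), df = n - p, lower.tail = FALSE)
  structure(list(coefficients = setNames(beta, colnames(X)),
                 se = setNames(se, colnames(X)),
                 t = setNames(tstat, colnames(X)),
                 p_value = setNames(pv, colnames(X)),
                 sigma2 = sigma2, V = V, n = n, df_residual = n - p),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS fit (Brownian covariance, n =", x$n, ")\n")
  tab <- cbind(estimate = x$coefficients, se = x$se, t = x$t, p = x$p_value)
  print(signif(tab, 4))
  invisible(x)
}

#' Simple least-squares fit with the signed-r2 display convention
#'
#' Ordinary least squares of `y` on `x`; `signed_r2 = sign(slope) * r2`
#' mirrors the convention of reporting negative r2 for negative
#' associations.
#'
#' @param y,x numeric vectors (`n >= 3`); rows with missing values dropped.
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`,
#'   `signed_r2`, `n`.
#' @export
ols_fit <- function(y, x) {
  keep <- is.finite(y) & is.finite(x)
  y <- y[keep]; x <- x[keep]
  if (length(y) < 3) stop("ols_fit needs at least 3 complete observations")
  if (var(x) == 0) stop("predictor has zero variance")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  slope <- unname(coef(fit)[2])
  list(slope = slope, intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2, 4]),
       signed_r2 = sign(slope) * sm$r.squared, n = length(y))
}
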