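#' Simple linear regression between a driver and PMPR
#'
#' Ordinary least squares of `y` on (optionally log10-transformed) `x`,
#' reporting both the Pearson correlation on the transformed scale (with the
#' OLS p-value) and the Spearman rank correlation on the raw scale, the two
#' conventions used for abundance-function scatter plots.
#'
#' @param x Predictor vector.
#' @param y Response vector.
#' @param x_transform `"identity"` or `"log10"` (requires positive `x`).
#' @return List of class `"regression_result"`: `slope`, `intercept`,
#'   `pearson_r`, `p_value` (OLS slope test), `spearman_rho`, `spearman_p`,
#'   `n`, `transform`.
#' @export
fit_regression <- function(x, y, x_transform = c("identity", "log10")) {
  x_transform <- match.arg(x_transform)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("fit_regression: need >= 3 finite pairs")
  xt <- if (x_transform == "log10") {
    if (any(x <= 0)) stop("fit_regression: log10 transform needs positive x")
    log10(x)
  } else x
  if (stats::sd(xt) == 0) stop("fit_regression: zero variance in x")
  fit <- stats::lm(y ~ xt)
  sm <- summary(fit)
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 pearson_r = stats::cor(xt, y),
                 p_value = sm$coefficients[2, 4],
                 spearman_rho = unname(sp$estimate),
                 spearman_p = sp$p.value,
                 n = length(x), transform = x_transform),
            class = "regression_result")
}

#' Random-forest permutation importance of PMPR predictors
#'
#' Fits a regression random forest and reports each predictor's importance
#' as the percent increase in out-of-bag mean squared error when the
#' predictor is permuted, 100 * (MSE_perm - MSE_oob) / MSE_oob. Significance
#' is assessed against a null distribution obtained by refitting the forest
#' on permuted responses.
#'
#' @param features Data frame or matrix of complete numeric predictors
#'   (>= 20 samples).
#' @param response Numeric response.
#' @param n_trees Trees per forest.
#' @param n_null Response permutations for the significance flags.
#' @param seed Seed controlling the whole procedure.
#' @param alpha Significance level for the flag.
#' @return Data frame (class `"importance_table"`): `predictor`,
#'   `pct_inc_mse`, `p_value`, `significant`, sorted by decreasing
#'   importance.
#' @export
forest_importance <- function(features, response, n_trees = 500,
                              n_null = 100, seed = NULL, alpha = 0.05) {
  features <- as.data.frame(features)
  if (nrow(features) < 20L) stop("forest_importance: need >= 20 samples")
  if (anyNA(features) || anyNA(response)) stop("forest_importance: missing values")
  if (stats::sd(response) == 0) stop("forest_importance: constant response")
  if (!is.null(seed)) set.seed(seed)
  imp_of <- function(y) {
    fit <- randomForest::randomForest(x = features, y = y, ntree = n_trees,
                                      importance = TRUE)
    raw <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
    100 * raw / fit$mse[n_trees]
  }
  obs <- imp_of(response)
  null_mat <- vapply(seq_len(n_null), function(i) imp_of(sample(response)),
                     numeric(length(obs)))
  if (is.null(dim(null_mat))) null_mat <- matrix(null_mat, nrow = 1)
  p <- vapply(seq_along(obs), function(j) {
    (1 + sum(null_mat[j, ] >= obs[j])) / (1 + n_null)
  }, numeric(1))
  out <- data.frame(predictor = names(obs), pct_inc_mse = unname(obs),
                    p_value = p, significant = p <= alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$pct_inc_mse), ]
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Variation partitioning of a response between two predictor sets
#'
#' Decomposes the variance of `response` explained by biotic and abiotic
#' predictor matrices into pure and shared adjusted-R2 fractions:
#' `pure_biotic = adjR2(A+B) - adjR2(B)`, `pure_abiotic = adjR2(A+B) -
#' adjR2(A)`, `shared = adjR2(A) + adjR2(B) - adjR2(A+B)`, `unexplained = 1 -
#' adjR2(A+B)`. The four fractions sum to one by construction; individual
#' fractions may be slightly negative (an adjusted-R2 artifact) and are
#' reported unclipped, with a zero-clipped copy for display.
#'
#' @param response Numeric response vector.
#' @param X_biotic,X_abiotic Non-empty data frames / matrices of predictors.
#' @return List of class `"vpa_result"`: `pure_biotic`, `pure_abiotic`,
#'   `shared`, `unexplained`, `clipped` (named vector with negatives set to
#'   0), and the three adjusted R2 values.
#' @export
variation_partition <- function(response, X_biotic, X_abiotic) {
  A <- as.data.frame(X_biotic)
  B <- as.data.frame(X_abiotic)
  if (ncol(A) == 0L || ncol(B) == 0L) stop("both predictor sets must be non-empty")
  n <- length(response)
  if (n <= ncol(A) + ncol(B) + 2) stop("too few samples for the combined design")
  names(B) <- make.unique(c(names(A), names(B)))[-seq_len(ncol(A))]
  both <- cbind(A, B)
  qrd <- qr(cbind(1, as.matrix(both)))
  if (qrd$rank < ncol(both) + 1L) {
    dropped <- setdiff(seq_len(ncol(both) + 1L), qrd$pivot[seq_len(qrd$rank)])
    stop("rank-deficient combined design; collinear column(s): ",
         paste(names(both)[dropped - 1L], collapse = ", "))
  }
  adj_r2 <- function(X) {
    summary(stats::lm(response ~ ., data = X))$adj.r.squared
  }
  rA <- adj_r2(A); rB <- adj_r2(B); rAB <- adj_r2(both)
  fr <- c(pure_biotic = rAB - rB, pure_abiotic = rAB - rA,
          shared = rA + rB - rAB, unexplained = 1 - rAB)
  structure(c(as.list(fr),
              list(clipped = pmax(fr, 0),
                   adj_r2_biotic = rA, adj_r2_abiotic = rB,
                   adj_r2_combined = rAB)),
            class = "vpa_result")
}

#' @export
print.vpa_result <- function(x, ...) {
  cat("Variation partitioning (adjusted R2 fractions)\n")
  cat(sprintf("  pure biotic : %6.3f\n  pure abiotic: %6.3f\n  shared      : %6.3f\n  unexplained : %6.3f\n",
              x$pure_biotic, x$pure_abiotic, x$shared, x$unexplained))
  invisible(x)
}
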