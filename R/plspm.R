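#' Specify a partial least squares path model
#'
#' A PLS path model is a set of latent blocks, each measured by one or more
#' indicator columns of the data, and a directed acyclic inner structure
#' among the blocks.
#'
#' @param blocks Named list; each element is a character vector of indicator
#'   column names for that latent block.
#' @param paths Square 0/1 matrix with row and column names equal to
#'   `names(blocks)`; `paths[i, j] = 1` means block j predicts block i. Must
#'   be lower triangular in the given block order (a topological order).
#' @return Object of class `"plspm_spec"`.
#' @export
plspm_spec <- function(blocks, paths) {
  stopifnot(is.list(blocks), !is.null(names(blocks)))
  paths <- as.matrix(paths)
  bn <- names(blocks)
  if (!identical(rownames(paths), bn) || !identical(colnames(paths), bn)) {
    stop("paths must have row/column names equal to names(blocks), in order")
  }
  if (any(paths[upper.tri(paths, diag = TRUE)] != 0)) {
    stop("paths must be lower triangular under the block order (acyclic)")
  }
  if (!all(paths %in% c(0, 1))) stop("paths entries must be 0 or 1")
  structure(list(blocks = blocks, paths = paths), class = "plspm_spec")
}

# Core alternating outer/inner estimation (Lohmoeller algorithm, mode A
# outer weighting). X: list of standardized indicator matrices per block.
plspm_engine <- function(X, paths, scheme = "centroid", tol = 1e-6,
                         max_iter = 300) {
  bn <- rownames(paths)
  nb <- length(bn)
  n <- nrow(X[[1]])
  adj <- (paths + t(paths)) > 0
  w <- lapply(X, function(m) rep(1, ncol(m)))
  score <- function(Xb, wb) {
    y <- Xb %*% wb
    as.numeric(scale(y))
  }
  Y <- vapply(seq_len(nb), function(b) score(X[[b]], w[[b]]), numeric(n))
  colnames(Y) <- bn
  unit <- function(v) v / sqrt(sum(v^2))
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    C <- stats::cor(Y)
    E <- if (scheme == "centroid") sign(C) else C
    E <- E * adj
    Z <- Y %*% E
    w_new <- lapply(seq_len(nb), function(b) {
      wb <- as.numeric(stats::cor(X[[b]], Z[, b]))
      if (all(wb == 0)) wb <- rep(1, length(wb))
      wb
    })
    delta <- max(vapply(seq_len(nb), function(b) {
      a <- unit(w[[b]]); bvec <- unit(w_new[[b]])
      min(max(abs(a - bvec)), max(abs(a + bvec)))  # sign-invariant change
    }, numeric(1)))
    w <- w_new
    Y <- vapply(seq_len(nb), function(b) score(X[[b]], w[[b]]), numeric(n))
    colnames(Y) <- bn
    trace <- c(trace, delta)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop("plspm: outer weights did not converge in ", max_iter,
         " iterations; last weight changes: ",
         paste(format(utils::tail(trace, 5), digits = 3), collapse = ", "))
  }
  # sign convention: latent scores positively aligned with their indicators
  for (b in seq_len(nb)) {
    if (sum(stats::cor(X[[b]], Y[, b])) < 0) {
      Y[, b] <- -Y[, b]
      w[[b]] <- -w[[b]]
    }
  }
  path_coef <- matrix(0, nb, nb, dimnames = dimnames(paths))
  r2 <- stats::setNames(rep(NA_real_, nb), bn)
  for (b in seq_len(nb)) {
    preds <- which(paths[b, ] == 1)
    if (length(preds) == 0L) next
    fit <- stats::lm.fit(cbind(1, Y[, preds, drop = FALSE]), Y[, b])
    path_coef[b, preds] <- fit$coefficients[-1]
    r2[b] <- 1 - sum(fit$residuals^2) / sum((Y[, b] - mean(Y[, b]))^2)
  }
  loadings <- lapply(seq_len(nb), function(b) {
    as.numeric(stats::cor(X[[b]], Y[, b]))
  })
  names(loadings) <- bn
  communality <- unlist(lapply(loadings, function(l) l^2))
  gof <- sqrt(mean(communality) * mean(r2, na.rm = TRUE))
  list(paths = path_coef, r2 = r2, scores = Y, weights = w,
       loadings = loadings, communality = communality, gof = gof,
       iterations = length(trace))
}

build_blocks <- function(data, spec) {
  lapply(spec$blocks, function(cols) {
    miss <- setdiff(cols, names(data))
    if (length(miss) > 0L) stop("plspm: indicator column(s) not in data: ",
                                paste(miss, collapse = ", "))
    m <- as.matrix(data[, cols, drop = FALSE])
    if (any(apply(m, 2, stats::sd) == 0)) {
      stop("plspm: constant indicator in block")
    }
    scale(m)
  })
}

#' Fit a PLS path model with bootstrap confidence intervals
#'
#' Estimates latent scores by the alternating outer/inner PLS algorithm
#' (reflective mode A outer weighting: indicators weighted by their
#' correlation with the inner proxy; centroid inner scheme by default),
#' iterated until the maximum absolute outer-weight change is below `tol`.
#' Path coefficients are per-endogenous-block least squares on the latent
#' scores. Direct, indirect (sums of products along directed chains) and
#' total effects are reported. Bootstrap resamples the rows with
#' replacement; percentile 95% intervals and significance stars
#' (* / ** / *** when the 95 / 99 / 99.9% interval excludes 0) are attached
#' to every path. The goodness of fit is
#' `GoF = sqrt(mean communality x mean R2)`.
#'
#' @param data Data frame holding all indicator columns (standardized
#'   internally).
#' @param spec A [plspm_spec()].
#' @param n_boot Bootstrap resamples; 0 skips the bootstrap.
#' @param seed Optional seed for the bootstrap.
#' @param scheme Inner weighting scheme, `"centroid"` (default) or
#'   `"factorial"`.
#' @param tol,max_iter Convergence control of the alternating algorithm.
#' @return Object of class `"plspm_result"`: `paths` (data frame `from`,
#'   `to`, `coef`, bootstrap `mean`, `se`, `ci_lower`, `ci_upper`, `stars`),
#'   `path_matrix`, `effects` (direct/indirect/total per block pair), `r2`,
#'   `loadings`, `communality`, `gof`, `scores`, `iterations`, `n_boot`.
#' @export
fit_plspm <- function(data, spec, n_boot = 1000, seed = NULL,
                      scheme = c("centroid", "factorial"), tol = 1e-6,
                      max_iter = 300) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(spec, "plspm_spec"))
  data <- as.data.frame(data)
  X <- build_blocks(data, spec)
  fit <- plspm_engine(X, spec$paths, scheme, tol, max_iter)
  bn <- names(spec$blocks)

  idx <- which(spec$paths == 1, arr.ind = TRUE)
  paths_df <- data.frame(from = bn[idx[, 2]], to = bn[idx[, 1]],
                         coef = fit$paths[idx], stringsAsFactors = FALSE)

  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(data)
    boot <- matrix(NA_real_, n_boot, nrow(paths_df))
    failed <- 0L
    for (b in seq_len(n_boot)) {
      rows <- sample.int(n, n, replace = TRUE)
      bfit <- tryCatch(
        plspm_engine(build_blocks(data[rows, , drop = FALSE], spec),
                     spec$paths, scheme, tol, max_iter),
        error = function(e) NULL)
      if (is.null(bfit)) { failed <- failed + 1L; next }
      boot[b, ] <- bfit$paths[idx]
    }
    qs <- function(p) apply(boot, 2, stats::quantile, probs = p, na.rm = TRUE)
    paths_df$boot_mean <- colMeans(boot, na.rm = TRUE)
    paths_df$boot_se <- apply(boot, 2, stats::sd, na.rm = TRUE)
    paths_df$ci_lower <- qs(0.025)
    paths_df$ci_upper <- qs(0.975)
    excl0 <- function(lo, hi) lo > 0 | hi < 0
    s95 <- excl0(paths_df$ci_lower, paths_df$ci_upper)
    s99 <- excl0(qs(0.005), qs(0.995))
    s999 <- excl0(qs(0.0005), qs(0.9995))
    paths_df$stars <- ifelse(s999, "***", ifelse(s99, "**", ifelse(s95, "*", "")))
    n_boot_ok <- n_boot - failed
  } else {
    n_boot_ok <- 0L
  }

  B <- fit$paths
  total <- matrix(0, length(bn), length(bn), dimnames = dimnames(B))
  term <- B
  for (k in seq_len(length(bn) - 1L)) {
    total <- total + term
    term <- term %*% B
  }
  effects <- data.frame(from = bn[idx[, 2]], to = bn[idx[, 1]],
                        direct = B[idx], total = total[idx],
                        stringsAsFactors = FALSE)
  # indirect effects exist also for unconnected pairs; report all nonzero
  all_idx <- which(total != 0 | B != 0, arr.ind = TRUE)
  effects <- data.frame(from = bn[all_idx[, 2]], to = bn[all_idx[, 1]],
                        direct = B[all_idx],
                        indirect = total[all_idx] - B[all_idx],
                        total = total[all_idx], stringsAsFactors = FALSE)

  structure(list(paths = paths_df, path_matrix = B, effects = effects,
                 r2 = fit$r2, loadings = fit$loadings,
                 communality = fit$communality, gof = fit$gof,
                 scores = fit$scores, iterations = fit$iterations,
                 n_boot = n_boot_ok),
            class = "plspm_result")
}

#' @export
print.plspm_result <- function(x, ...) {
  cat("PLS path model (", x$iterations, " iterations, GoF = ",
      format(x$gof, digits = 3), ")\n", sep = "")
  df <- x$paths
  df$coef <- round(df$coef, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
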