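#' Validate a sample-by-ASV count table
#'
#' A count table is a nonnegative integer matrix with samples as rows and
#' ASVs as columns, both uniquely named.
#'
#' @param x Matrix to validate.
#' @return The matrix, invisibly, in integer storage.
#' @export
validate_count_table <- function(x) {
  if (!is.matrix(x)) stop("count table must be a matrix (samples x ASVs)")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("count table needs sample row names and ASV column names")
  }
  if (anyDuplicated(rownames(x))) stop("duplicate sample identifiers")
  if (anyDuplicated(colnames(x))) stop("duplicate ASV identifiers")
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x))) {
    stop("counts must be nonnegative integers")
  }
  storage.mode(x) <- "integer"
  invisible(x)
}

#' Remove rare ASVs from a count table
#'
#' Drops every ASV whose total read count summed across all samples falls
#' below `min_reads`; samples are untouched. The default of 10 removes ASVs
#' with fewer than 10 reads in the whole dataset.
#'
#' @param x Count table (samples x ASVs).
#' @param min_reads Minimum dataset-wide total for an ASV to be kept.
#' @return Filtered count table.
#' @export
filter_rare_asvs <- function(x, min_reads = 10) {
  x <- validate_count_table(x)
  keep <- colSums(x) >= min_reads
  if (!any(keep)) stop("filter_rare_asvs: all ASVs removed at min_reads = ", min_reads)
  x[, keep, drop = FALSE]
}

#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads. Samples with fewer total reads than `depth` are dropped with a
#' message. Deterministic given `seed`.
#'
#' @param x Count table (samples x ASVs).
#' @param depth Target reads per sample (the study convention is the lowest
#'   observed sequencing depth).
#' @param seed Integer seed for the subsampling.
#' @return Rarefied count table; every row sums to `depth`.
#' @export
rarefy <- function(x, depth = 1016, seed = NULL) {
  x <- validate_count_table(x)
  stopifnot(depth >= 1)
  keep <- rowSums(x) >= depth
  if (!all(keep)) {
    message("rarefy: dropping ", sum(!keep), " sample(s) below depth ", depth, ": ",
            paste(rownames(x)[!keep], collapse = ", "))
  }
  x <- x[keep, , drop = FALSE]
  if (nrow(x) == 0L) stop("rarefy: no samples at or above depth ", depth)
  if (!is.null(seed)) set.seed(seed)
  out <- vegan::rrarefy(x, depth)
  storage.mode(out) <- "integer"
  out
}

#' Alpha diversity per sample
#'
#' Observed ASV richness and the Shannon index (natural logarithm) for each
#' sample of a (typically rarefied) count table.
#'
#' @param x Count table (samples x ASVs).
#' @return Data frame with `sample_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(x) {
  x <- validate_count_table(x)
  if (any(rowSums(x) == 0)) {
    stop("alpha_diversity: zero-sum sample(s): ",
         paste(rownames(x)[rowSums(x) == 0], collapse = ", "))
  }
  data.frame(
    sample_id = rownames(x),
    richness = as.integer(rowSums(x > 0)),
    shannon = as.numeric(vegan::diversity(x, index = "shannon")),
    stringsAsFactors = FALSE
  )
}

#' Bray-Curtis dissimilarity matrix
#'
#' @param x Count table (samples x ASVs).
#' @return Symmetric sample-by-sample matrix with zero diagonal and entries
#'   in \[0, 1\].
#' @export
bray_curtis <- function(x) {
  x <- validate_count_table(x)
  as.matrix(vegan::vegdist(x, method = "bray"))
}

#' One-way PERMANOVA on a dissimilarity matrix
#'
#' Permutational multivariate analysis of variance using the pseudo-F
#' statistic computed from among- and within-group sums of squared
#' dissimilarities (the Gower-centered formulation): with total sum of
#' squares \eqn{SS_T = \sum_{i<j} d_{ij}^2 / n} and within-group
#' \eqn{SS_W = \sum_g \sum_{i<j \in g} d_{ij}^2 / n_g},
#' \eqn{F = ((SS_T - SS_W)/(a-1)) / (SS_W/(n-a))}. The p-value is
#' \eqn{(1 + \#\{F^* \ge F\}) / (1 + n_{perm})} over random relabelings.
#'
#' @param d Square symmetric dissimilarity matrix (or `dist`).
#' @param groups Grouping factor, one level per sample, each level with at
#'   least two samples.
#' @param n_perm Number of label permutations.
#' @param seed Optional seed for the permutations.
#' @return List of class `"permanova"`: `f`, `p_value`, `df`, `ss_among`,
#'   `ss_within`, `n_perm`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(ncol(d) == n, isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
  groups <- factor(groups)
  if (length(groups) != n) stop("permanova: groups must match the matrix dimension")
  if (any(table(groups) < 2)) stop("permanova: every group needs >= 2 samples")
  a <- nlevels(groups)
  d2 <- d^2
  ss_total <- sum(d2) / (2 * n)
  ssw_of <- function(g) {
    s <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      s <- s + sum(d2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  ssw <- ssw_of(groups)
  f_of <- function(w) ((ss_total - w) / (a - 1)) / (w / (n - a))
  f_obs <- f_of(ssw)
  if (!is.null(seed)) set.seed(seed)
  f_perm <- vapply(seq_len(n_perm), function(i) {
    f_of(ssw_of(sample(groups)))
  }, numeric(1))
  p <- (1 + sum(f_perm >= f_obs)) / (1 + n_perm)
  structure(list(f = f_obs, p_value = p, df = c(a - 1, n - a),
                 ss_among = ss_total - ssw, ss_within = ssw, n_perm = n_perm),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA  pseudo-F =", format(x$f, digits = 4),
      " df =", paste(x$df, collapse = ","),
      " p =", format(x$p_value, digits = 4),
      " (", x$n_perm, "permutations )\n")
  invisible(x)
}

#' Forward selection of environmental terms in distance-based RDA
#'
#' Constrained analysis of principal coordinates: the dissimilarity matrix is
#' embedded by principal coordinates and constrained on environmental
#' variables (via [vegan::dbrda()]). Starting from the null model, the
#' candidate term adding the most constrained inertia among those whose
#' marginal permutation p-value (conditioned on terms already selected) is at
#' most `alpha` is added; selection stops when no candidate passes.
#'
#' Negative principal-coordinate eigenvalues are left uncorrected (no Lingoes
#' correction); this is recorded in the result's `note`.
#'
#' @param d Dissimilarity matrix (or `dist`).
#' @param env Data frame of numeric environmental variables; standardized to
#'   z-scores internally. A constant column is an error.
#' @param n_perm Permutations for each marginal test.
#' @param alpha Inclusion threshold on the permutation p-value.
#' @param seed Optional seed making the whole selection deterministic.
#' @return List of class `"dbrda_selection"`: `terms` (data frame of selected
#'   terms in order with added inertia, pseudo-F and p), `scores` (first two
#'   constrained axis scores per sample, NULL when nothing selected),
#'   `note`.
#' @export
forward_select_dbrda <- function(d, env, n_perm = 999, alpha = 0.05, seed = NULL) {
  d <- stats::as.dist(as.matrix(d))
  env <- as.data.frame(env)
  if (!all(vapply(env, is.numeric, logical(1)))) stop("env must be all numeric")
  sds <- vapply(env, stats::sd, numeric(1))
  if (any(sds == 0)) {
    stop("constant environmental column(s): ",
         paste(names(env)[sds == 0], collapse = ", "))
  }
  envz <- as.data.frame(scale(env))
  if (!is.null(seed)) set.seed(seed)

  selected <- character(0)
  rows <- list()
  candidates <- names(envz)
  repeat {
    remaining <- setdiff(candidates, selected)
    if (length(remaining) == 0L) break
    stats_tab <- lapply(remaining, function(term) {
      rhs <- term
      if (length(selected) > 0L) {
        rhs <- paste(term, "+ Condition(", paste(selected, collapse = " + "), ")")
      }
      fml <- stats::as.formula(paste("d ~", rhs))
      fit <- vegan::dbrda(fml, data = envz)
      an <- vegan::anova.cca(fit, permutations = n_perm)
      data.frame(term = term,
                 inertia = fit$CCA$tot.chi,
                 f = an$F[1],
                 p = an[["Pr(>F)"]][1],
                 stringsAsFactors = FALSE)
    })
    stats_tab <- do.call(rbind, stats_tab)
    ok <- stats_tab[stats_tab$p <= alpha, , drop = FALSE]
    if (nrow(ok) == 0L) break
    best <- ok[which.max(ok$inertia), , drop = FALSE]
    selected <- c(selected, best$term)
    rows[[length(rows) + 1L]] <- best
  }

  terms <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(term = character(0), inertia = numeric(0),
               f = numeric(0), p = numeric(0))
  scores <- NULL
  if (length(selected) > 0L) {
    final <- vegan::dbrda(stats::as.formula(
      paste("d ~", paste(selected, collapse = " + "))), data = envz)
    k <- min(2L, ncol(final$CCA$u))
    scores <- vegan::scores(final, display = "sites", choices = seq_len(k))
  }
  structure(list(terms = terms, scores = scores,
                 note = "negative PCoA eigenvalues uncorrected (no Lingoes correction)"),
            class = "dbrda_selection")
}

#' Community composition index by principal component analysis
#'
#' Converts the count table to relative abundances, column-centers (no
#' scaling) and extracts the first two principal components as a compact
#' index of community composition.
#'
#' @param x Count table (samples x ASVs), at least 3 samples.
#' @return List: `scores` (data frame `sample_id`, `PC1`, `PC2`) and
#'   `explained` (variance fractions of all components, non-increasing,
#'   summing to at most 1).
#' @export
community_pca <- function(x) {
  x <- validate_count_table(x)
  if (nrow(x) < 3L) stop("community_pca: need at least 3 samples")
  rel <- x / rowSums(x)
  pr <- stats::prcomp(rel, center = TRUE, scale. = FALSE)
  expl <- pr$sdev^2 / sum(pr$sdev^2)
  k <- min(2L, ncol(pr$x))
  sc <- as.data.frame(pr$x[, seq_len(k), drop = FALSE])
  if (k == 1L) sc$PC2 <- 0
  data_out <- data.frame(sample_id = rownames(x), PC1 = sc$PC1, PC2 = sc$PC2,
                         stringsAsFactors = FALSE)
  list(scores = data_out, explained = expl)
}

#' One-way ANOVA with Tukey HSD compact letter display
#'
#' Classic group comparison: one-way ANOVA F test followed by Tukey honest
#' significant differences at alpha = 0.05, compressed to a letter display in
#' which groups sharing a letter are not significantly different. Letters are
#' the maximal cliques of the graph of non-significant pairs, ordered by
#' descending group mean.
#'
#' @param values Numeric response, one value per observation.
#' @param groups Grouping factor (>= 2 levels, each >= 2 observations).
#' @param alpha Significance level for the letter display.
#' @return List of class `"group_compare"`: `f`, `p_value`, `tukey` (matrix of
#'   adjusted pairwise p-values), `letters` (named character vector of letter
#'   codes per group), `means`.
#' @export
group_compare <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  if (nlevels(groups) < 2L) stop("group_compare: need >= 2 groups")
  if (any(table(groups) < 2L)) stop("group_compare: every group needs >= 2 observations")
  if (all(tapply(values, groups, stats::sd) == 0)) {
    stop("group_compare: zero within-group variance in every group")
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  lev <- levels(groups)
  k <- length(lev)
  padj <- matrix(1, k, k, dimnames = list(lev, lev))
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      r <- intersect(c(paste0(lev[j], "-", lev[i]), paste0(lev[i], "-", lev[j])),
                     rownames(tk))[1]
      padj[lev[i], lev[j]] <- padj[lev[j], lev[i]] <- tk[r, "p adj"]
    }
  }
  means <- tapply(values, groups, mean)
  letters_vec <- tukey_letters(padj, means, alpha)
  structure(list(f = tab$`F value`[1], p_value = tab$`Pr(>F)`[1],
                 tukey = padj, letters = letters_vec, means = means),
            class = "group_compare")
}

# Compact letter display: letters are maximal cliques of the non-significant
# pair graph, ordered so that 'a' contains the largest group mean.
tukey_letters <- function(padj, means, alpha = 0.05) {
  lev <- rownames(padj)
  nonsig <- padj > alpha
  diag(nonsig) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(nonsig, mode = "undirected")
  cliques <- igraph::max_cliques(g)
  cl_max_mean <- vapply(cliques, function(cl) max(means[lev[as.integer(cl)]]), numeric(1))
  cliques <- cliques[order(-cl_max_mean)]
  out <- stats::setNames(rep("", length(lev)), lev)
  for (i in seq_along(cliques)) {
    members <- lev[as.integer(cliques[[i]])]
    out[members] <- paste0(out[members], letters[i])
  }
  out
}
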