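#' Spearman correlation and p-value matrices for a community table
#'
#' Rank correlations (average ranks for ties) between all pairs of ASVs,
#' computed on per-sample relative abundances. P-values use the t
#' approximation with n - 2 degrees of freedom. ASVs present in fewer than
#' `min_occurrence` of the samples, and constant ASVs, are excluded before
#' correlation (correlations among mostly-zero vectors are spurious).
#'
#' @param x Count table (samples x ASVs) or a nonnegative abundance matrix.
#' @param min_occurrence Minimum fraction of samples in which an ASV must be
#'   present (nonzero) to enter the correlation matrix.
#' @return List: `rho` and `p` (symmetric matrices over the retained ASVs,
#'   unit diagonal / NA diagonal respectively), `n` (samples used), `kept`
#'   (retained ASV ids).
#' @export
spearman_matrix <- function(x, min_occurrence = 0.2) {
  stopifnot(is.matrix(x), nrow(x) >= 5)
  rel <- x / rowSums(x)
  occ <- colMeans(rel > 0)
  keep <- occ >= min_occurrence
  const <- apply(rel, 2, function(v) length(unique(v)) == 1L)
  if (any(const & keep)) {
    message("spearman_matrix: excluding ", sum(const & keep),
            " constant ASV column(s)")
    keep <- keep & !const
  }
  if (sum(keep) < 2L) stop("spearman_matrix: fewer than 2 ASVs pass the occurrence filter")
  rel <- rel[, keep, drop = FALSE]
  n <- nrow(rel)
  rho <- stats::cor(rel, method = "spearman")
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- NA_real_
  list(rho = rho, p = p, n = n, kept = colnames(rel))
}

#' Build a co-occurrence network from correlation matrices
#'
#' An undirected edge joins two ASVs when the absolute Spearman coefficient
#' strictly exceeds `r_threshold` and the p-value is strictly below
#' `p_threshold` (a coefficient of exactly the threshold is excluded). No
#' multiple-testing correction is applied by default (the raw-p convention of
#' correlation-threshold networks); set `fdr = TRUE` to filter on
#' Benjamini-Hochberg adjusted p-values instead.
#'
#' @param rho,p Symmetric matrices as returned by [spearman_matrix()].
#' @param r_threshold Absolute correlation threshold (strict).
#' @param p_threshold P-value threshold (strict).
#' @param drop_isolated Drop nodes with no edges from the node set (default).
#' @param fdr Filter on BH-adjusted p-values.
#' @return Object of class `"cooc_network"`: `nodes` (ASV ids), `edges`
#'   (data frame `from`, `to`, `rho`, `sign`, `p`), `params`.
#' @export
build_network <- function(rho, p, r_threshold = 0.6, p_threshold = 0.01,
                          drop_isolated = TRUE, fdr = FALSE) {
  stopifnot(is.matrix(rho), identical(dim(rho), dim(p)))
  ids <- colnames(rho)
  ut <- upper.tri(rho)
  pv <- p
  if (fdr) pv[ut] <- stats::p.adjust(p[ut], method = "BH")
  keep <- which(ut & abs(rho) > r_threshold & pv < p_threshold, arr.ind = TRUE)
  edges <- data.frame(
    from = ids[keep[, 1]],
    to = ids[keep[, 2]],
    rho = rho[keep],
    sign = ifelse(rho[keep] > 0, "positive", "negative"),
    p = pv[keep],
    stringsAsFactors = FALSE
  )
  nodes <- if (drop_isolated) sort(unique(c(edges$from, edges$to))) else ids
  net <- structure(list(nodes = nodes, edges = edges,
                        params = list(r_threshold = r_threshold,
                                      p_threshold = p_threshold,
                                      fdr = fdr,
                                      drop_isolated = drop_isolated,
                                      n_samples = NA_integer_)),
                   class = "cooc_network")
  if (nrow(edges) == 0L) warning("build_network: empty network (no edge passes the thresholds)")
  net
}

#' @export
print.cooc_network <- function(x, ...) {
  cat("Co-occurrence network:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges (|rho| >", x$params$r_threshold, ", p <", x$params$p_threshold, ")\n")
  invisible(x)
}

#' Convert a co-occurrence network to an igraph graph
#'
#' @param net A `cooc_network`.
#' @return An undirected [igraph::igraph] graph with edge attributes `rho`,
#'   `sign`, `p`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "cooc_network"))
  igraph::graph_from_data_frame(net$edges,
                                vertices = data.frame(name = net$nodes),
                                directed = FALSE)
}

#' Ten topological properties of a co-occurrence network
#'
#' Computes node count (NN), edge count (NE), connectance (realized fraction
#' of possible edges), average degree (AD = 2 NE / NN), global clustering
#' coefficient (GCC, transitivity), average local clustering coefficient
#' (ACC; nodes of degree < 2 contribute 0), average neighborhood connectivity
#' (AN, mean over nodes of the mean degree of their neighbors; degree-0 nodes
#' contribute 0), average degree centrality (ADC = AD / (NN - 1)), Freeman
#' degree centralization (DC = sum(kmax - ki) / ((NN-1)(NN-2))) and the
#' number of positive edges. Degenerate graphs (NN < 3) return 0 for GCC,
#' ACC and DC by convention, recorded in the `degenerate` attribute.
#'
#' @param net A `cooc_network` (may be empty or disconnected).
#' @return One-row data frame with columns `NN`, `NE`, `connectance`, `AD`,
#'   `GCC`, `ACC`, `AN`, `ADC`, `DC`, `n_positive_edges`.
#' @export
topology <- function(net) {
  stopifnot(inherits(net, "cooc_network"))
  nn <- length(net$nodes)
  ne <- nrow(net$edges)
  if (nn == 0L) {
    out <- data.frame(NN = 0, NE = 0, connectance = 0, AD = 0, GCC = 0,
                      ACC = 0, AN = 0, ADC = 0, DC = 0, n_positive_edges = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  connectance <- if (nn >= 2) ne / (nn * (nn - 1) / 2) else 0
  ad <- 2 * ne / nn
  if (nn >= 3) {
    gcc <- igraph::transitivity(g, type = "global")
    if (is.nan(gcc)) gcc <- 0
    loc <- igraph::transitivity(g, type = "local")
    loc[is.nan(loc)] <- 0
    acc <- mean(loc)
    dc <- sum(max(deg) - deg) / ((nn - 1) * (nn - 2))
  } else {
    gcc <- acc <- dc <- 0
  }
  an_per_node <- vapply(seq_len(nn), function(i) {
    nb <- igraph::neighbors(g, i)
    if (length(nb) == 0L) 0 else mean(deg[nb])
  }, numeric(1))
  an <- mean(an_per_node)
  adc <- if (nn >= 2) ad / (nn - 1) else 0
  out <- data.frame(NN = nn, NE = ne, connectance = connectance, AD = ad,
                    GCC = gcc, ACC = acc, AN = an, ADC = adc, DC = dc,
                    n_positive_edges = sum(net$edges$sign == "positive"))
  attr(out, "degenerate") <- nn < 3
  out
}

#' Per-sample induced subnetwork
#'
#' The subgraph of a habitat-level network induced by the ASVs detected
#' (nonzero abundance) in one sample; edges are restricted to pairs with both
#' endpoints present.
#'
#' @param net A `cooc_network` built from the habitat's full sample set.
#' @param sample_counts Named numeric vector: one sample's row of the count
#'   table (names are ASV ids).
#' @return A `cooc_network` on the present ASVs.
#' @export
sample_subnetwork <- function(net, sample_counts) {
  stopifnot(inherits(net, "cooc_network"), !is.null(names(sample_counts)))
  present <- names(sample_counts)[sample_counts > 0]
  nodes <- intersect(net$nodes, present)
  edges <- net$edges[net$edges$from %in% nodes & net$edges$to %in% nodes, ,
                     drop = FALSE]
  if (length(nodes) == 0L) warning("sample_subnetwork: sample contains no network ASVs")
  structure(list(nodes = nodes, edges = edges, params = net$params),
            class = "cooc_network")
}

topology_metrics <- c("NN", "NE", "connectance", "AD", "GCC", "ACC", "AN",
                      "ADC", "DC", "n_positive_edges")

#' Network complexity index from per-sample topology profiles
#'
#' Each topological property is min-max standardized across all samples,
#' \eqn{(X_{raw} - X_{min}) / (X_{max} - X_{min})}, and the complexity index
#' is the unweighted mean of the ten standardized scores. A metric with zero
#' range across samples contributes 0 and is flagged.
#'
#' @param profiles Data frame with a `sample_id` column and the ten topology
#'   metric columns (one row per sample), e.g. built by row-binding
#'   [topology()] outputs of [sample_subnetwork()]s.
#' @return Data frame `sample_id`, the ten standardized scores (suffix
#'   `_std`), and `complexity`; the names of zero-range metrics are attached
#'   as attribute `"zero_range"`.
#' @export
complexity_index <- function(profiles) {
  stopifnot(is.data.frame(profiles), "sample_id" %in% names(profiles))
  miss <- setdiff(topology_metrics, names(profiles))
  if (length(miss) > 0L) stop("complexity_index: missing metric column(s): ",
                              paste(miss, collapse = ", "))
  if (nrow(profiles) < 2L) {
    stop("complexity_index: min-max standardization needs >= 2 samples")
  }
  std <- matrix(0, nrow(profiles), length(topology_metrics),
                dimnames = list(NULL, paste0(topology_metrics, "_std")))
  zero_range <- character(0)
  for (i in seq_along(topology_metrics)) {
    v <- profiles[[topology_metrics[i]]]
    rng <- range(v)
    if (diff(rng) == 0) {
      zero_range <- c(zero_range, topology_metrics[i])
    } else {
      std[, i] <- (v - rng[1]) / diff(rng)
    }
  }
  if (length(zero_range) == length(topology_metrics)) {
    stop("complexity_index: every metric has zero range across samples")
  }
  out <- data.frame(sample_id = profiles$sample_id, std,
                    complexity = rowMeans(std), stringsAsFactors = FALSE)
  attr(out, "zero_range") <- zero_range
  out
}

#' Zi-Pi classification of network nodes
#'
#' Modules are found by greedy modularity maximization
#' ([igraph::cluster_fast_greedy()], deterministic for a given graph). For
#' node i in module s, the within-module degree z-score is
#' \eqn{z_i = (k_{is} - \bar k_s) / sd(k_s)} over the within-module degrees
#' of module s (zi = 0 when the sd is 0), and the participation coefficient
#' is \eqn{p_i = 1 - \sum_s (k_{is}/k_i)^2}. Nodes are sorted into
#' peripherals (zi <= 2.5, pi <= 0.62), connectors (zi <= 2.5, pi > 0.62),
#' module hubs (zi > 2.5, pi <= 0.62) and network hubs (zi > 2.5, pi > 0.62);
#' boundary values fall in the "<=" class. Connectors, module hubs and
#' network hubs are the keystone categories.
#'
#' @param net A `cooc_network` with at least one edge.
#' @param seed Accepted for interface symmetry; the greedy module detection
#'   is deterministic and does not consume randomness.
#' @return Data frame `asv_id`, `module`, `zi`, `pi`, `category` (factor with
#'   levels peripheral, connector, module_hub, network_hub).
#' @export
zi_pi <- function(net, seed = NULL) {
  stopifnot(inherits(net, "cooc_network"))
  if (nrow(net$edges) == 0L) stop("zi_pi: network has no edges")
  g <- as_igraph(net)
  memb <- igraph::membership(igraph::cluster_fast_greedy(g))
  ids <- igraph::V(g)$name
  mod <- as.integer(memb)
  names(mod) <- ids
  deg <- igraph::degree(g)
  # within-module degree of every node into every module
  ek <- igraph::as_edgelist(g)
  n <- length(ids)
  nmod <- max(mod)
  kis <- matrix(0L, n, nmod, dimnames = list(ids, NULL))
  for (e in seq_len(nrow(ek))) {
    a <- ek[e, 1]; b <- ek[e, 2]
    kis[a, mod[b]] <- kis[a, mod[b]] + 1L
    kis[b, mod[a]] <- kis[b, mod[a]] + 1L
  }
  own <- kis[cbind(seq_len(n), mod[ids])]
  zi <- numeric(n)
  for (s in seq_len(nmod)) {
    idx <- which(mod[ids] == s)
    mu <- mean(own[idx])
    sdv <- stats::sd(own[idx])
    zi[idx] <- if (length(idx) < 2L || is.na(sdv) || sdv == 0) 0 else
      (own[idx] - mu) / sdv
  }
  pi_coef <- ifelse(deg[ids] == 0, 0,
                    1 - rowSums((kis / pmax(deg[ids], 1))^2))
  data.frame(asv_id = ids, module = mod[ids], zi = zi, pi = pi_coef,
             category = zipi_category(zi, pi_coef),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Four-quadrant Zi-Pi node role
#'
#' Applies the standard thresholds zi = 2.5 and pi = 0.62: peripherals
#' (zi <= 2.5, pi <= 0.62), connectors (zi <= 2.5, pi > 0.62), module hubs
#' (zi > 2.5, pi <= 0.62), network hubs (zi > 2.5, pi > 0.62).
#'
#' @param zi Within-module degree z-score(s).
#' @param pi Participation coefficient(s).
#' @return Factor with levels peripheral, connector, module_hub, network_hub.
#' @export
zipi_category <- function(zi, pi) {
  category <- ifelse(zi > 2.5,
                     ifelse(pi > 0.62, "network_hub", "module_hub"),
                     ifelse(pi > 0.62, "connector", "peripheral"))
  factor(category, levels = c("peripheral", "connector", "module_hub",
                              "network_hub"))
}
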