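# Independent reference implementations used as oracles. Deliberately naive
# (double loops over an adjacency matrix) and kept free of igraph so they
# cannot share a defect with the code under test.

# Topology profile of an undirected simple graph given its adjacency matrix.
naive_topology <- function(adj) {
  nn <- nrow(adj)
  deg <- rowSums(adj)
  ne <- sum(adj) / 2
  connectance <- if (nn >= 2) ne / (nn * (nn - 1) / 2) else 0
  ad <- if (nn > 0) 2 * ne / nn else 0
  tri_at <- function(i) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) return(0)
    cnt <- 0
    for (a in seq_along(nb)) {
      for (b in seq_along(nb)) {
        if (a < b && adj[nb[a], nb[b]] == 1) cnt <- cnt + 1
      }
    }
    cnt
  }
  if (nn >= 3) {
    closed <- sum(vapply(seq_len(nn), tri_at, numeric(1)))
    triples <- sum(deg * (deg - 1) / 2)
    gcc <- if (triples > 0) closed / triples else 0
    loc <- vapply(seq_len(nn), function(i) {
      if (deg[i] < 2) return(0)
      tri_at(i) / (deg[i] * (deg[i] - 1) / 2)
    }, numeric(1))
    acc <- mean(loc)
    dc <- sum(max(deg) - deg) / ((nn - 1) * (nn - 2))
  } else {
    gcc <- acc <- dc <- 0
  }
  an <- if (nn > 0) {
    mean(vapply(seq_len(nn), function(i) {
      nb <- which(adj[i, ] == 1)
      if (length(nb) == 0) 0 else mean(deg[nb])
    }, numeric(1)))
  } else 0
  adc <- if (nn >= 2) ad / (nn - 1) else 0
  list(NN = nn, NE = ne, connectance = connectance, AD = ad, GCC = gcc,
       ACC = acc, AN = an, ADC = adc, DC = dc)
}

# Wrap an adjacency matrix (optionally with signed weights) as a cooc_network.
adj_to_network <- function(adj, rho = NULL) {
  ids <- rownames(adj)
  if (is.null(ids)) ids <- sprintf("n%02d", seq_len(nrow(adj)))
  dimnames(adj) <- list(ids, ids)
  idx <- which(upper.tri(adj) & adj != 0, arr.ind = TRUE)
  r <- if (is.null(rho)) rep(0.9, nrow(idx)) else rho
  edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                      rho = r[seq_len(nrow(idx))],
                      sign = rep_len("positive", nrow(idx)),
                      p = rep_len(1e-6, nrow(idx)), stringsAsFactors = FALSE)
  edges$sign <- ifelse(edges$rho > 0, "positive", "negative")
  structure(list(nodes = ids, edges = edges,
                 params = list(r_threshold = 0.6, p_threshold = 0.01,
                               fdr = FALSE, drop_isolated = FALSE,
                               n_samples = NA_integer_)),
            class = "cooc_network")
}

random_graph <- function(nn, p_edge = 0.3) {
  adj <- matrix(0L, nn, nn)
  adj[upper.tri(adj)] <- stats::rbinom(nn * (nn - 1) / 2, 1, p_edge)
  adj <- adj + t(adj)
  dimnames(adj) <- list(sprintf("n%02d", seq_len(nn)), sprintf("n%02d", seq_len(nn)))
  adj
}

# Pseudo-F of a one-way design on a distance matrix, straight from the
# definition (no shared code with permanova()).
naive_pseudo_f <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- factor(groups)
  a <- nlevels(groups)
  sst <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) sst <- sst + d[i, j]^2
  sst <- sst / n
  ssw <- 0
  for (lev in levels(groups)) {
    idx <- which(groups == lev)
    if (length(idx) >= 2) {
      s <- 0
      for (i in seq_along(idx)) {
        for (j in seq_along(idx)) if (i < j) s <- s + d[idx[i], idx[j]]^2
      }
      ssw <- ssw + s / length(idx)
    }
  }
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

# Bray-Curtis from the closed form, double loop.
naive_bray <- function(x) {
  n <- nrow(x)
  out <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- 1 - 2 * sum(pmin(x[i, ], x[j, ])) / (sum(x[i, ]) + sum(x[j, ]))
    }
  }
  out
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

# Small field design used across tests where the full 128-sample default
# would be slow.
small_config <- function(seed = 1, ...) {
  synth_config(n_sites = 2, plots_per_site = 4, depths = c("0_5cm", "5_10cm"),
               n_asvs = 80, n_modules = 2, seed = seed, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
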