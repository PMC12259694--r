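test_that("Spearman matrix reproduces the rank formula, including ties", {
  set.seed(1)
  x <- matrix(rpois(10 * 4, 8), 10, 4)
  x[, 2] <- x[, 1] + 1L            # perfectly monotone pair
  x[, 3] <- max(x[, 1]) - x[, 1]   # anti-monotone pair
  # balance the row totals so relative abundances preserve the count ranks
  x <- cbind(x, 200L - rowSums(x))
  rownames(x) <- paste0("s", 1:10)
  colnames(x) <- paste0("a", 1:5)
  sp <- spearman_matrix(x, min_occurrence = 0)
  expect_equal(sp$rho["a1", "a2"], 1)
  expect_equal(sp$rho["a1", "a3"], -1)
  # rank-formula oracle with average ranks (ties present in Poisson draws)
  rel <- x / rowSums(x)
  r1 <- rank(rel[, 1]); r4 <- rank(rel[, 4])
  rho_hand <- sum((r1 - mean(r1)) * (r4 - mean(r4))) /
    sqrt(sum((r1 - mean(r1))^2) * sum((r4 - mean(r4))^2))
  expect_equal(sp$rho["a1", "a4"], rho_hand, tolerance = 1e-12)
  t_hand <- rho_hand * sqrt(8 / (1 - rho_hand^2))
  expect_equal(sp$p["a1", "a4"], 2 * pt(-abs(t_hand), 8), tolerance = 1e-12)
  expect_equal(sp$rho, t(sp$rho))
})

test_that("edge thresholds are strict and the filter is monotone", {
  ids <- c("x", "y", "z")
  rho <- matrix(c(1, 0.6, 0.95, 0.6, 1, -0.7, 0.95, -0.7, 1), 3, 3,
                dimnames = list(ids, ids))
  p <- matrix(1e-6, 3, 3, dimnames = list(ids, ids)); diag(p) <- NA
  net <- build_network(rho, p)
  ek <- edge_key(net$edges$from, net$edges$to)
  expect_false(edge_key("x", "y") %in% ek)   # rho exactly 0.6 excluded
  expect_true(edge_key("x", "z") %in% ek)
  expect_equal(net$edges$sign[net$edges$rho < 0], "negative")
  # p threshold strict as well
  p2 <- p; p2["x", "z"] <- p2["z", "x"] <- 0.01
  expect_false(edge_key("x", "z") %in%
    with(build_network(rho, p2)$edges, edge_key(from, to)))
  # raising the correlation threshold never adds edges
  set.seed(2)
  m <- 12
  rr <- stats::cor(matrix(rnorm(20 * m), 20, m), method = "spearman")
  dimnames(rr) <- list(paste0("a", 1:m), paste0("a", 1:m))
  pp <- matrix(1e-4, m, m, dimnames = dimnames(rr)); diag(pp) <- NA
  ne <- vapply(seq(0, 0.9, 0.1), function(thr) {
    nrow(suppressWarnings(build_network(rr, pp, r_threshold = thr))$edges)
  }, numeric(1))
  expect_true(all(diff(ne) <= 0))
  # empty network warns instead of failing
  expect_warning(build_network(rho, p, r_threshold = 0.99), "empty")
})

test_that("topology matches closed forms on canonical graphs", {
  tri <- adj_to_network(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3))
  tt <- topology(tri)
  expect_equal(tt$GCC, 1); expect_equal(tt$ACC, 1)
  expect_equal(tt$connectance, 1); expect_equal(tt$AD, 2)
  expect_equal(tt$DC, 0)
  star <- matrix(0, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1
  st <- topology(adj_to_network(star))
  expect_equal(st$DC, 1); expect_equal(st$GCC, 0)
  expect_equal(st$AD, 8 / 5)
  expect_equal(st$AN, (1 + 4 * 4) / 5)  # hub sees degree-1 spokes, spokes see the hub
  # degenerate sizes fall back to the stated conventions
  empty <- structure(list(nodes = character(0),
                          edges = data.frame(from = character(0),
                                             to = character(0), rho = numeric(0),
                                             sign = character(0), p = numeric(0)),
                          params = list()), class = "cooc_network")
  expect_true(all(topology(empty) == 0))
  pair <- adj_to_network(matrix(c(0, 1, 1, 0), 2, 2))
  tp <- topology(pair)
  expect_true(attr(tp, "degenerate"))
  expect_equal(tp$GCC, 0)
})

test_that("per-sample subnetworks are exact induced subgraphs", {
  adj <- matrix(0, 6, 6,
                dimnames = list(paste0("a", 1:6), paste0("a", 1:6)))
  pairs <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6), c(1, 6), c(2, 5))
  for (k in seq_len(nrow(pairs))) {
    adj[pairs[k, 1], pairs[k, 2]] <- adj[pairs[k, 2], pairs[k, 1]] <- 1
  }
  net <- adj_to_network(adj)
  all_present <- setNames(rep(3, 6), paste0("a", 1:6))
  sub_full <- sample_subnetwork(net, all_present)
  expect_setequal(sub_full$nodes, net$nodes)
  expect_equal(nrow(sub_full$edges), nrow(net$edges))
  # present at a1, a2, a3, a5: induced edges a1-a2, a2-a3, a2-a5 only
  some <- setNames(c(1, 2, 5, 0, 1, 0), paste0("a", 1:6))
  sub <- sample_subnetwork(net, some)
  expect_setequal(edge_key(sub$edges$from, sub$edges$to),
                  c(edge_key("a1", "a2"), edge_key("a2", "a3"),
                    edge_key("a2", "a5")))
  expect_warning(none <- sample_subnetwork(net, setNames(rep(0, 6), paste0("a", 1:6))),
                 "no network ASVs")
  expect_length(none$nodes, 0)
})

test_that("complexity index obeys the min-max contract and affine invariance", {
  profiles <- data.frame(sample_id = c("lo", "mid", "hi"),
                         NN = c(2, 5, 10), NE = c(1, 6, 20),
                         connectance = c(0.1, 0.4, 0.5), AD = c(1, 2.4, 4),
                         GCC = c(0, 0.3, 0.6), ACC = c(0, 0.25, 0.5),
                         AN = c(1, 2, 4), ADC = c(0.2, 0.5, 0.6),
                         DC = c(0, 0.2, 0.4), n_positive_edges = c(1, 5, 18))
  cx <- complexity_index(profiles)
  expect_equal(cx$complexity[cx$sample_id == "hi"], 1)
  expect_equal(cx$complexity[cx$sample_id == "lo"], 0)
  # hand value for the middle sample
  mids <- vapply(names(profiles)[-1], function(m) {
    v <- profiles[[m]]
    (v[2] - min(v)) / (max(v) - min(v))
  }, numeric(1))
  expect_equal(cx$complexity[cx$sample_id == "mid"], mean(mids),
               tolerance = 1e-12)
  # invariant to affine rescaling of any raw metric
  resc <- profiles
  resc$NE <- 100 + 7 * resc$NE
  resc$GCC <- 3 * resc$GCC - 1
  expect_equal(complexity_index(resc)$complexity, cx$complexity,
               tolerance = 1e-12)
  # zero-range metric contributes zero and is flagged
  flat <- profiles; flat$DC <- c(1, 1, 1)
  cf <- complexity_index(flat)
  expect_identical(attr(cf, "zero_range"), "DC")
  expect_true(all(cf$DC_std == 0))
  expect_error(complexity_index(profiles[1, ]), ">= 2 samples")
})

test_that("Zi-Pi closed forms, quadrants and label invariance hold", {
  expect_equal(as.character(zipi_category(c(3, 3, 1, 1), c(0.7, 0.5, 0.7, 0.5))),
               c("network_hub", "module_hub", "connector", "peripheral"))
  # boundary values fall in the '<=' class
  expect_equal(as.character(zipi_category(c(2.5, 2.5), c(0.62, 0.7))),
               c("peripheral", "connector"))

  # two 4-cliques joined by one bridge: every node keeps most links at home
  adj <- matrix(0, 8, 8, dimnames = list(paste0("a", 1:8), paste0("a", 1:8)))
  adj[1:4, 1:4] <- 1; adj[5:8, 5:8] <- 1; diag(adj) <- 0
  adj[4, 5] <- adj[5, 4] <- 1
  zp <- zi_pi(adj_to_network(adj))
  expect_equal(zp$pi[zp$asv_id == "a1"], 0)          # all neighbors in module
  expect_equal(zp$pi[zp$asv_id == "a4"], 1 - (3 / 4)^2 - (1 / 4)^2)
  expect_true(all(zp$pi >= 0 & zp$pi <= 1 - 1 / max(zp$module)))

  # a node with degree 4 split over 4 modules is a connector: build four
  # triangle modules plus one center attached to one vertex of each
  m <- matrix(0, 13, 13, dimnames = list(paste0("n", 1:13), paste0("n", 1:13)))
  for (k in 0:3) {
    idx <- 2 + k * 3 + 0:2
    m[idx, idx] <- 1
    m[1, idx[1]] <- m[idx[1], 1] <- 1
  }
  diag(m) <- 0
  zc <- zi_pi(adj_to_network(m))
  expect_equal(zc$pi[zc$asv_id == "n1"], 0.75)
  expect_equal(as.character(zc$category[zc$asv_id == "n1"]), "connector")

  # permuting node labels permutes the records identically
  perm <- c(3, 1, 2, 4, 8, 6, 7, 5)
  adj_p <- adj[perm, perm]
  zp_p <- zi_pi(adj_to_network(adj_p))
  both <- merge(zp, zp_p, by = "asv_id")
  expect_equal(both$zi.x, both$zi.y, tolerance = 1e-12)
  expect_equal(both$pi.x, both$pi.y, tolerance = 1e-12)

  expect_error(zi_pi(adj_to_network(matrix(0, 3, 3))), "no edges")
})

test_that("planted module hubs are recovered as keystones", {
  recall <- vapply(1:10, function(seed) {
    ds <- generate_dataset(synth_config(seed = seed, module_structure = "hub",
                                        n_satellites = 0, module_size = 12))
    filtered <- filter_rare_asvs(ds$counts, 10)
    sp <- spearman_matrix(filtered, 0.2)
    net <- build_network(sp$rho, sp$p)
    zp <- zi_pi(net)
    keystones <- zp$asv_id[zp$category != "peripheral"]
    mean(ds$truth$planted_keystones %in% keystones)
  }, numeric(1))
  expect_gte(mean(recall), 0.7)
})
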