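toy_table <- function(m, samples = NULL, asvs = NULL) {
  m <- as.matrix(m)
  rownames(m) <- samples %||% paste0("s", seq_len(nrow(m)))
  colnames(m) <- asvs %||% paste0("a", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  m
}

test_that("rare-ASV filter applies the dataset-wide total with a strict boundary", {
  x <- toy_table(rbind(c(4, 5, 2, 12),
                       c(3, 5, 0, 0),
                       c(2, 0, 1, 3)))
  # totals: 9, 10, 3, 15 -> 'fewer than 10 reads' removes a1 and a3
  out <- filter_rare_asvs(x, min_reads = 10)
  expect_identical(colnames(out), c("a2", "a4"))
  expect_identical(out, x[, c("a2", "a4")])
  expect_identical(filter_rare_asvs(x, min_reads = 0), x)
  expect_error(filter_rare_asvs(x, min_reads = 100), "all ASVs removed")
})

test_that("rarefaction subsamples to exact depth, deterministically", {
  set.seed(1)
  x <- toy_table(matrix(rpois(80, 40), 8, 10))
  out <- suppressWarnings(rarefy(x, depth = 100, seed = 5))
  expect_true(all(rowSums(out) == 100))
  expect_true(all(out <= x))
  expect_identical(out, suppressWarnings(rarefy(x, depth = 100, seed = 5)))
  # a sample holding exactly depth reads is returned unchanged
  y <- toy_table(rbind(c(60, 40), c(10, 20)))
  expect_identical(suppressWarnings(rarefy(y, depth = 100, seed = 1))["s1", ], y["s1", ])
  # under-depth samples are dropped with a message
  expect_message(out2 <- suppressWarnings(rarefy(y, depth = 100, seed = 1)),
                 "dropping 1")
  expect_identical(rownames(out2), "s1")
})

test_that("rarefaction preserves expected relative abundances", {
  set.seed(2)
  x <- toy_table(matrix(rpois(60, c(400, 100, 50, 20, 10, 5)), 10, 6,
                        byrow = TRUE))
  p_before <- colSums(x) / sum(x)
  mean_p <- Reduce(`+`, lapply(1:500, function(s) {
    r <- rarefy(x, depth = 300, seed = s)
    colSums(r) / sum(r)
  })) / 500
  abundant <- p_before > 0.05
  expect_true(all(abs(mean_p[abundant] - p_before[abundant]) /
                    p_before[abundant] < 0.02))
})

test_that("alpha diversity matches closed forms and the direct formula", {
  x <- toy_table(rbind(c(10, 0, 0, 0),
                       c(5, 5, 0, 0),
                       c(4, 3, 2, 1)))
  d <- alpha_diversity(x)
  expect_equal(d$richness, c(1L, 2L, 4L))
  expect_equal(d$shannon[1], 0)
  expect_equal(d$shannon[2], log(2))
  p <- c(4, 3, 2, 1) / 10
  expect_equal(d$shannon[3], -sum(p * log(p)))
  expect_true(all(d$shannon <= log(d$richness) + 1e-12))
  bad <- toy_table(rbind(c(1, 1), c(0, 0)))
  expect_error(alpha_diversity(bad), "zero-sum")
})

test_that("Bray-Curtis matches the closed form and the semimetric axioms", {
  x <- toy_table(rbind(c(2, 1, 0), c(0, 1, 3), c(2, 1, 0), c(5, 0, 0)))
  bc <- bray_curtis(x)
  expect_equal(bc["s1", "s2"], 5 / 7)       # 1 - 2*min-sum/total
  expect_equal(bc["s1", "s3"], 0)           # identical samples
  expect_equal(bc["s2", "s4"], 1)           # disjoint samples
  set.seed(3)
  for (i in 1:5) {
    y <- toy_table(matrix(rpois(48, 5), 6, 8))
    y[1, ] <- y[1, ] + 1L  # avoid zero-sum rows
    got <- bray_curtis(y)
    expect_equal(got, naive_bray(y), tolerance = 1e-12)
    expect_equal(got, t(got))
    expect_true(all(diag(got) == 0))
    expect_true(all(got >= 0 & got <= 1))
  }
})

test_that("PERMANOVA pseudo-F matches brute force and vegan, p is exact-minimal for separated groups", {
  set.seed(4)
  x <- matrix(rnorm(30), 6, 5)
  rownames(x) <- paste0("s", 1:6)
  d <- as.matrix(dist(x))
  g <- factor(rep(c("A", "B"), each = 3))
  res <- permanova(d, g, n_perm = 199, seed = 1)
  expect_equal(res$f, naive_pseudo_f(d, g), tolerance = 1e-12)
  ad <- vegan::adonis2(as.dist(d) ~ g, permutations = 19)
  expect_equal(res$f, ad$F[1], tolerance = 1e-8)
  # exhaustive permutation distribution: p from complete enumeration
  perms <- combn(6, 3)
  f_all <- apply(perms, 2, function(idx) {
    gg <- factor(ifelse(seq_len(6) %in% idx, "A", "B"))
    naive_pseudo_f(d, gg)
  })
  p_exact <- mean(f_all >= res$f - 1e-12)
  res_big <- permanova(d, g, n_perm = 999, seed = 2)
  expect_lt(abs(res_big$p_value - p_exact), 0.08)
  # two maximally separated clusters reach the minimal attainable p
  y <- rbind(matrix(rnorm(40, 0, 0.1), 10, 4), matrix(rnorm(40, 50, 0.1), 10, 4))
  rownames(y) <- paste0("t", 1:20)
  res2 <- permanova(as.matrix(dist(y)), rep(c("A", "B"), each = 10),
                    n_perm = 99, seed = 3)
  expect_equal(res2$p_value, 1 / 100)
  expect_error(permanova(d, factor(c("A", "A", "A", "A", "A", "B"))), ">= 2")
})

test_that("PERMANOVA p-values are uniform under an exchangeable null", {
  set.seed(5)
  p_vals <- vapply(1:300, function(i) {
    y <- matrix(rnorm(20 * 4), 20, 4)
    rownames(y) <- paste0("s", 1:20)
    permanova(as.matrix(dist(y)), rep(c("A", "B"), each = 10),
              n_perm = 99)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(p_vals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("community PCA satisfies its geometric contracts and an eigen oracle", {
  set.seed(6)
  x <- toy_table(matrix(rpois(20, 30) + 1L, 5, 4))
  res <- community_pca(x)
  expect_true(all(diff(res$explained) <= 1e-12))
  expect_lte(sum(res$explained), 1 + 1e-12)
  # oracle: eigen-decomposition of the covariance of centered proportions
  rel <- x / rowSums(x)
  cen <- scale(rel, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(cen))
  expect_equal(abs(res$scores$PC1), abs(as.numeric(cen %*% ev$vectors[, 1])),
               tolerance = 1e-9)
  # duplicated samples get identical scores
  x2 <- toy_table(rbind(x, x[1, , drop = FALSE]),
                  samples = c(rownames(x), "dup"))
  res2 <- community_pca(x2)
  expect_equal(res2$scores[res2$scores$sample_id == "dup", c("PC1", "PC2")],
               res2$scores[res2$scores$sample_id == "s1", c("PC1", "PC2")],
               ignore_attr = TRUE)
  # compositions varying along a single direction: PC1 carries all the variance
  r1 <- toy_table(rbind(c(20L, 80L), c(30L, 70L), c(50L, 50L), c(90L, 10L)))
  expect_equal(community_pca(r1)$explained[1], 1, tolerance = 1e-9)
  expect_error(community_pca(x[1:2, ]), "3 samples")
})

test_that("group comparison reproduces a textbook ANOVA and sensible letters", {
  vals <- c(6, 8, 4, 5, 3, 4, 8, 12, 9, 11, 13, 8, 13, 9, 11, 8, 12, 13, 10, 15)
  grp <- rep(c("g1", "g2", "g3", "g4"), each = 5)
  res <- group_compare(vals, grp)
  # hand ANOVA decomposition
  gm <- mean(vals)
  ssb <- sum(tapply(vals, grp, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(vals, grp, function(v) sum((v - mean(v))^2)))
  f_hand <- (ssb / 3) / (ssw / 16)
  expect_equal(res$f, f_hand, tolerance = 1e-12)
  # same means share a letter; far-apart groups differ
  set.seed(7)
  v2 <- rnorm(30)
  r2 <- group_compare(v2, rep(c("a", "b", "c"), 10))
  expect_length(unique(r2$letters), 1L)
  v3 <- c(rnorm(10), rnorm(10, 100))
  r3 <- group_compare(v3, rep(c("lo", "hi"), each = 10))
  expect_false(any(grepl(r3$letters["lo"], r3$letters["hi"], fixed = TRUE)))
  expect_error(group_compare(rep(1, 10), rep(c("a", "b"), each = 5)),
               "zero within-group variance")
})

test_that("forward db-RDA selection finds a planted gradient and resists noise", {
  set.seed(8)
  n <- 40
  grad <- sort(rnorm(n))
  # community driven by the gradient
  x <- toy_table(matrix(rpois(n * 12, lambda = exp(2 + outer(grad, seq(-1, 1, length.out = 12)))),
                        n, 12))
  x[rowSums(x) == 0, 1] <- 1L
  d <- bray_curtis(x)
  env <- data.frame(driver = grad, junk1 = rnorm(n), junk2 = rnorm(n))
  sel <- forward_select_dbrda(d, env, n_perm = 199, seed = 1)
  expect_equal(sel$terms$term[1], "driver")
  expect_true(all(sel$terms$p <= 0.05))
  expect_equal(nrow(sel$scores), n)
  # deterministic given a seed
  sel2 <- forward_select_dbrda(d, env, n_perm = 199, seed = 1)
  expect_identical(sel$terms, sel2$terms)
  # constant column rejected by name
  expect_error(forward_select_dbrda(d, data.frame(flat = rep(1, n))), "flat")
  # pure-noise environments select nothing most of the time
  hits <- vapply(1:40, function(i) {
    y <- matrix(rpois(20 * 8, 10), 20, 8)
    rownames(y) <- paste0("s", 1:20)
    colnames(y) <- paste0("a", 1:8)
    storage.mode(y) <- "integer"
    dn <- bray_curtis(y)
    nrow(forward_select_dbrda(dn, data.frame(e = rnorm(20)), n_perm = 99,
                              seed = i)$terms) > 0
  }, logical(1))
  expect_lte(mean(hits), 0.1)
})
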