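rand_expr <- function(nr, nc, seed = 1, mean = 0) {
  set.seed(seed)
  m <- matrix(rnorm(nr * nc, mean = mean), nr, nc,
              dimnames = list(paste0("g", seq_len(nr)),
                              paste0("s", seq_len(nc))))
  expr_matrix(m, "raw")
}

test_that("pca matches a direct covariance eigendecomposition", {
  m <- rand_expr(20, 10, seed = 21)
  p <- pca(m)
  # variance fractions sum to one and are non-increasing
  expect_equal(sum(p$all_variance_fractions), 1, tolerance = 1e-9)
  expect_true(all(diff(p$variance_fractions) <= 1e-12))
  # loadings orthonormal
  gram <- crossprod(p$loadings)
  expect_equal(gram, diag(ncol(p$loadings)), tolerance = 1e-9,
               ignore_attr = TRUE)
  # eigensolve oracle: eigenvalues of the sample covariance of t(m)
  x <- t(unclass(m))
  ev <- eigen(cov(x), symmetric = TRUE)$values
  expect_equal(p$all_variance_fractions, (ev / sum(ev))[seq_along(p$all_variance_fractions)],
               tolerance = 1e-8)
  # full-rank scores reproduce the centered data
  centered <- sweep(x, 2L, colMeans(x))
  expect_equal(p$scores %*% t(p$loadings), centered, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("rank-1 data loads entirely on the first component", {
  pattern <- rnorm(15)
  m <- outer(pattern, c(1, 2, 3, 5, 8))
  dimnames(m) <- list(paste0("g", 1:15), paste0("s", 1:5))
  p <- pca(expr_matrix(m, "raw"))
  expect_equal(p$variance_fractions[1], 1, tolerance = 1e-12)
  # sign convention: largest-magnitude loading entry is positive
  for (j in seq_len(ncol(p$loadings))) {
    expect_gte(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }
})

test_that("pca input validation", {
  m <- rand_expr(6, 4)
  expect_error(pca(m, n_components = 10), "exceeds")
  expect_error(pca(expr_matrix(matrix(1:4, 2, 2,
    dimnames = list(c("a", "b"), c("x", "y"))) * 1.0, "raw"),
    n_components = 0), "n_components")
})

test_that("silhouette separates separated blobs and is ~0 under permutation", {
  set.seed(31)
  scores <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
                  matrix(rnorm(40, 10, 0.1), 20, 2))
  labels <- rep(c("x", "y"), each = 20)
  sep <- cluster_separation(scores, labels, k = 2L)
  expect_gt(sep$overall, 0.9)
  perms <- replicate(20, {
    cluster_separation(scores, sample(labels), k = 2L)$overall
  })
  expect_lt(abs(mean(perms)), 0.05)
  # groups of size < 2 are excluded with a warning
  expect_warning(
    cluster_separation(scores, c("solo", labels[-1]), k = 2L),
    "solo"
  )
})

test_that("normalization mode flips whether tissue or species dominates", {
  tissue_wins <- 0L; species_wins <- 0L
  for (seed in 1:3) {
    d <- tiny_design(seed = seed)
    u <- generate_universe(d)
    e <- generate_expression(d, u)
    pm <- build_pairing_map(u$orthologs, u$probes_a, u$probes_b)
    merge_mode <- function(fun) {
      merge_matrices(fun(e$expr_a), fun(e$expr_b), pm$pairs,
                     e$annot_a, e$annot_b)
    }
    mg_p <- merge_mode(normalize_by_probeset)
    p <- pca(mg_p, 3L)
    sil_t <- cluster_separation(p$scores, mg_p$annotation$tissue, 3L)$overall
    sil_s <- cluster_separation(p$scores, mg_p$annotation$species, 3L)$overall
    tissue_wins <- tissue_wins + (sil_t > sil_s)
    mg_s <- merge_mode(normalize_by_sample)
    ps <- pca(mg_s, 3L)
    sil_t2 <- cluster_separation(ps$scores, mg_s$annotation$tissue, 3L)$overall
    sil_s2 <- cluster_separation(ps$scores, mg_s$annotation$species, 3L)$overall
    species_wins <- species_wins + (sil_s2 > sil_t2)
  }
  expect_identical(tissue_wins, 3L)
  expect_identical(species_wins, 3L)
})

test_that("group-mean correlation matrix equals a brute-force pair loop", {
  set.seed(41)
  m <- matrix(rnorm(10 * 12), 10, 12,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:12)))
  groups <- rep(c("g1", "g2", "g3"), each = 4)
  annot <- data.frame(sample_id = colnames(m),
                      species = "A", tissue = groups)
  tc <- tissue_correlation_matrix(expr_matrix(m, "raw"), annot)
  oracle <- tissue_cor_oracle(m, paste("A", groups, sep = "."))
  expect_equal(tc$values, oracle, tolerance = 1e-12)
  # symmetry and range
  expect_equal(tc$values, t(tc$values), tolerance = 1e-12)
  expect_true(all(tc$values >= -1 & tc$values <= 1))
})

test_that("copy groups and noise groups behave as expected", {
  set.seed(51)
  one <- rnorm(400)
  # t1 and t2 are exact copies of the same expression pattern
  m <- cbind(one, one, one, one, one, one, matrix(rnorm(400 * 3), 400, 3))
  dimnames(m) <- list(paste0("g", 1:400), paste0("s", 1:9))
  annot <- data.frame(sample_id = colnames(m), species = "A",
                      tissue = rep(c("t1", "t2", "noise"), each = 3))
  tc <- tissue_correlation_matrix(expr_matrix(m, "raw"), annot)
  # exact copies: cross-group mean equals within-group mean
  expect_equal(tc$values["A.t1", "A.t2"], tc$values["A.t1", "A.t1"],
               tolerance = 1e-12)
  # uncorrelated noise group: entry near 0 at 3/sqrt(n_rows)
  expect_lt(abs(tc$values["A.t1", "A.noise"]), 3 / sqrt(400))
})

test_that("complete-linkage clustering equals a hand agglomeration trace", {
  # 4 x 2 feature matrix with unambiguous merge order
  vals <- matrix(c(0, 0,
                   0.1, 0,
                   5, 5,
                   5.3, 5), 4, 2, byrow = TRUE,
                 dimnames = list(c("r1", "r2", "r3", "r4"), NULL))
  dd <- hierarchical_cluster(vals)
  h <- dd$hclust
  # trace: r1+r2 at 0.1; r3+r4 at 0.3; then both clusters at complete
  # linkage distance max over cross pairs = dist(r1, r4)
  expect_equal(h$height, c(0.1, 0.3, sqrt(5.3^2 + 5^2)), tolerance = 1e-12)
  expect_identical(sort(dd$order[1:2]), c("r1", "r2"))
  expect_identical(sort(dd$order[3:4]), c("r3", "r4"))
  # two identical rows join first at height 0
  vals2 <- matrix(c(1, 1, 1, 1, 9, 9), 3, 2, byrow = TRUE,
                  dimnames = list(c("a", "b", "c"), NULL))
  h2 <- hierarchical_cluster(vals2)$hclust
  expect_equal(h2$height[1], 0)
  expect_identical(sort(h2$labels[-h2$merge[1, ]]), c("a", "b"))
  # 2 groups: single join
  vals3 <- vals[1:2, , drop = FALSE]
  expect_length(hierarchical_cluster(vals3)$merge_heights, 1L)
})

test_that("conserved tissue signal pairs species groups in the tree", {
  sibs <- numeric(0)
  same_gt_off <- numeric(0)
  for (seed in 1:5) {
    d <- tiny_design(seed = seed)
    u <- generate_universe(d)
    e <- generate_expression(d, u)
    pm <- build_pairing_map(u$orthologs, u$probes_a, u$probes_b)
    mg <- merge_matrices(normalize_by_probeset(e$expr_a),
                         normalize_by_probeset(e$expr_b),
                         pm$pairs, e$annot_a, e$annot_b)
    tc <- tissue_correlation_matrix(mg)
    g <- tc$groups
    # same-tissue cross-species entry vs mean off-tissue cross-species entry
    for (t in unique(g$tissue)) {
      ga <- g$group[g$tissue == t & g$species == "speciesA"]
      gb <- g$group[g$tissue == t & g$species == "speciesB"]
      off <- g$group[g$tissue != t & g$species == "speciesB"]
      same_gt_off <- c(same_gt_off,
                       tc$values[ga, gb] > mean(tc$values[ga, off]))
    }
    sibs <- c(sibs, sibling_tissue_fraction(hierarchical_cluster(tc),
                                            tc$groups))
  }
  expect_gte(mean(same_gt_off), 0.9)
  expect_gte(mean(sibs), 0.75)
})
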