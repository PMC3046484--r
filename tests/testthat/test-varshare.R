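test_that("variance ranking sorts by tissue-wise sample variance", {
  m <- rbind(g1 = c(0, 2, 4), g2 = c(1, 1, 1), g3 = c(0, 10, 20))
  colnames(m) <- paste0("s", 1:3)
  annot <- data.frame(sample_id = colnames(m), tissue = "liver")
  r <- gene_variance_ranking(m, annot, "liver")
  # var(c(0,2,4)) = (4+0+4)/2 = 4 with the n-1 denominator
  expect_equal(r$variance[r$gene == "g1"], 4)
  expect_identical(r$gene, c("g3", "g1", "g2"))
  # constant rows rank last with variance zero
  expect_equal(r$variance[3], 0)
  expect_error(gene_variance_ranking(m, annot, "kidney"), "kidney")
})

test_that("planted tissue-specific genes top their tissue's ranking", {
  recovered <- 0L; total <- 0L
  for (seed in 1:5) {
    d <- tiny_design(seed = seed, effect_size = 2)
    u <- generate_universe(d)
    e <- generate_expression(d, u)
    key <- u$truth$true_probeset_pairs
    m <- unclass(e$expr_a)[key$probeset_a, ]
    for (t in names(u$truth$specific_genes)) {
      planted <- key$probeset_a[key$gene_a %in% u$truth$specific_genes[[t]]]
      r <- gene_variance_ranking(m, e$annot_a, t)
      top <- r$gene[seq_len(ceiling(0.15 * nrow(m)))]
      recovered <- recovered + sum(planted %in% top)
      total <- total + length(planted)
    }
  }
  expect_gte(recovered / total, 0.8)
})

test_that("window sharing matches brute-force set intersection", {
  genes_a <- paste0("a", 1:12)
  genes_b <- paste0("b", 1:12)
  pairing <- data.frame(probeset_a = genes_a, probeset_b = genes_b)
  # identical ranking through the pairing: every window fully shared
  ws <- window_shared_fraction(genes_a, genes_b, pairing, window_size = 4L)
  expect_equal(ws$frac_mean, rep(1, 3))
  # reversed ranking: top window disjoint from the other species' top
  ws_rev <- window_shared_fraction(genes_a, rev(genes_b), pairing,
                                   window_size = 4L)
  expect_equal(ws_rev$frac_mean[1], 0)
  # constructed permutation vs brute-force window intersection
  set.seed(71)
  perm <- sample(12)
  rb <- genes_b[perm]
  ws_p <- window_shared_fraction(genes_a, rb, pairing, window_size = 4L)
  for (w in 1:3) {
    wa <- genes_a[((w - 1) * 4 + 1):(w * 4)]
    wb <- rb[((w - 1) * 4 + 1):(w * 4)]
    expect_equal(ws_p$frac_a_in_b[w],
                 length(intersect(paste0("b", sub("a", "", wa)), wb)) / 4)
  }
  # directions agree under a one-to-one pairing
  expect_equal(ws_p$frac_a_in_b, ws_p$frac_b_in_a)
  expect_error(window_shared_fraction(genes_a, genes_b, pairing,
                                      window_size = 20L), "window_size")
})

test_that("randomized baseline converges to window_size / n_genes", {
  # single full window: fraction exactly 1
  b1 <- randomized_baseline(10, window_size = 10, n_reps = 3, seed = 1)
  expect_equal(b1$mean_fraction, 1)
  # small-scale convergence to the analytic expectation 0.5
  b2 <- randomized_baseline(10, window_size = 5, n_reps = 2000, seed = 2)
  expect_equal(b2$mean_fraction, 0.5, tolerance = 0.02)
  # three sizes: mean within 3 mc-sd of window/n
  for (cfg in list(c(60, 12), c(100, 25), c(300, 50))) {
    b <- randomized_baseline(cfg[1], cfg[2], n_reps = 200, seed = 3)
    expect_equal(b$mean_fraction, cfg[2] / cfg[1], tolerance = 0.05)
  }
  # determinism
  expect_identical(randomized_baseline(100, 20, 10, seed = 9),
                   randomized_baseline(100, 20, 10, seed = 9))
})

test_that("top conserved lists equal brute-force intersections", {
  genes_a <- paste0("a", 1:20)
  genes_b <- paste0("b", 1:20)
  pairing <- data.frame(probeset_a = genes_a, probeset_b = genes_b)
  # identical rankings: list = top ceiling(0.1 * 20) = 2 genes of either
  top <- top_conserved_list(genes_a, genes_b, pairing, top_fraction = 0.1)
  expect_identical(top$gene_a, c("a1", "a2"))
  # disjoint tops: empty
  top2 <- top_conserved_list(genes_a, rev(genes_b), pairing,
                             top_fraction = 0.25)
  expect_identical(nrow(top2), 0L)
  # random permutation vs brute force
  set.seed(73)
  rb <- sample(genes_b)
  top3 <- top_conserved_list(genes_a, rb, pairing, top_fraction = 0.5)
  expected <- intersect(paste0("b", 1:10), rb[1:10])
  expect_setequal(top3$gene_b, expected)
  # ordered by mean rank
  expect_true(!is.unsorted(top3$mean_rank))
})

test_that("planted orthologs share top windows far above baseline", {
  ratios <- numeric(0)
  for (seed in 1:5) {
    d <- tiny_design(seed = seed, effect_size = 2)
    u <- generate_universe(d)
    e <- generate_expression(d, u)
    pm <- build_pairing_map(u$orthologs, u$probes_a, u$probes_b)
    pp <- pm$pairs
    ma <- unclass(normalize_by_probeset(e$expr_a))[pp$probeset_a, ]
    mb <- unclass(normalize_by_probeset(e$expr_b))[pp$probeset_b, ]
    ws <- 10L
    t <- "liver"
    ra <- gene_variance_ranking(ma, e$annot_a, t)
    rb <- gene_variance_ranking(mb, e$annot_b, t)
    shares <- window_shared_fraction(ra, rb, pp, window_size = ws)
    base <- randomized_baseline(nrow(pp), ws, n_reps = 200, seed = seed)
    ratios <- c(ratios, shares$frac_mean[1] / base$mean_fraction)
  }
  expect_gte(mean(ratios), 3)
})

test_that("hypergeometric tail is exact against full enumeration", {
  # N=10, K=4, n=3, k=2: 40 of the 120 possible draws overlap >= 2
  expect_equal(hypergeom_overlap_test(10, 4, 3, 2)$p_value, 40 / 120,
               tolerance = 1e-12)
  expect_equal(hyper_tail_oracle(10, 4, 3, 2), 40 / 120, tolerance = 1e-12)
  # exhaustive enumeration across a spread of parameters up to N = 25
  set.seed(74)
  cases <- list(c(6, 3, 2), c(12, 5, 6), c(18, 9, 4), c(25, 10, 7),
                c(25, 4, 20), c(20, 20, 5))
  for (cs in cases) {
    N <- cs[1]; K <- cs[2]; n <- cs[3]
    for (k in 0:min(K, n)) {
      expect_equal(hypergeom_overlap_test(N, K, n, k)$p_value,
                   hyper_tail_oracle(N, K, n, k), tolerance = 1e-12)
    }
  }
  # tail at zero is 1; p non-increasing in k
  expect_equal(hypergeom_overlap_test(500, 50, 30, 0)$p_value, 1)
  ps <- sapply(0:20, function(k) {
    hypergeom_overlap_test(200, 40, 20, k)$p_value
  })
  expect_true(all(diff(ps) <= 1e-15))
  # invariant violations rejected
  expect_error(hypergeom_overlap_test(10, 4, 3, 4), "overlap")
  expect_error(hypergeom_overlap_test(10, 11, 3, 1), "universe")
  expect_error(hypergeom_overlap_test(0, 0, 0, 0), "N")
})
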