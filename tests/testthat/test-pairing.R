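test_that("alignment scores match simple closed-form cases", {
  s <- paste(rep(c("A", "C", "G", "T"), length.out = 25), collapse = "")
  expect_equal(align_probes(s, s), 25)
  # one central substitution: full-length alignment 24 matches - 1 mismatch
  s2 <- s
  substr(s2, 13, 13) <- "A"  # position 13 is "A"? ensure a real change below
  substr(s2, 13, 13) <- if (substr(s, 13, 13) == "A") "C" else "A"
  expect_equal(align_probes(s, s2), 24 * 1 - 3)
  # no shared 7-mer on the given strands -> 0 even though the DP score
  # would be positive
  a <- strrep("A", 25)
  b <- paste(rep(c("A", "C"), length.out = 25), collapse = "")
  expect_false(shares_word(a, b))
  expect_equal(align_probes(a, b), 0)
  expect_gt(align_probes(a, b, alignment_params(require_seed = FALSE)), 0)
  # empty sequence and invalid characters
  expect_equal(align_probes("", s), 0)
  expect_error(align_probes("ACGTX", s), "invalid character")
})

test_that("seeded scores equal an exhaustive Smith-Waterman oracle", {
  set.seed(101)
  p_noseed <- alignment_params(require_seed = FALSE)
  p_seed <- alignment_params()
  for (r in 1:1000) {
    a <- random_dna(25)
    b <- if (r %% 3 == 0) random_dna(25) else mutate_dna(a, sample(0:12, 1))
    orc <- sw_oracle(a, b)
    expect_identical(align_probes(a, b, p_noseed), orc)
    expect_identical(align_probes(a, b, p_seed),
                     if (shares_word(a, b)) orc else 0)
  }
})

test_that("scores decay along substitution ladders", {
  # Adding substitutions degrades the alignment. A single substitution can
  # occasionally create a fortuitous match on a shifted diagonal, so the
  # per-step decrease is a strong stochastic trend rather than a strict
  # identity; the score can never exceed the unmutated maximum.
  set.seed(7)
  p <- alignment_params(require_seed = FALSE)
  steps_down <- 0L; steps <- 0L
  for (r in 1:20) {
    a <- random_dna(25)
    a_chars <- strsplit(a, "")[[1]]
    b_chars <- a_chars
    prev <- align_probes(a, a, p)
    scores <- prev
    # mutate fresh positions only, never back toward a
    for (pos in sample(25, 10)) {
      b_chars[pos] <- sample(setdiff(c("A", "C", "G", "T"), a_chars[pos]), 1)
      cur <- align_probes(a, paste(b_chars, collapse = ""), p)
      expect_lte(cur, 25)
      steps <- steps + 1L
      steps_down <- steps_down + (cur <= prev)
      prev <- cur
      scores <- c(scores, cur)
    }
    # strong downward trend over the whole ladder
    expect_lt(cor(seq_along(scores), scores, method = "spearman"), -0.8)
  }
  expect_gte(steps_down / steps, 0.95)
})

test_that("greedy one-to-one matching follows descending-score order", {
  s <- replicate(5, random_dna(25))
  names(s) <- paste0("p", 1:5)
  # identical copies: every probe pairs with its own copy at the max score
  m <- best_one_to_one_matches(s, s)
  expect_identical(nrow(m), 5L)
  expect_identical(m$probe_a, m$probe_b)
  expect_true(all(m$score == 25))
  # all-zero scores: empty match list
  za <- c(x1 = strrep("A", 25))
  zb <- c(y1 = strrep("C", 25))
  expect_identical(nrow(best_one_to_one_matches(za, zb)), 0L)
})

test_that("greedy matching equals an exhaustive greedy simulation", {
  # conflict case: a1 is the best partner of both b1 and b2
  set.seed(12)
  base <- random_dna(25)
  probes_a <- c(a1 = base, a2 = mutate_dna(base, 6), a3 = random_dna(25))
  probes_b <- c(b1 = base, b2 = mutate_dna(base, 1), b3 = mutate_dna(base, 9))
  params <- alignment_params()
  scores <- outer(names(probes_a), names(probes_b),
                  Vectorize(function(i, j) {
                    align_probes(probes_a[[i]], probes_b[[j]], params)
                  }))
  dimnames(scores) <- list(names(probes_a), names(probes_b))
  # hand-rolled greedy on the oracle score matrix
  expected <- list()
  sc <- scores
  while (any(sc > 0)) {
    best <- max(sc)
    hit <- which(sc == best, arr.ind = TRUE)
    hit <- hit[order(rownames(sc)[hit[, 1]], colnames(sc)[hit[, 2]]), ,
               drop = FALSE][1L, ]
    expected[[length(expected) + 1L]] <-
      c(rownames(sc)[hit[1]], colnames(sc)[hit[2]])
    sc[hit[1], ] <- 0; sc[, hit[2]] <- 0
  }
  got <- best_one_to_one_matches(probes_a, probes_b, params)
  expect_identical(nrow(got), length(expected))
  for (i in seq_along(expected)) {
    expect_identical(c(got$probe_a[i], got$probe_b[i]), expected[[i]])
  }
})

test_that("probeset choice maximizes matches then total score", {
  s <- random_dna(25)
  # single probeset per side: chosen directly
  single <- pair_probesets(c("g1", "g2"),
                           list(A1 = c(p1 = s)), list(B1 = c(q1 = s)))
  expect_identical(single$probeset_a, "A1")
  expect_identical(single$n_top_matches, 1L)
  # equal match counts, unequal total score: higher total wins
  set.seed(30)
  s_mut <- mutate_dna(s, 1)
  res <- pair_probesets(c("g1", "g2"), list(A1 = c(p1 = s)),
                        list(B1 = c(q1 = s_mut), B2 = c(q2 = s)))
  expect_identical(res$probeset_b, "B2")
  expect_identical(res$total_score, 25)
  # no combination with a positive match: unpairable
  expect_null(pair_probesets(c("g1", "g2"),
                             list(A1 = c(p1 = strrep("A", 25))),
                             list(B1 = c(q1 = strrep("C", 25)))))
})

test_that("pairing map recovers ground truth and flags gaps", {
  # zero divergence: exact recovery of every intended pair
  d0 <- tiny_design(seed = 6L, n_genes = 50L, probe_divergence = 0)
  u0 <- generate_universe(d0)
  pm0 <- build_pairing_map(u0$orthologs, u0$probes_a, u0$probes_b)
  expect_identical(nrow(pm0$pairs), 50L)
  expect_identical(pm0$pairs$probeset_a, u0$truth$true_probeset_pairs$probeset_a)
  expect_identical(pm0$pairs$probeset_b, u0$truth$true_probeset_pairs$probeset_b)
  # empty ortholog table -> empty pairing
  empty <- build_pairing_map(u0$orthologs[0, ], u0$probes_a, u0$probes_b)
  expect_identical(nrow(empty$pairs), 0L)
  # a gene with no species-B probes is flagged, not dropped silently
  gb_drop <- u0$orthologs$gene_b[7]
  pm1 <- build_pairing_map(u0$orthologs, u0$probes_a,
                           u0$probes_b[u0$probes_b$gene_id != gb_drop, ])
  expect_identical(nrow(pm1$pairs), 49L)
  expect_identical(pm1$unpairable$gene_b, gb_drop)
  expect_match(pm1$unpairable$reason, "gene_b")
  # duplicated gene ids rejected
  dup <- rbind(u0$orthologs, u0$orthologs[1, ])
  expect_error(build_pairing_map(dup, u0$probes_a, u0$probes_b),
               "one-to-one")
})

test_that("pairing is symmetric at zero divergence", {
  d0 <- tiny_design(seed = 8L, n_genes = 50L, probe_divergence = 0)
  u0 <- generate_universe(d0)
  fwd <- build_pairing_map(u0$orthologs, u0$probes_a, u0$probes_b)
  rev_orth <- data.frame(gene_a = u0$orthologs$gene_b,
                         gene_b = u0$orthologs$gene_a)
  bwd <- build_pairing_map(rev_orth, u0$probes_b, u0$probes_a)
  expect_identical(fwd$pairs$probeset_a, bwd$pairs$probeset_b)
  expect_identical(fwd$pairs$probeset_b, bwd$pairs$probeset_a)
})
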