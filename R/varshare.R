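#' Rank genes by expression variance within one tissue
#'
#' Per-gene sample variance (denominator n - 1) over the samples of one
#' tissue in one species, sorted descending; ties are broken by gene id so
#' the ranking is deterministic.
#'
#' @param m Expression matrix (rows restricted to paired probesets, row
#'   names used as gene/probeset keys).
#' @param annotation Data.frame with `sample_id` and `tissue` covering the
#'   matrix columns.
#' @param tissue Tissue category to use, or `"all"` for every sample.
#' @return A data.frame `gene` (row key), `variance`, ordered by descending
#'   variance.
#' @export
gene_variance_ranking <- function(m, annotation, tissue) {
  m <- unclass(m)
  if (identical(tissue, "all")) {
    cols <- colnames(m)
  } else {
    cols <- annotation$sample_id[annotation$tissue == tissue]
    cols <- intersect(colnames(m), cols)
  }
  if (length(cols) < 3L) {
    stop(sprintf("tissue `%s` has %d sample(s); need >= 3", tissue,
                 length(cols)), call. = FALSE)
  }
  v <- apply(m[, cols, drop = FALSE], 1L, var)
  ord <- order(-v, rownames(m))
  data.frame(gene = rownames(m)[ord], variance = unname(v[ord]),
             stringsAsFactors = FALSE)
}

as_ranked_genes <- function(x) {
  if (is.data.frame(x)) x$gene else as.character(x)
}

# Map species-A keys to species-B keys under a one-to-one pairing.
pairing_lookup <- function(pairing) {
  pp <- if (inherits(pairing, "probeset_pairing")) pairing$pairs else pairing
  stats::setNames(pp$probeset_b, pp$probeset_a)
}

#' Shared-ortholog fraction per variance window
#'
#' Both species' tissue-wise variance rankings are cut into consecutive
#' non-overlapping windows of `window_size` genes (most variable first;
#' remainder genes dropped). For window w, the fraction of its genes whose
#' ortholog falls in the same-index window of the other species is computed
#' in both directions. With a one-to-one pairing over a common universe the
#' two directions are identical; this is asserted.
#'
#' @param ranked_a,ranked_b Ranked gene lists (data.frames from
#'   [gene_variance_ranking()] or character vectors), covering the same
#'   paired universe.
#' @param pairing A `probeset_pairing` or data.frame with `probeset_a`,
#'   `probeset_b` mapping the two key spaces.
#' @param window_size Genes per window (default 600).
#' @return A data.frame of class `window_sharing`: `window`, `frac_a_in_b`,
#'   `frac_b_in_a`, `frac_mean`.
#' @export
window_shared_fraction <- function(ranked_a, ranked_b, pairing,
                                   window_size = 600L) {
  stop_if_not_count(window_size, "window_size")
  ga <- as_ranked_genes(ranked_a)
  gb <- as_ranked_genes(ranked_b)
  map <- pairing_lookup(pairing)
  if (!setequal(ga, names(map)) || !setequal(gb, unname(map))) {
    stop("rankings must cover exactly the paired gene universe",
         call. = FALSE)
  }
  n <- length(ga)
  if (window_size > n) {
    stop("window_size exceeds number of genes", call. = FALSE)
  }
  n_win <- n %/% window_size
  win_of_b <- stats::setNames(rep(seq_len(n_win), each = window_size),
                              gb[seq_len(n_win * window_size)])
  win_of_a <- stats::setNames(rep(seq_len(n_win), each = window_size),
                              ga[seq_len(n_win * window_size)])
  frac_ab <- frac_ba <- numeric(n_win)
  inv_map <- stats::setNames(names(map), unname(map))
  for (w in seq_len(n_win)) {
    idx <- ((w - 1L) * window_size + 1L):(w * window_size)
    orth_b <- unname(map[ga[idx]])
    frac_ab[w] <- sum(!is.na(win_of_b[orth_b]) & win_of_b[orth_b] == w) /
      window_size
    orth_a <- unname(inv_map[gb[idx]])
    frac_ba[w] <- sum(!is.na(win_of_a[orth_a]) & win_of_a[orth_a] == w) /
      window_size
  }
  stopifnot(isTRUE(all.equal(frac_ab, frac_ba)))
  structure(data.frame(window = seq_len(n_win), frac_a_in_b = frac_ab,
                       frac_b_in_a = frac_ba,
                       frac_mean = (frac_ab + frac_ba) / 2),
            class = c("window_sharing", "data.frame"))
}

#' Randomized baseline for the window-sharing fraction
#'
#' Negative control for [window_shared_fraction()]: both species' rankings
#' are replaced by independent uniform-random permutations of the same
#' universe and the per-window shared fraction recomputed. The analytic
#' expectation is `window_size / n_genes` in every window.
#'
#' @param n_genes Universe size.
#' @param window_size Genes per window.
#' @param n_reps Number of replicates (>= 1).
#' @param seed Integer seed.
#' @return A list of class `window_baseline`: `per_window` (data.frame
#'   `window`, `mean`, `sd` over replicates), `mean_fraction` (grand mean
#'   over windows and replicates), `expected` (analytic
#'   `window_size / n_genes`), `n_reps`, `seed`.
#' @export
randomized_baseline <- function(n_genes, window_size = 600L, n_reps = 100L,
                                seed = 1L) {
  stop_if_not_count(n_genes, "n_genes")
  stop_if_not_count(window_size, "window_size")
  stop_if_not_count(n_reps, "n_reps")
  if (window_size > n_genes) {
    stop("window_size exceeds n_genes", call. = FALSE)
  }
  n_win <- n_genes %/% window_size
  with_seed(seed, {
    fracs <- matrix(NA_real_, n_win, n_reps)
    for (r in seq_len(n_reps)) {
      # ortholog identity: gene i in A pairs gene i in B; random rankings
      rank_a <- sample.int(n_genes)
      rank_b <- sample.int(n_genes)
      win_b <- integer(n_genes)
      win_b[rank_b[seq_len(n_win * window_size)]] <-
        rep(seq_len(n_win), each = window_size)
      for (w in seq_len(n_win)) {
        genes <- rank_a[((w - 1L) * window_size + 1L):(w * window_size)]
        fracs[w, r] <- sum(win_b[genes] == w) / window_size
      }
    }
    structure(list(
      per_window = data.frame(window = seq_len(n_win),
                              mean = rowMeans(fracs),
                              sd = apply(fracs, 1L, stats::sd)),
      mean_fraction = mean(fracs),
      expected = window_size / n_genes,
      n_reps = n_reps, seed = seed
    ), class = "window_baseline")
  })
}

#' @export
print.window_baseline <- function(x, ...) {
  cat(sprintf(
    "randomized window baseline: mean shared fraction %.4f (expected %.4f), %d reps\n",
    x$mean_fraction, x$expected, x$n_reps))
  invisible(x)
}

#' Orthologs in the top variance fraction of both species
#'
#' Genes in the top `ceiling(top_fraction * n)` of both species' variance
#' rankings (orthologs matched through the pairing), ordered by mean rank
#' across the two species.
#'
#' @param ranked_a,ranked_b Ranked gene lists over the paired universe.
#' @param pairing Pairing mapping species-A keys to species-B keys.
#' @param top_fraction Fraction of the ranking to call "top" (0 < f <= 1).
#' @return Data.frame `gene_a`, `gene_b`, `rank_a`, `rank_b`, `mean_rank`.
#' @export
top_conserved_list <- function(ranked_a, ranked_b, pairing,
                               top_fraction = 0.1) {
  if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction > 1) {
    stop("`top_fraction` must be in (0, 1]", call. = FALSE)
  }
  ga <- as_ranked_genes(ranked_a)
  gb <- as_ranked_genes(ranked_b)
  map <- pairing_lookup(pairing)
  k <- ceiling(top_fraction * length(ga))
  top_a <- ga[seq_len(k)]
  top_b <- gb[seq_len(min(k, length(gb)))]
  hit <- top_a[unname(map[top_a]) %in% top_b]
  if (!length(hit)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      rank_a = integer(0), rank_b = integer(0),
                      mean_rank = numeric(0), stringsAsFactors = FALSE))
  }
  rank_a <- match(hit, ga)
  rank_b <- match(unname(map[hit]), gb)
  out <- data.frame(gene_a = hit, gene_b = unname(map[hit]),
                    rank_a = rank_a, rank_b = rank_b,
                    mean_rank = (rank_a + rank_b) / 2,
                    stringsAsFactors = FALSE)
  out[order(out$mean_rank, out$gene_a), , drop = FALSE]
}

#' Exact hypergeometric gene-list overlap test
#'
#' Upper-tail probability that two gene lists of sizes K and n, drawn from
#' a common universe of size N, share at least k genes:
#' P(X >= k) with X ~ Hypergeometric(N, K, n). Computed via the stable
#' log-space tail implementation in `stats::phyper`.
#'
#' @param N Universe size.
#' @param K Genes in list 1 (within the universe).
#' @param n Genes in list 2 (within the universe).
#' @param k Observed overlap.
#' @return A list of class `overlap_test`: `N`, `K`, `n`, `k`, `p_value`.
#' @export
hypergeom_overlap_test <- function(N, K, n, k) {
  stop_if_not_count(N, "N")
  stop_if_not_count(K, "K", min = 0L)
  stop_if_not_count(n, "n", min = 0L)
  stop_if_not_count(k, "k", min = 0L)
  if (K > N || n > N) stop("list sizes cannot exceed the universe",
                           call. = FALSE)
  if (k > min(K, n)) stop("overlap k cannot exceed min(K, n)", call. = FALSE)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(list(N = N, K = K, n = n, k = k, p_value = p),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "hypergeometric overlap: %d shared between lists of %d and %d (universe %d)\n",
    x$k, x$K, x$n, x$N))
  cat(sprintf("  P(X >= %d) = %.3g\n", x$k, x$p_value))
  invisible(x)
}
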