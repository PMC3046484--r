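# Row-wise Spearman correlation matrix: rank each row once (average ranks
# for ties), then Pearson on the rank-transformed rows. Constant rows have
# no defined correlation; they are flagged and their entries set to 0.
spearman_row_cor <- function(m) {
  ranked <- t(apply(m, 1L, rank))
  const <- apply(m, 1L, function(v) length(unique(v)) == 1L)
  s <- suppressWarnings(cor(t(ranked)))
  if (any(const)) s[const, ] <- s[, const] <- 0
  diag(s) <- 1
  attr(s, "constant_rows") <- rownames(m)[const]
  s
}

#' Transcriptome-wide Spearman correlation profile of one gene
#'
#' For a gene (probeset row), the vector of Spearman rank correlations with
#' every other row of the same matrix, in row order and excluding the gene
#' itself — length n - 1 for an n-row matrix. Constant rows are flagged and
#' their correlations set to 0.
#'
#' @param m Numeric matrix restricted to the paired probesets, rows ordered
#'   by the pairing.
#' @param row Row index or row name of the gene.
#' @return Named numeric vector of length `nrow(m) - 1`.
#' @export
correlation_profile <- function(m, row) {
  m <- unclass(m)
  if (ncol(m) < 3L) stop("need >= 3 samples for Spearman", call. = FALSE)
  if (is.character(row)) row <- match(row, rownames(m))
  stop_if_not_count(row, "row")
  if (row > nrow(m)) stop("row index out of range", call. = FALSE)
  s <- spearman_row_cor(m)
  s[row, -row]
}

#' Correlation of correlation coefficients (corCor) for every ortholog pair
#'
#' For ortholog pair (A, A'), corCor is the correlation between A's vector
#' of within-species transcriptome-wide Spearman correlations and the
#' corresponding vector for A' on the other platform, entries aligned by
#' the ortholog pairing. High |corCor| indicates conserved co-expression;
#' negative values indicate anti-correlated behaviour. The outer correlation
#' is Pearson by default.
#'
#' @param m_a,m_b Expression matrices restricted to the paired probesets,
#'   with row i of `m_a` orthologous to row i of `m_b`.
#' @param pairing Optional `probeset_pairing` (or its `pairs` data.frame);
#'   when given, rows are subset and ordered by it.
#' @param outer_method `"pearson"` (default) or `"spearman"` for the outer
#'   correlation between the two profile vectors.
#' @return A list of class `corcor_result`: `values` (named numeric, one
#'   corCor per pair; `NA` when a profile vector has zero variance),
#'   `pairs` (data.frame), `n_samples` (per species), `outer_method`,
#'   `undefined` (pair keys with undefined corCor).
#' @export
corcor_all <- function(m_a, m_b, pairing = NULL,
                       outer_method = c("pearson", "spearman")) {
  outer_method <- match.arg(outer_method)
  m_a <- unclass(m_a); m_b <- unclass(m_b)
  if (!is.null(pairing)) {
    pp <- if (inherits(pairing, "probeset_pairing")) pairing$pairs else pairing
    m_a <- m_a[pp$probeset_a, , drop = FALSE]
    m_b <- m_b[pp$probeset_b, , drop = FALSE]
    keys <- paste(pp$probeset_a, pp$probeset_b, sep = "|")
    pairs <- pp
  } else {
    if (nrow(m_a) != nrow(m_b)) {
      stop("matrices must have the same number of (aligned) rows",
           call. = FALSE)
    }
    keys <- paste(rownames(m_a), rownames(m_b), sep = "|")
    pairs <- data.frame(probeset_a = rownames(m_a),
                        probeset_b = rownames(m_b),
                        stringsAsFactors = FALSE)
  }
  n <- nrow(m_a)
  if (n < 3L) stop("need >= 3 ortholog pairs", call. = FALSE)
  s_a <- spearman_row_cor(m_a)
  s_b <- spearman_row_cor(m_b)
  vals <- vapply(seq_len(n), function(i) {
    va <- s_a[i, -i]; vb <- s_b[i, -i]
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) return(NA_real_)
    if (outer_method == "pearson") cor(va, vb) else
      cor(va, vb, method = "spearman")
  }, 0)
  names(vals) <- keys
  structure(list(values = vals, pairs = pairs,
                 n_samples = c(a = ncol(m_a), b = ncol(m_b)),
                 outer_method = outer_method,
                 undefined = keys[is.na(vals)]),
            class = "corcor_result")
}

#' @export
print.corcor_result <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("corCor over %d ortholog pairs (%d undefined)\n",
              length(x$values), length(x$undefined)))
  if (length(v)) {
    cat(sprintf("  mean %.4f, median %.4f, range [%.4f, %.4f]\n",
                mean(v), median(v), min(v), max(v)))
    cat(sprintf("  pairs with corCor > 0.1: %d\n", sum(v > 0.1)))
  }
  invisible(x)
}

shuffle_matrix <- function(m, mode) {
  if (mode == "shuffle_within_row") {
    t(apply(m, 1L, sample))
  } else {
    matrix(sample(m), nrow(m), ncol(m), dimnames = dimnames(m))
  }
}

#' Randomized null distribution of corCor
#'
#' Destroys the gene-gene correlation structure by shuffling expression
#' values (each row independently across samples by default, or globally),
#' recomputes corCor for every pair, and counts exceedances at the given
#' thresholds. Deterministic under `seed`.
#'
#' @param m_a,m_b Aligned paired matrices, as in [corcor_all()].
#' @param pairing Optional pairing, as in [corcor_all()].
#' @param n_reps Number of randomization replicates (>= 1).
#' @param seed Integer seed.
#' @param mode `"shuffle_within_row"` (default) or `"shuffle_global"`.
#' @param thresholds Thresholds for strict-exceedance counts.
#' @return A list of class `corcor_null`: `values` (pairs x reps matrix of
#'   null corCor), `exceedance` (thresholds x reps counts), `mode`, `seed`.
#' @export
corcor_null <- function(m_a, m_b, pairing = NULL, n_reps = 10L, seed = 1L,
                        mode = c("shuffle_within_row", "shuffle_global"),
                        thresholds = c(0.05, 0.1)) {
  mode <- match.arg(mode)
  stop_if_not_count(n_reps, "n_reps")
  with_seed(seed, {
    reps <- vapply(seq_len(n_reps), function(r) {
      ra <- shuffle_matrix(unclass(m_a), mode)
      rb <- shuffle_matrix(unclass(m_b), mode)
      rownames(ra) <- rownames(m_a); rownames(rb) <- rownames(m_b)
      corcor_all(ra, rb, pairing)$values
    }, numeric(if (is.null(pairing)) nrow(m_a) else {
      pp <- if (inherits(pairing, "probeset_pairing")) pairing$pairs
            else pairing
      nrow(pp)
    }))
    reps <- matrix(reps, ncol = n_reps)
    exceed <- vapply(seq_len(n_reps), function(r) {
      vapply(thresholds, function(th) sum(reps[, r] > th, na.rm = TRUE), 0)
    }, numeric(length(thresholds)))
    exceed <- matrix(exceed, nrow = length(thresholds),
                     dimnames = list(paste0(">", thresholds), NULL))
    structure(list(values = reps, exceedance = exceed, mode = mode,
                   seed = seed, thresholds = thresholds),
              class = "corcor_null")
  })
}

#' @export
print.corcor_null <- function(x, ...) {
  cat(sprintf("corCor null: %d pairs x %d reps (%s)\n", nrow(x$values),
              ncol(x$values), x$mode))
  for (i in seq_along(x$thresholds)) {
    cat(sprintf("  mean count %s: %.2f\n", rownames(x$exceedance)[i],
                mean(x$exceedance[i, ])))
  }
  invisible(x)
}

#' Count ortholog pairs with corCor strictly above a threshold
#'
#' @param result A `corcor_result`.
#' @param threshold Numeric threshold (strict inequality).
#' @return A list: `count`, `n_defined`, `n_undefined`.
#' @export
count_exceeding <- function(result, threshold) {
  if (!inherits(result, "corcor_result")) {
    stop("`result` must be a corcor_result", call. = FALSE)
  }
  v <- result$values
  list(count = sum(v > threshold, na.rm = TRUE),
       n_defined = sum(!is.na(v)),
       n_undefined = sum(is.na(v)))
}
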