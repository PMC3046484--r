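# Independent oracles used across the suite. These stay deliberately
# brute-force and share no code with the package internals.

# Exhaustive Smith-Waterman with affine gaps (gap of length L costs
# open + L * ext), full dynamic-programming matrices, no seeding.
sw_oracle <- function(a, b, match = 1, mis = -3, open = 5, ext = 2) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  if (!n || !m) return(0)
  NEG <- -1e18
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      s <- H[i - 1, j - 1] + if (a[i - 1] == b[j - 1]) match else mis
      H[i, j] <- max(0, s, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

shares_word <- function(a, b, w = 7L) {
  words <- substring(a, seq_len(nchar(a) - w + 1L),
                     seq_len(nchar(a) - w + 1L) + w - 1L)
  any(vapply(words, function(x) grepl(x, b, fixed = TRUE), TRUE))
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutate_dna <- function(seq, n_subs) {
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), n_subs)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

# Exhaustive hypergeometric upper tail by enumerating every draw of size n
# from a universe of size N with a fixed K-subset marked.
hyper_tail_oracle <- function(N, K, n, k) {
  draws <- combn(N, n)
  marked <- seq_len(K)
  overlaps <- apply(draws, 2L, function(d) sum(d %in% marked))
  mean(overlaps >= k)
}

# Brute-force two-stage corCor: explicit rank transform, then per-pair
# nested-loop Spearman profiles and an outer Pearson correlation.
corcor_oracle <- function(ma, mb) {
  n <- nrow(ma)
  spearman <- function(x, y) cor(rank(x), rank(y))
  vapply(seq_len(n), function(i) {
    va <- vapply(setdiff(seq_len(n), i), function(j) {
      spearman(ma[i, ], ma[j, ])
    }, 0)
    vb <- vapply(setdiff(seq_len(n), i), function(j) {
      spearman(mb[i, ], mb[j, ])
    }, 0)
    cor(va, vb)
  }, 0)
}

# Direct loop over all column pairs for the group-mean correlation matrix.
tissue_cor_oracle <- function(m, groups) {
  labs <- unique(groups)
  out <- matrix(NA_real_, length(labs), length(labs),
                dimnames = list(labs, labs))
  for (gi in labs) {
    for (gj in labs) {
      ci <- which(groups == gi); cj <- which(groups == gj)
      vals <- c()
      for (a in ci) {
        for (b in cj) {
          if (gi == gj && a >= b) next
          vals <- c(vals, cor(m[, a], m[, b]))
        }
      }
      out[gi, gj] <- mean(vals)
    }
  }
  out
}

# Small default design reused by several files.
tiny_design <- function(seed = 1L, ...) {
  args <- list(n_genes = 100L, tissues = c("liver", "brain", "heart"),
               samples_per_tissue_per_species = 15L,
               n_specific_per_tissue = 10L, n_housekeeping = 10L,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synth_design, args)
}
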