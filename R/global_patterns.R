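#' Principal component analysis of an expression matrix
#'
#' Samples are the observations: the probeset-by-sample matrix is transposed
#' before decomposition. Variables (probeset rows) are mean-centered but not
#' rescaled, matching `prcomp` defaults. Because PCA signs are arbitrary,
#' each loading vector is flipped so its largest-magnitude entry is
#' positive, making scores reproducible.
#'
#' @param m An `expr_matrix` or the `values` of a merged matrix (a
#'   `merged_matrix` is also accepted directly).
#' @param n_components Number of components to keep (default: all).
#' @return A list of class `pca_result`: `scores` (samples x components),
#'   `loadings` (probesets x components), `variance_fractions` (per kept
#'   component), `all_variance_fractions` (over every component).
#' @export
pca <- function(m, n_components = NULL) {
  if (inherits(m, "merged_matrix")) m <- m$values
  x <- t(unclass(m))
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("need at least 2 samples and 2 probesets", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("non-finite values in matrix", call. = FALSE)
  max_comp <- min(dim(x))
  if (is.null(n_components)) n_components <- max_comp
  stop_if_not_count(n_components, "n_components")
  if (n_components > max_comp) {
    stop(sprintf("n_components (%d) exceeds min(dim) = %d", n_components,
                 max_comp), call. = FALSE)
  }
  fit <- prcomp(x, center = TRUE, scale. = FALSE)
  all_fracs <- fit$sdev^2 / sum(fit$sdev^2)
  keep <- seq_len(n_components)
  loadings <- fit$rotation[, keep, drop = FALSE]
  scores <- fit$x[, keep, drop = FALSE]
  # sign convention: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 variance_fractions = all_fracs[keep],
                 all_variance_fractions = all_fracs),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(5L, length(x$variance_fractions))
  cat(sprintf("PCA: %d samples, %d components kept\n", nrow(x$scores),
              ncol(x$scores)))
  cat("  variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_len(k),
                    100 * x$variance_fractions[seq_len(k)]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Silhouette-based cluster separation on PCA scores
#'
#' Quantifies how well samples cluster by a grouping (e.g. tissue or
#' species) in the space of the first `k` principal components, using the
#' standard silhouette with Euclidean distance.
#'
#' @param scores Sample-by-component score matrix (from [pca()]).
#' @param groups Character/factor vector of group labels, one per sample.
#' @param k Number of leading components to use.
#' @return A list with `overall` (mean silhouette width), `per_group`
#'   (named mean widths), and `excluded` (groups with < 2 samples, dropped
#'   with a warning).
#' @export
cluster_separation <- function(scores, groups, k = 3L) {
  stop_if_not_count(k, "k")
  if (k > ncol(scores)) stop("k exceeds available components", call. = FALSE)
  if (length(groups) != nrow(scores)) {
    stop("`groups` must have one label per sample", call. = FALSE)
  }
  groups <- as.character(groups)
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("excluding group(s) with < 2 samples: ",
            paste(small, collapse = ", "), call. = FALSE)
  }
  keep <- !groups %in% small
  g <- factor(groups[keep])
  if (nlevels(g) < 2L) stop("need at least 2 usable groups", call. = FALSE)
  d <- dist(scores[keep, seq_len(k), drop = FALSE])
  sil <- cluster::silhouette(as.integer(g), d)
  widths <- sil[, "sil_width"]
  list(overall = mean(widths),
       per_group = tapply(widths, g, mean),
       excluded = small)
}

#' Mean-correlation matrix between (species, tissue) sample groups
#'
#' Splits the merged matrix's samples into annotation groups (each species
#' crossed with each tissue category) and fills a group-by-group matrix with
#' the mean Pearson correlation over all cross-group sample pairs
#' (correlations computed across probeset rows). Within-group entries are
#' means over distinct sample pairs, excluding each sample's correlation
#' with itself.
#'
#' @param merged A `merged_matrix` (normalized by probeset) or an
#'   `expr_matrix` plus `annotation`.
#' @param annotation Required when `merged` is a plain matrix: data.frame
#'   with `sample_id`, `species`, `tissue` covering every column.
#' @return A list of class `tissue_cor`: `values` (group x group mean
#'   correlations), `groups` (data.frame `group`, `species`, `tissue`,
#'   `n_samples`), `dropped` (empty groups).
#' @export
tissue_correlation_matrix <- function(merged, annotation = NULL) {
  if (inherits(merged, "merged_matrix")) {
    annotation <- merged$annotation
    m <- unclass(merged$values)
  } else {
    if (is.null(annotation)) stop("`annotation` required", call. = FALSE)
    m <- unclass(merged)
  }
  annotation <- annotation[match(colnames(m), annotation$sample_id), ]
  if (anyNA(annotation$sample_id)) {
    stop("annotation does not cover every sample", call. = FALSE)
  }
  grp <- paste(annotation$species, annotation$tissue, sep = ".")
  labels <- unique(grp)
  # one pass: full sample-sample correlation, then group-block means
  cc <- cor(m)
  n_g <- length(labels)
  vals <- matrix(NA_real_, n_g, n_g, dimnames = list(labels, labels))
  idx <- split(seq_along(grp), grp)[labels]
  for (i in seq_len(n_g)) {
    for (j in i:n_g) {
      block <- cc[idx[[i]], idx[[j]], drop = FALSE]
      if (i == j) {
        if (nrow(block) < 2L) next  # no off-diagonal pairs
        v <- mean(block[upper.tri(block)])
      } else {
        v <- mean(block)
      }
      vals[i, j] <- v
      vals[j, i] <- v
    }
  }
  groups <- data.frame(group = labels,
                       species = annotation$species[match(labels, grp)],
                       tissue = annotation$tissue[match(labels, grp)],
                       n_samples = lengths(idx),
                       stringsAsFactors = FALSE)
  structure(list(values = vals, groups = groups, dropped = character(0)),
            class = "tissue_cor")
}

#' @export
print.tissue_cor <- function(x, ...) {
  cat(sprintf("tissue/species mean-correlation matrix: %d groups\n",
              nrow(x$values)))
  invisible(x)
}

#' Hierarchical clustering of the tissue-correlation matrix
#'
#' Agglomerative clustering of the group-by-group mean-correlation matrix
#' rows with Euclidean distance and complete linkage (the defaults of the
#' usual heatmap functions). Tie-breaks follow the input group order, which
#' `hclust` applies deterministically.
#'
#' @param tc A `tissue_cor` object (or a plain numeric matrix with
#'   dimnames).
#' @return A list of class `tissue_dendro`: `hclust` (the tree), `order`
#'   (group labels in dendrogram order), `merge_heights`.
#' @export
hierarchical_cluster <- function(tc) {
  vals <- if (inherits(tc, "tissue_cor")) tc$values else tc
  if (!is.matrix(vals) || is.null(rownames(vals))) {
    stop("need a matrix with row names", call. = FALSE)
  }
  if (anyNA(vals)) {
    stop("correlation matrix has missing entries (singleton groups?)",
         call. = FALSE)
  }
  hc <- hclust(dist(vals), method = "complete")
  structure(list(hclust = hc, order = rownames(vals)[hc$order],
                 merge_heights = hc$height),
            class = "tissue_dendro")
}

#' @export
print.tissue_dendro <- function(x, ...) {
  cat("hierarchical clustering of", length(x$order), "groups\n")
  cat("  order:", paste(x$order, collapse = ", "), "\n")
  invisible(x)
}

#' Fraction of tissues whose two species' groups are dendrogram siblings
#'
#' Scores the "species pairs up by tissue" phenomenon: for each tissue with
#' groups in both species, checks whether the two (species, tissue) leaves
#' merge with each other before merging with anything else.
#'
#' @param dendro A `tissue_dendro` from [hierarchical_cluster()].
#' @param groups The `groups` data.frame from [tissue_correlation_matrix()].
#' @return Proportion of tissues (present in both species) whose groups are
#'   siblings in the tree.
#' @export
sibling_tissue_fraction <- function(dendro, groups) {
  hc <- dendro$hclust
  lab <- hc$labels
  tissues <- unique(groups$tissue)
  both <- tissues[vapply(tissues, function(t) {
    sum(groups$tissue == t) == 2L
  }, TRUE)]
  if (!length(both)) return(NA_real_)
  is_sibling <- vapply(both, function(t) {
    g <- groups$group[groups$tissue == t]
    i <- match(g, lab)
    any(hc$merge[, 1] == -i[1] & hc$merge[, 2] == -i[2]) ||
      any(hc$merge[, 1] == -i[2] & hc$merge[, 2] == -i[1])
  }, TRUE)
  mean(is_sibling)
}
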