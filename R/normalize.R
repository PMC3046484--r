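#' Construct an expression matrix object
#'
#' A thin wrapper around a numeric matrix (probesets x samples) carrying a
#' `scale_tag` attribute that records which normalization, if any, has been
#' applied. The tag guards against double normalization and against merging
#' matrices normalized in different modes.
#'
#' @param m Numeric matrix with unique row and column names.
#' @param scale_tag One of `"raw"`, `"by_probeset"`, `"by_sample"`.
#' @return The matrix with class `expr_matrix` and the tag attached.
#' @export
expr_matrix <- function(m, scale_tag = c("raw", "by_probeset", "by_sample")) {
  scale_tag <- match.arg(scale_tag)
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("`m` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    stop("`m` must have unique row names (probeset ids)", call. = FALSE)
  }
  if (is.null(colnames(m)) || anyDuplicated(colnames(m))) {
    stop("`m` must have unique column names (sample ids)", call. = FALSE)
  }
  if (!all(is.finite(m))) stop("`m` contains non-finite values", call. = FALSE)
  structure(m, scale_tag = scale_tag, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d probesets x %d samples (scale: %s)\n",
              nrow(x), ncol(x), scale_tag(x)))
  flagged <- attr(x, "mad_zero")
  if (length(flagged)) {
    cat(sprintf("  %d MAD-zero vector(s) set to zero: %s%s\n", length(flagged),
                paste(head(flagged, 5L), collapse = ", "),
                if (length(flagged) > 5L) ", ..." else ""))
  }
  invisible(x)
}

#' Get the normalization tag of an expression matrix
#' @param m An `expr_matrix` (or plain matrix, treated as raw).
#' @return The scale tag string.
#' @export
scale_tag <- function(m) {
  tag <- attr(m, "scale_tag")
  if (is.null(tag)) "raw" else tag
}

center_scale <- function(v) {
  med <- median(v)
  centered <- v - med
  s <- median(abs(centered))
  if (s == 0) NULL else centered / s
}

normalize_axis <- function(m, by) {
  if (scale_tag(m) != "raw") {
    stop("matrix is already normalized (scale_tag = ", scale_tag(m),
         "); refusing to normalize twice", call. = FALSE)
  }
  if (!all(is.finite(m))) stop("matrix contains non-finite values", call. = FALSE)
  out <- unclass(m)
  n <- if (by == "row") nrow(m) else ncol(m)
  ids <- if (by == "row") rownames(m) else colnames(m)
  flagged <- character(0)
  for (i in seq_len(n)) {
    v <- if (by == "row") out[i, ] else out[, i]
    z <- center_scale(v)
    if (is.null(z)) {
      z <- rep(0, length(v))
      flagged <- c(flagged, ids[i])
    }
    if (by == "row") out[i, ] <- z else out[, i] <- z
  }
  res <- expr_matrix(out, if (by == "row") "by_probeset" else "by_sample")
  attr(res, "mad_zero") <- flagged
  res
}

#' Normalize an expression matrix by probeset (rows)
#'
#' Each row is centered on median zero by subtracting the row median, then
#' divided by its median absolute deviation (unscaled MAD, no consistency
#' factor). Rows whose MAD is zero cannot be scaled; they are set to all
#' zeros and recorded in the `mad_zero` attribute of the result.
#'
#' @param m A raw `expr_matrix`.
#' @return An `expr_matrix` with `scale_tag = "by_probeset"` and a `mad_zero`
#'   attribute listing flagged row ids.
#' @export
normalize_by_probeset <- function(m) normalize_axis(m, "row")

#' Normalize an expression matrix by sample (columns)
#'
#' Column-wise analogue of [normalize_by_probeset()]: each column is centered
#' on its median and divided by its (unscaled) MAD.
#'
#' @param m A raw `expr_matrix`.
#' @return An `expr_matrix` with `scale_tag = "by_sample"` and a `mad_zero`
#'   attribute listing flagged column ids.
#' @export
normalize_by_sample <- function(m) normalize_axis(m, "col")

#' Vectors flagged as MAD-zero during normalization
#' @param m A normalized `expr_matrix`.
#' @return Character vector of flagged row/column ids (possibly empty).
#' @export
mad_zero_ids <- function(m) {
  f <- attr(m, "mad_zero")
  if (is.null(f)) character(0) else f
}

#' Merge two species' normalized matrices on a probeset pairing
#'
#' Rows of the merged matrix are ortholog probeset pairs (keyed
#' `probeset_a|probeset_b`, ordered as in `pairing`); columns are the
#' species-A samples followed by the species-B samples. Values are copied
#' bit-for-bit; no renormalization happens during the merge.
#'
#' @param m_a,m_b `expr_matrix` objects normalized in the same mode.
#' @param pairing A data.frame with columns `probeset_a`, `probeset_b`
#'   (e.g. from [build_pairing_map()]).
#' @param annot_a,annot_b Sample annotations for each matrix (data.frames
#'   with a `sample_id` column covering the matrix columns).
#' @return A list of class `merged_matrix` with elements `values` (an
#'   `expr_matrix`), `annotation` (row-bound annotations, in column order)
#'   and `pairing`.
#' @export
merge_matrices <- function(m_a, m_b, pairing, annot_a, annot_b) {
  tag_a <- scale_tag(m_a); tag_b <- scale_tag(m_b)
  if (!tag_a %in% c("by_probeset", "by_sample") || tag_a != tag_b) {
    stop("normalize both sides identically before merging (got `", tag_a,
         "` and `", tag_b, "`)", call. = FALSE)
  }
  missing_a <- setdiff(pairing$probeset_a, rownames(m_a))
  missing_b <- setdiff(pairing$probeset_b, rownames(m_b))
  if (length(missing_a) || length(missing_b)) {
    stop("probeset(s) in pairing absent from matrix: ",
         paste(head(c(missing_a, missing_b), 5L), collapse = ", "),
         call. = FALSE)
  }
  if (length(intersect(colnames(m_a), colnames(m_b)))) {
    stop("sample ids overlap between the two matrices", call. = FALSE)
  }
  vals <- cbind(unclass(m_a)[pairing$probeset_a, , drop = FALSE],
                unclass(m_b)[pairing$probeset_b, , drop = FALSE])
  rownames(vals) <- paste(pairing$probeset_a, pairing$probeset_b, sep = "|")
  annot <- rbind(
    annot_a[match(colnames(m_a), annot_a$sample_id), , drop = FALSE],
    annot_b[match(colnames(m_b), annot_b$sample_id), , drop = FALSE]
  )
  if (anyNA(annot$sample_id)) {
    stop("annotation does not cover every sample column", call. = FALSE)
  }
  rownames(annot) <- NULL
  structure(
    list(values = expr_matrix(vals, tag_a), annotation = annot,
         pairing = pairing),
    class = "merged_matrix"
  )
}

#' @export
print.merged_matrix <- function(x, ...) {
  cat(sprintf(
    "merged cross-species matrix: %d ortholog probeset pairs x %d samples (%s)\n",
    nrow(x$values), ncol(x$values), scale_tag(x$values)))
  cat("  samples per species:\n")
  print(table(x$annotation$species))
  invisible(x)
}

#' Drop tissue categories whose samples are unbalanced between species
#'
#' Compendia assembled from public repositories can contain tissue
#' categories dominated by one species (e.g. thousands of samples of one
#' tissue in one species and a handful in the other); these distort global
#' structure and are removed from both species. The rule is either an
#' explicit drop-list (default) or a maximum between-species share ratio.
#'
#' @param m An `expr_matrix`.
#' @param annot Annotation for `m`'s samples.
#' @param drop_tissues Character vector of tissue categories to remove.
#' @param max_ratio Optional: if given (and `drop_tissues` is `NULL`),
#'   `annot_other` must be supplied and any tissue whose per-species sample
#'   share differs by more than this ratio is dropped.
#' @param annot_other Annotation of the other species (for `max_ratio` mode).
#' @return A list with the filtered `matrix`, its `annotation`, and
#'   `dropped` sample ids.
#' @export
filter_unbalanced_tissues <- function(m, annot, drop_tissues = NULL,
                                      max_ratio = NULL, annot_other = NULL) {
  if (is.null(drop_tissues)) {
    if (is.null(max_ratio) || is.null(annot_other)) {
      stop("supply `drop_tissues`, or both `max_ratio` and `annot_other`",
           call. = FALSE)
    }
    share_self <- table(annot$tissue) / nrow(annot)
    share_other <- table(annot_other$tissue) / nrow(annot_other)
    tissues <- union(names(share_self), names(share_other))
    s1 <- ifelse(tissues %in% names(share_self), share_self[tissues], 0)
    s2 <- ifelse(tissues %in% names(share_other), share_other[tissues], 0)
    ratio <- pmax(s1, s2) / pmax(pmin(s1, s2), .Machine$double.eps)
    drop_tissues <- tissues[ratio > max_ratio]
  }
  keep <- annot$sample_id[!annot$tissue %in% drop_tissues]
  dropped <- setdiff(colnames(m), keep)
  kept_m <- expr_matrix(unclass(m)[, colnames(m) %in% keep, drop = FALSE],
                        scale_tag(m))
  list(matrix = kept_m,
       annotation = annot[annot$sample_id %in% colnames(kept_m), , drop = FALSE],
       dropped = dropped)
}
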