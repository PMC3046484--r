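#' Read an expression matrix from TSV
#'
#' The expected layout is one header line, a first column `probeset_id`
#' holding unique row keys, and one tab-separated numeric column per sample.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix (probesets x samples) with dimnames and a
#'   `scale_tag` attribute of `"raw"`.
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "probeset_id") {
    stop("expression TSV must have first column `probeset_id`", call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df$probeset_id
  expr_matrix(m, scale_tag = "raw")
}

#' Write an expression matrix to TSV
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(probeset_id = rownames(m), m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-annotation table
#'
#' Columns: `sample_id`, `species`, `tissue`, `experiment`.
#'
#' @param path Path to a tab-separated file.
#' @return A data.frame.
#' @export
read_annotation_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "species", "tissue", "experiment")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("annotation TSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read an ortholog gene-pair table (`gene_a`, `gene_b`)
#' @param path Path to a tab-separated file.
#' @return A data.frame with columns `gene_a`, `gene_b`.
#' @export
read_ortholog_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b") %in% names(df))) {
    stop("ortholog TSV must have columns `gene_a`, `gene_b`", call. = FALSE)
  }
  df
}

#' Read probe sequences from FASTA
#'
#' Headers follow `>{probeset_id}|{probe_index}|{gene_id}`.
#'
#' @param path FASTA file path.
#' @return A data.frame with columns `probeset_id`, `probe_index`, `gene_id`,
#'   `sequence`.
#' @export
read_probe_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(ss), "|", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed probe FASTA header: ", names(ss)[bad][1], call. = FALSE)
  }
  data.frame(
    probeset_id = vapply(parts, `[`, "", 1L),
    probe_index = as.integer(vapply(parts, `[`, "", 2L)),
    gene_id = vapply(parts, `[`, "", 3L),
    sequence = as.character(ss),
    stringsAsFactors = FALSE
  )
}

#' Write probe sequences to FASTA
#'
#' @param probes A data.frame as returned by [read_probe_fasta()].
#' @param path Output FASTA path.
#' @export
write_probe_fasta <- function(probes, path) {
  ss <- Biostrings::DNAStringSet(probes$sequence)
  names(ss) <- sprintf("%s|%d|%s", probes$probeset_id, probes$probe_index,
                       probes$gene_id)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Read a per-array QC metrics table
#'
#' Columns: `array_id`, `AvgBg`, `PP`, `RNAdeg`, `sfs`, `nuse`, `rle`.
#'
#' @param path Path to a tab-separated file.
#' @return A data.frame.
#' @export
read_qc_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("array_id", "AvgBg", "PP", "RNAdeg", "sfs", "nuse", "rle")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("QC TSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}
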