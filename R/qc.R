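#' Array quality-control thresholds
#'
#' Acceptance ranges for the six standard array QC metrics: average
#' background (`AvgBg`), percent present calls (`PP`), RNA degradation slope
#' (`RNAdeg`), scale factors (`sfs`), normalized unscaled standard error
#' (`nuse`) and relative log expression (`rle`). All bounds are inclusive
#' except `RNAdeg`, which is a strict upper bound.
#'
#' @param avgbg_range Numeric length-2: acceptable average background.
#' @param pp_range Numeric length-2: acceptable percent-present (in percent).
#' @param rnadeg_max Strict (exclusive) upper bound on RNA degradation slope.
#' @param sfs_range Numeric length-2: acceptable scale factors.
#' @param nuse_range Numeric length-2: acceptable NUSE.
#' @param rle_range Numeric length-2: acceptable RLE.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(avgbg_range = c(20, 150),
                          pp_range = c(25, 65),
                          rnadeg_max = 1.7,
                          sfs_range = c(0.1, 2.5),
                          nuse_range = c(0.97, 1.05),
                          rle_range = c(-0.15, 0.15)) {
  ranges <- list(avgbg_range = avgbg_range, pp_range = pp_range,
                 sfs_range = sfs_range, nuse_range = nuse_range,
                 rle_range = rle_range)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (!is.numeric(r) || length(r) != 2L || !all(is.finite(r)) || r[1] > r[2]) {
      stop(sprintf("`%s` must be a finite numeric range [lower, upper]", nm),
           call. = FALSE)
    }
  }
  if (!is.numeric(rnadeg_max) || length(rnadeg_max) != 1L ||
      !is.finite(rnadeg_max)) {
    stop("`rnadeg_max` must be a single finite number", call. = FALSE)
  }
  structure(c(ranges[c("avgbg_range", "pp_range")],
              list(rnadeg_max = rnadeg_max),
              ranges[c("sfs_range", "nuse_range", "rle_range")]),
            class = "qc_thresholds")
}

#' Filter arrays by quality metrics
#'
#' An array passes only if every metric lies inside its acceptance range
#' (inclusive bounds, except the strict `RNAdeg` maximum). The report lists
#' every violated criterion per failing array, not just the first.
#'
#' @param metrics Data.frame with columns `array_id`, `AvgBg`, `PP`,
#'   `RNAdeg`, `sfs`, `nuse`, `rle` (numeric, no missing values).
#' @param thresholds A [qc_thresholds()] object.
#' @return A list of class `qc_filter` with `pass` (character vector of
#'   passing array ids) and `report` (data.frame `array_id`,
#'   `failed_criteria` with `;`-separated violated metric names).
#' @export
filter_arrays <- function(metrics, thresholds = qc_thresholds()) {
  need <- c("array_id", "AvgBg", "PP", "RNAdeg", "sfs", "nuse", "rle")
  miss <- setdiff(need, names(metrics))
  if (length(miss)) {
    stop("metrics table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(need, "array_id")) {
    v <- metrics[[col]]
    if (!is.numeric(v)) {
      bad <- metrics$array_id[which(is.na(suppressWarnings(as.numeric(v))))[1]]
      stop(sprintf("non-numeric value in column `%s` (array %s)", col,
                   if (is.na(bad)) "?" else bad), call. = FALSE)
    }
    if (anyNA(v)) {
      stop(sprintf("missing value in column `%s` (array %s)", col,
                   metrics$array_id[which(is.na(v))[1]]), call. = FALSE)
    }
  }
  th <- thresholds
  in_range <- function(x, r) x >= r[1] & x <= r[2]
  checks <- cbind(
    AvgBg = in_range(metrics$AvgBg, th$avgbg_range),
    PP = in_range(metrics$PP, th$pp_range),
    RNAdeg = metrics$RNAdeg < th$rnadeg_max,
    sfs = in_range(metrics$sfs, th$sfs_range),
    nuse = in_range(metrics$nuse, th$nuse_range),
    rle = in_range(metrics$rle, th$rle_range)
  )
  ok <- rowSums(!checks) == 0L
  report <- data.frame(
    array_id = metrics$array_id[!ok],
    failed_criteria = apply(checks[!ok, , drop = FALSE], 1L, function(row) {
      paste(colnames(checks)[!row], collapse = ";")
    }),
    stringsAsFactors = FALSE
  )
  rownames(report) <- NULL
  structure(list(pass = metrics$array_id[ok], report = report),
            class = "qc_filter")
}

#' @export
print.qc_filter <- function(x, ...) {
  cat(sprintf("array QC filter: %d passed, %d failed\n",
              length(x$pass), nrow(x$report)))
  if (nrow(x$report)) {
    tab <- sort(table(unlist(strsplit(x$report$failed_criteria, ";"))),
                decreasing = TRUE)
    cat("  failures by criterion:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}
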