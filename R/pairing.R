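#' Probe-alignment parameters
#'
#' Scoring scheme for seeded local alignment of probe sequences, defaulting
#' to legacy nucleotide-BLAST conventions: match +1, mismatch -3, affine gap
#' open 5 / extend 2, word size 7, low-complexity filtering off. A nonzero
#' score is reported only when the two sequences share at least one exact
#' word of `word_size` bases (the seed requirement).
#'
#' @param word_size Exact-word seed length.
#' @param gap_open_penalty,gap_extend_penalty Positive affine gap penalties;
#'   a gap of length L costs `gap_open_penalty + L * gap_extend_penalty`.
#' @param match_reward Positive match score.
#' @param mismatch_penalty Negative mismatch score.
#' @param low_complexity_filter Unused placeholder (filtering is off);
#'   kept so parameter sets are recorded completely.
#' @param require_seed Require a shared exact word for a nonzero score.
#' @return A list of class `alignment_params`.
#' @export
alignment_params <- function(word_size = 7L, gap_open_penalty = 5,
                             gap_extend_penalty = 2, match_reward = 1,
                             mismatch_penalty = -3,
                             low_complexity_filter = FALSE,
                             require_seed = TRUE) {
  stop_if_not_count(word_size, "word_size")
  if (gap_open_penalty <= 0 || gap_extend_penalty <= 0) {
    stop("gap penalties must be positive", call. = FALSE)
  }
  if (match_reward <= 0) stop("`match_reward` must be positive", call. = FALSE)
  if (mismatch_penalty >= 0) {
    stop("`mismatch_penalty` must be negative", call. = FALSE)
  }
  structure(list(word_size = as.integer(word_size),
                 gap_open_penalty = gap_open_penalty,
                 gap_extend_penalty = gap_extend_penalty,
                 match_reward = match_reward,
                 mismatch_penalty = mismatch_penalty,
                 low_complexity_filter = isFALSE(low_complexity_filter),
                 require_seed = isTRUE(require_seed)),
            class = "alignment_params")
}

check_seq <- function(s, name) {
  if (!is.character(s) || length(s) != 1L || is.na(s)) {
    stop(sprintf("`%s` must be a single string", name), call. = FALSE)
  }
  if (nzchar(s) && grepl("[^ACGTN]", s)) {
    stop(sprintf("invalid character in `%s` (allowed: A, C, G, T, N)", name),
         call. = FALSE)
  }
  s
}

#' Score the best seeded local alignment of two probe sequences
#'
#' Smith-Waterman local alignment under the scoring scheme in `params`.
#' The score is reported only when the two sequences share at least one
#' exact word of `word_size` bases; without a seed the score is 0 even if
#' the dynamic program would find a positive-scoring alignment.
#'
#' @param seq_a,seq_b Nucleotide strings over `A`,`C`,`G`,`T`,`N`.
#' @param params An [alignment_params()] object.
#' @return The best local-alignment score (0 if no seeded hit).
#' @export
align_probes <- function(seq_a, seq_b, params = alignment_params()) {
  check_seq(seq_a, "seq_a")
  check_seq(seq_b, "seq_b")
  if (!nzchar(seq_a) || !nzchar(seq_b)) return(0)
  .sw_score(seq_a, seq_b, params$match_reward, params$mismatch_penalty,
            params$gap_open_penalty, params$gap_extend_penalty,
            params$word_size, params$require_seed)
}

#' Greedy best one-to-one probe matching
#'
#' Computes all pairwise seeded alignment scores between two probe sets and
#' retains matches greedily: repeatedly take the highest-scoring unmatched
#' (a, b) pair with score > 0; each probe is used at most once. Ties are
#' broken by (probe_a id, probe_b id) lexicographic order.
#'
#' @param probes_a,probes_b Named character vectors of probe sequences
#'   (names are probe ids).
#' @param params An [alignment_params()] object.
#' @return A data.frame with columns `probe_a`, `probe_b`, `score`
#'   (possibly zero rows).
#' @export
best_one_to_one_matches <- function(probes_a, probes_b,
                                    params = alignment_params()) {
  if (!length(probes_a) || !length(probes_b)) {
    stop("probe lists must be nonempty", call. = FALSE)
  }
  if (is.null(names(probes_a)) || is.null(names(probes_b))) {
    stop("probes must be named (probe ids)", call. = FALSE)
  }
  for (s in probes_a) check_seq(s, "probes_a")
  for (s in probes_b) check_seq(s, "probes_b")
  scores <- .sw_score_matrix(unname(probes_a), unname(probes_b),
                             params$match_reward, params$mismatch_penalty,
                             params$gap_open_penalty,
                             params$gap_extend_penalty,
                             params$word_size, params$require_seed)
  dimnames(scores) <- list(names(probes_a), names(probes_b))
  greedy_one_to_one(scores)
}

# Greedy maximum-score matching on a score matrix; deterministic tie-break
# by (row name, column name) lexicographic order.
greedy_one_to_one <- function(scores) {
  out <- list()
  avail_r <- rep(TRUE, nrow(scores))
  avail_c <- rep(TRUE, ncol(scores))
  ord_r <- order(rownames(scores))
  ord_c <- order(colnames(scores))
  repeat {
    sub <- scores[avail_r, avail_c, drop = FALSE]
    if (!length(sub) || max(sub) <= 0) break
    best <- max(sub)
    hits <- which(scores == best & outer(avail_r, avail_c, `&`),
                  arr.ind = TRUE)
    # lexicographic tie-break on ids
    pick <- hits[order(match(hits[, 1], ord_r), match(hits[, 2], ord_c))[1L],
                 , drop = TRUE]
    out[[length(out) + 1L]] <- data.frame(
      probe_a = rownames(scores)[pick[1]],
      probe_b = colnames(scores)[pick[2]],
      score = best, stringsAsFactors = FALSE)
    avail_r[pick[1]] <- FALSE
    avail_c[pick[2]] <- FALSE
  }
  if (!length(out)) {
    return(data.frame(probe_a = character(0), probe_b = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Choose the probeset pair representing one ortholog gene pair
#'
#' For every candidate (probeset_a, probeset_b) combination, the greedy
#' one-to-one probe matching is computed; the combination with the most
#' retained probe-probe matches is selected, ties broken by larger total
#' alignment score, then by lexicographic probeset ids. If no combination
#' yields a single positive-scoring match the gene pair is unpairable.
#'
#' @param gene_pair Character length-2: (gene_a id, gene_b id); used only
#'   for labelling.
#' @param probesets_a,probesets_b Named lists of named probe-sequence
#'   vectors; list names are probeset ids.
#' @param params An [alignment_params()] object.
#' @return A one-row data.frame (`gene_a`, `gene_b`, `probeset_a`,
#'   `probeset_b`, `n_top_matches`, `total_score`), or `NULL` when the gene
#'   pair is unpairable.
#' @export
pair_probesets <- function(gene_pair, probesets_a, probesets_b,
                           params = alignment_params()) {
  if (!length(probesets_a) || !length(probesets_b)) {
    stop("each side needs at least one probeset with at least one probe",
         call. = FALSE)
  }
  cand <- expand.grid(a = sort(names(probesets_a)),
                      b = sort(names(probesets_b)),
                      stringsAsFactors = FALSE)
  cand$n <- 0L
  cand$total <- 0
  for (r in seq_len(nrow(cand))) {
    m <- best_one_to_one_matches(probesets_a[[cand$a[r]]],
                                 probesets_b[[cand$b[r]]], params)
    cand$n[r] <- nrow(m)
    cand$total[r] <- sum(m$score)
  }
  if (max(cand$n) == 0L) return(NULL)
  ord <- order(-cand$n, -cand$total, cand$a, cand$b)
  best <- cand[ord[1L], ]
  data.frame(gene_a = gene_pair[1], gene_b = gene_pair[2],
             probeset_a = best$a, probeset_b = best$b,
             n_top_matches = best$n, total_score = best$total,
             stringsAsFactors = FALSE)
}

#' Build the cross-species probeset pairing map
#'
#' Applies [pair_probesets()] to every row of a one-to-one ortholog gene
#' table, producing the merge key used by the rest of the pipeline.
#'
#' @param orthologs Data.frame with columns `gene_a`, `gene_b`; gene ids
#'   must be unique within each column (one-to-one input required).
#' @param probes_a,probes_b Probe tables (columns `probeset_id`,
#'   `probe_index`, `gene_id`, `sequence`), e.g. from [generate_universe()]
#'   or [read_probe_fasta()].
#' @param params An [alignment_params()] object.
#' @return A list of class `probeset_pairing` with `pairs` (one row per
#'   pairable gene pair: `gene_a`, `gene_b`, `probeset_a`, `probeset_b`,
#'   `n_top_matches`, `total_score`), `unpairable` (gene pairs with the
#'   reason), and `params`.
#' @export
build_pairing_map <- function(orthologs, probes_a, probes_b,
                              params = alignment_params()) {
  if (anyDuplicated(orthologs$gene_a) || anyDuplicated(orthologs$gene_b)) {
    stop("duplicate gene ids in ortholog table; one-to-one input required",
         call. = FALSE)
  }
  split_probes <- function(probes, gene) {
    sub <- probes[probes$gene_id == gene, , drop = FALSE]
    if (!nrow(sub)) return(list())
    lapply(split(sub, sub$probeset_id), function(ps) {
      stats::setNames(ps$sequence,
                      sprintf("%s|%d", ps$probeset_id, ps$probe_index))
    })
  }
  pairs <- list()
  unpairable <- list()
  for (i in seq_len(nrow(orthologs))) {
    ga <- orthologs$gene_a[i]; gb <- orthologs$gene_b[i]
    psa <- split_probes(probes_a, ga)
    psb <- split_probes(probes_b, gb)
    if (!length(psa) || !length(psb)) {
      unpairable[[length(unpairable) + 1L]] <- data.frame(
        gene_a = ga, gene_b = gb,
        reason = paste0("no probes for ",
                        if (!length(psa)) "gene_a" else "gene_b"),
        stringsAsFactors = FALSE)
      next
    }
    hit <- pair_probesets(c(ga, gb), psa, psb, params)
    if (is.null(hit)) {
      unpairable[[length(unpairable) + 1L]] <- data.frame(
        gene_a = ga, gene_b = gb, reason = "no probe match",
        stringsAsFactors = FALSE)
    } else {
      pairs[[length(pairs) + 1L]] <- hit
    }
  }
  empty_un <- data.frame(gene_a = character(0), gene_b = character(0),
                         reason = character(0), stringsAsFactors = FALSE)
  empty_pairs <- data.frame(gene_a = character(0), gene_b = character(0),
                            probeset_a = character(0),
                            probeset_b = character(0),
                            n_top_matches = integer(0),
                            total_score = numeric(0),
                            stringsAsFactors = FALSE)
  structure(list(
    pairs = if (length(pairs)) do.call(rbind, pairs) else empty_pairs,
    unpairable = if (length(unpairable)) do.call(rbind, unpairable)
                 else empty_un,
    params = params
  ), class = "probeset_pairing")
}

#' @export
print.probeset_pairing <- function(x, ...) {
  cat(sprintf("probeset pairing: %d gene pairs paired, %d unpairable\n",
              nrow(x$pairs), nrow(x$unpairable)))
  if (nrow(x$pairs)) {
    cat(sprintf("  probe matches per pair: median %g (range %d-%d)\n",
                median(x$pairs$n_top_matches), min(x$pairs$n_top_matches),
                max(x$pairs$n_top_matches)))
  }
  invisible(x)
}
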