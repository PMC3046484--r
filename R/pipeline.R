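#' Run the cross-species comparison pipeline from a configuration
#'
#' Orchestrates the full workflow — synthetic-data simulation, array QC,
#' probeset pairing, normalization, merging, global-pattern analysis
#' (PCA + tissue correlation), corCor, variance-window sharing and the
#' hypergeometric overlap test — in dependency order, writing stage outputs
#' as TSV under the configured output directory and a machine-readable JSON
#' run manifest with parameters, file checksums and warnings. Reruns with
#' the same configuration (seeds included) reproduce identical outputs.
#'
#' @param config A named list, or the path to a YAML file holding one.
#'   Recognized top-level keys: `outdir` (required), `stages` (character
#'   vector; default all), `seed`, and per-stage blocks `simulate`
#'   (arguments of [synth_design()]), `qc` (`n_arrays`, `fail_fraction`),
#'   `pair` (arguments of [alignment_params()]), `normalize` (`mode`:
#'   `"probeset"` or `"sample"`; `drop_tissues`), `corcor` (`null_reps`,
#'   `thresholds`, `mode`), `varshare` (`tissue`, `window_size`,
#'   `baseline_reps`, `top_fraction`), `overlap` (`N`, `K`, `n`, `k`).
#'   Unknown keys are rejected before any stage runs.
#' @param input Optional named list of pre-built inputs (used when the
#'   `simulate` stage is disabled): `universe`, `expr` as returned by the
#'   generator functions.
#' @return The run manifest (invisibly also written to
#'   `<outdir>/manifest.json`).
#' @export
run_pipeline <- function(config, input = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("`config` must be a list or YAML path",
                             call. = FALSE)
  all_stages <- c("simulate", "qc", "pair", "normalize", "merge",
                  "global_patterns", "corcor", "varshare", "overlap")
  known <- c("outdir", "stages", "seed", "simulate", "qc", "pair",
             "normalize", "corcor", "varshare", "overlap")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(config$outdir)) stop("config needs `outdir`", call. = FALSE)
  stages <- config$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  stages <- all_stages[all_stages %in% stages]
  seed <- as.integer(config$seed %||% 1L)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   seed = seed, stages = list(), warnings = character(0),
                   status = "running")
  state <- input %||% list()
  log_msg <- function(...) message("[pipeline] ", sprintf(...))
  emit <- function(stage, params, files) {
    manifest$stages[[stage]] <<- list(
      params = params,
      outputs = lapply(files, function(f) {
        list(path = f, md5 = unname(tools::md5sum(f)))
      }))
  }
  finish <- function(status) {
    manifest$status <<- status
    manifest$finished <<- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  run_stage <- function(stage) {
    log_msg("stage: %s", stage)
    switch(stage,
      simulate = {
        args <- config$simulate %||% list()
        args$seed <- args$seed %||% seed
        design <- do.call(synth_design, args)
        state$design <<- design
        state$universe <<- generate_universe(design)
        state$expr <<- generate_expression(design, state$universe)
        f <- file.path(outdir, c("expr_a.tsv", "expr_b.tsv", "annot_a.tsv",
                                 "annot_b.tsv", "orthologs.tsv",
                                 "probes_a.fasta", "probes_b.fasta"))
        write_expression_tsv(state$expr$expr_a, f[1])
        write_expression_tsv(state$expr$expr_b, f[2])
        write.table(state$expr$annot_a, f[3], sep = "\t", quote = FALSE,
                    row.names = FALSE)
        write.table(state$expr$annot_b, f[4], sep = "\t", quote = FALSE,
                    row.names = FALSE)
        write.table(state$universe$orthologs, f[5], sep = "\t",
                    quote = FALSE, row.names = FALSE)
        write_probe_fasta(state$universe$probes_a, f[6])
        write_probe_fasta(state$universe$probes_b, f[7])
        emit(stage, args, as.list(f))
      },
      qc = {
        args <- config$qc %||% list(n_arrays = 100L, fail_fraction = 0.2)
        qc_tab <- generate_qc_table(args$n_arrays, args$fail_fraction,
                                    seed = args$seed %||% seed)
        res <- filter_arrays(qc_tab)
        state$qc <<- res
        f <- file.path(outdir, c("qc_metrics.tsv", "qc_pass.txt",
                                 "qc_report.tsv"))
        write.table(qc_tab, f[1], sep = "\t", quote = FALSE,
                    row.names = FALSE)
        writeLines(res$pass, f[2])
        write.table(res$report, f[3], sep = "\t", quote = FALSE,
                    row.names = FALSE)
        emit(stage, args, as.list(f))
      },
      pair = {
        if (is.null(state$universe)) {
          stop("pair stage needs a universe (enable `simulate` or supply ",
               "`input`)", call. = FALSE)
        }
        params <- do.call(alignment_params, config$pair %||% list())
        pairing <- build_pairing_map(state$universe$orthologs,
                                     state$universe$probes_a,
                                     state$universe$probes_b, params)
        state$pairing <<- pairing
        f <- file.path(outdir, "pairing.tsv")
        write.table(pairing$pairs, f, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        emit(stage, unclass(params), list(f))
      },
      normalize = {
        if (is.null(state$expr)) stop("normalize stage needs expression data",
                                      call. = FALSE)
        args <- config$normalize %||% list()
        mode <- args$mode %||% "probeset"
        fun <- if (mode == "probeset") normalize_by_probeset
               else normalize_by_sample
        ea <- state$expr$expr_a; eb <- state$expr$expr_b
        aa <- state$expr$annot_a; ab <- state$expr$annot_b
        if (!is.null(args$drop_tissues)) {
          fa <- filter_unbalanced_tissues(ea, aa,
                                          drop_tissues = args$drop_tissues)
          fb <- filter_unbalanced_tissues(eb, ab,
                                          drop_tissues = args$drop_tissues)
          ea <- fa$matrix; aa <- fa$annotation
          eb <- fb$matrix; ab <- fb$annotation
        }
        state$norm <<- list(a = fun(ea), b = fun(eb),
                            annot_a = aa, annot_b = ab)
        f <- file.path(outdir, c("norm_a.tsv", "norm_b.tsv"))
        write_expression_tsv(state$norm$a, f[1])
        write_expression_tsv(state$norm$b, f[2])
        emit(stage, list(mode = mode,
                         drop_tissues = args$drop_tissues %||% character(0)),
             as.list(f))
      },
      merge = {
        if (is.null(state$norm) || is.null(state$pairing)) {
          stop("merge stage needs normalized matrices and a pairing",
               call. = FALSE)
        }
        state$merged <<- merge_matrices(state$norm$a, state$norm$b,
                                        state$pairing$pairs,
                                        state$norm$annot_a,
                                        state$norm$annot_b)
        f <- file.path(outdir, "merged.tsv")
        write_expression_tsv(state$merged$values, f)
        emit(stage, list(), list(f))
      },
      global_patterns = {
        if (is.null(state$merged)) stop("global_patterns needs merged data",
                                        call. = FALSE)
        p <- pca(state$merged, n_components = min(10L,
                 nrow(state$merged$values), ncol(state$merged$values)))
        ann <- state$merged$annotation
        sep_t <- cluster_separation(p$scores, ann$tissue, k = 3L)
        sep_s <- cluster_separation(p$scores, ann$species, k = 3L)
        tc <- tissue_correlation_matrix(state$merged)
        dd <- hierarchical_cluster(tc)
        state$global <<- list(pca = p, sil_tissue = sep_t,
                              sil_species = sep_s, tissue_cor = tc,
                              dendro = dd)
        f <- file.path(outdir, c("pca_scores.tsv", "pca_variance.tsv",
                                 "tissue_cor.tsv", "dendro_order.txt"))
        write.table(data.frame(sample_id = rownames(p$scores), p$scores,
                               species = ann$species, tissue = ann$tissue),
                    f[1], sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(data.frame(component = seq_along(p$variance_fractions),
                               variance_fraction = p$variance_fractions),
                    f[2], sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(data.frame(group = rownames(tc$values), tc$values,
                               check.names = FALSE),
                    f[3], sep = "\t", quote = FALSE, row.names = FALSE)
        writeLines(dd$order, f[4])
        emit(stage, list(silhouette_tissue = sep_t$overall,
                         silhouette_species = sep_s$overall), as.list(f))
      },
      corcor = {
        if (is.null(state$norm) || is.null(state$pairing)) {
          stop("corcor needs normalized matrices and a pairing",
               call. = FALSE)
        }
        args <- config$corcor %||% list()
        res <- corcor_all(state$norm$a, state$norm$b, state$pairing)
        nul <- corcor_null(
          unclass(state$norm$a)[state$pairing$pairs$probeset_a, ,
                                drop = FALSE],
          unclass(state$norm$b)[state$pairing$pairs$probeset_b, ,
                                drop = FALSE],
          n_reps = args$null_reps %||% 3L,
          seed = args$seed %||% seed,
          mode = args$mode %||% "shuffle_within_row",
          thresholds = args$thresholds %||% c(0.05, 0.1))
        state$corcor <<- list(observed = res, null = nul)
        f <- file.path(outdir, "corcor.tsv")
        write.table(cbind(res$pairs, corcor = unname(res$values)), f,
                    sep = "\t", quote = FALSE, row.names = FALSE)
        emit(stage, list(null_reps = ncol(nul$values), mode = nul$mode,
                         thresholds = nul$thresholds), list(f))
      },
      varshare = {
        if (is.null(state$norm) || is.null(state$pairing)) {
          stop("varshare needs normalized matrices and a pairing",
               call. = FALSE)
        }
        args <- config$varshare %||% list()
        pp <- state$pairing$pairs
        tissue <- args$tissue %||% "all"
        ma <- unclass(state$norm$a)[pp$probeset_a, , drop = FALSE]
        mb <- unclass(state$norm$b)[pp$probeset_b, , drop = FALSE]
        ws <- args$window_size %||% max(1L, nrow(pp) %/% 10L)
        ra <- gene_variance_ranking(ma, state$norm$annot_a, tissue)
        rb <- gene_variance_ranking(mb, state$norm$annot_b, tissue)
        shares <- window_shared_fraction(ra, rb, pp, window_size = ws)
        base <- randomized_baseline(nrow(pp), window_size = ws,
                                    n_reps = args$baseline_reps %||% 100L,
                                    seed = args$seed %||% seed)
        top <- top_conserved_list(ra, rb, pp,
                                  top_fraction = args$top_fraction %||% 0.1)
        state$varshare <<- list(windows = shares, baseline = base,
                                top = top)
        f <- file.path(outdir, c("windows.tsv", "top_conserved.tsv"))
        write.table(shares, f[1], sep = "\t", quote = FALSE,
                    row.names = FALSE)
        write.table(top, f[2], sep = "\t", quote = FALSE, row.names = FALSE)
        emit(stage, list(tissue = tissue, window_size = ws,
                         baseline_mean = base$mean_fraction), as.list(f))
      },
      overlap = {
        args <- config$overlap %||% list(N = 1344L, K = 79L, n = 51L,
                                         k = 13L)
        res <- hypergeom_overlap_test(args$N, args$K, args$n, args$k)
        state$overlap <<- res
        f <- file.path(outdir, "overlap.json")
        jsonlite::write_json(unclass(res), f, auto_unbox = TRUE,
                             digits = NA)
        emit(stage, args, list(f))
      }
    )
  }

  for (stage in stages) {
    ok <- tryCatch({ run_stage(stage); TRUE },
                   error = function(e) {
                     manifest$warnings <<- c(manifest$warnings,
                                             sprintf("stage %s failed: %s",
                                                     stage,
                                                     conditionMessage(e)))
                     finish("failed")
                     stop(e)
                   })
  }
  finish("completed")
  invisible(structure(c(manifest, list(results = state)),
                      class = "pipeline_run"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("pipeline run (%s): %d stage(s)\n", x$status,
              length(x$stages)))
  cat("  stages:", paste(names(x$stages), collapse = " -> "), "\n")
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}
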