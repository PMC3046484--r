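#' Design for a synthetic two-species expression study
#'
#' Bundles and validates all parameters of the synthetic-data generator. The
#' generator emulates a two-species (e.g. human/mouse) microarray compendium:
#' RMA-like log2 intensities for orthologous probesets over many tissues,
#' with planted tissue-specific and housekeeping genes, per-experiment batch
#' effects, a per-probeset species/platform offset, and 25-mer probe
#' sequences diverged between the species.
#'
#' @param n_genes Number of orthologous gene pairs.
#' @param tissues Character vector of tissue-category names (default: 13
#'   general categories, mirroring large public compendia).
#' @param samples_per_tissue_per_species Samples per tissue per species.
#' @param n_specific_per_tissue Planted tissue-specific genes per tissue.
#' @param n_housekeeping Planted low-variance (housekeeping) genes.
#' @param effect_size Mean log2 up-shift of a tissue-specific gene in its
#'   tissue (conserved in both species). On top of the shift, each
#'   signature gene is modulated across the conditions, labs and sample
#'   states collected under one tissue category, with a per-gene amplitude
#'   (drawn once, between 0.75 and 1.75 times `effect_size`) inherited by
#'   both orthologs; this makes signature genes the most variable genes
#'   within their own tissue, with conserved variance ranks. Background
#'   genes likewise carry a conserved per-gene residual sd
#'   (`noise_sd` times a log-normal factor).
#' @param noise_sd Residual per-sample standard deviation (log2 units).
#' @param batch_sd Standard deviation of per-experiment, per-gene-block
#'   additive batch effects.
#' @param species_shift_sd Standard deviation of the per-probeset additive
#'   species/platform offset (applied to species B).
#' @param probe_len Probe length in nucleotides.
#' @param probes_per_probeset Probes per probeset.
#' @param probe_divergence Per-base substitution probability between the two
#'   species' orthologous probes.
#' @param multi_probeset_fraction Fraction of genes carrying two probesets
#'   per species (exercises the pairing choice).
#' @param decoy_divergence_factor Decoy probesets on species B are mutated at
#'   `probe_divergence * decoy_divergence_factor` (capped at 0.75), so the
#'   intended pair is the lowest-divergence one.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A list of class `synth_design`.
#' @export
synth_design <- function(n_genes = 300L,
                         tissues = c("liver", "nervous_system", "muscle_heart",
                                     "cell_line", "kidney", "lung", "spleen",
                                     "thymus", "bone_marrow", "embryo", "skin",
                                     "intestine", "pancreas"),
                         samples_per_tissue_per_species = 15L,
                         n_specific_per_tissue = 5L,
                         n_housekeeping = 40L,
                         effect_size = 2,
                         noise_sd = 1,
                         batch_sd = 0.5,
                         species_shift_sd = 2,
                         probe_len = 25L,
                         probes_per_probeset = 11L,
                         probe_divergence = 0.15,
                         multi_probeset_fraction = 0.2,
                         decoy_divergence_factor = 2,
                         seed = 1L) {
  stop_if_not_count(n_genes, "n_genes")
  if (!is.character(tissues) || !length(tissues) || anyDuplicated(tissues)) {
    stop("`tissues` must be a non-empty character vector without duplicates",
         call. = FALSE)
  }
  stop_if_not_count(samples_per_tissue_per_species,
                    "samples_per_tissue_per_species")
  stop_if_not_count(n_specific_per_tissue, "n_specific_per_tissue", min = 0L)
  stop_if_not_count(n_housekeeping, "n_housekeeping", min = 0L)
  stop_if_not_count(probe_len, "probe_len")
  stop_if_not_count(probes_per_probeset, "probes_per_probeset")
  stop_if_not_prob(probe_divergence, "probe_divergence")
  stop_if_not_prob(multi_probeset_fraction, "multi_probeset_fraction")
  for (nm in c("effect_size", "noise_sd", "batch_sd", "species_shift_sd",
               "decoy_divergence_factor")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop(sprintf("`%s` must be a single non-negative number", nm),
           call. = FALSE)
    }
  }
  if (n_specific_per_tissue * length(tissues) + n_housekeeping > n_genes) {
    stop("invariant violated: n_specific_per_tissue * |tissues| + ",
         "n_housekeeping must be <= n_genes", call. = FALSE)
  }
  structure(
    list(n_genes = as.integer(n_genes), tissues = tissues,
         samples_per_tissue_per_species =
           as.integer(samples_per_tissue_per_species),
         n_specific_per_tissue = as.integer(n_specific_per_tissue),
         n_housekeeping = as.integer(n_housekeeping),
         effect_size = effect_size, noise_sd = noise_sd, batch_sd = batch_sd,
         species_shift_sd = species_shift_sd,
         probe_len = as.integer(probe_len),
         probes_per_probeset = as.integer(probes_per_probeset),
         probe_divergence = probe_divergence,
         multi_probeset_fraction = multi_probeset_fraction,
         decoy_divergence_factor = decoy_divergence_factor,
         seed = as.integer(seed)),
    class = "synth_design"
  )
}

#' @export
print.synth_design <- function(x, ...) {
  cat(sprintf(
    "synthetic study design: %d ortholog pairs, %d tissues x %d samples/species, seed %d\n",
    x$n_genes, length(x$tissues), x$samples_per_tissue_per_species, x$seed))
  invisible(x)
}

random_probe <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
}

mutate_probe <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    # substitute to one of the three other bases
    alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
    chars[hit] <- vapply(chars[hit], function(b) {
      i <- sample.int(3L, 1L)
      substr(alt[[b]], i, i)
    }, "")
  }
  paste(chars, collapse = "")
}

# Hamming divergence between two equal-length sequences, as a proportion.
hamming_divergence <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  stopifnot(length(ca) == length(cb))
  mean(ca != cb)
}

# Mean per-base divergence between two probesets' probes, index-matched.
probeset_divergence <- function(probes_a, probes_b) {
  k <- min(nrow(probes_a), nrow(probes_b))
  mean(vapply(seq_len(k), function(i) {
    hamming_divergence(probes_a$sequence[i], probes_b$sequence[i])
  }, 0))
}

#' Generate the synthetic ortholog/probeset universe
#'
#' Creates the gene- and probe-level scaffolding for a two-species study:
#' a one-to-one ortholog gene table, probe sequences per probeset for both
#' species, and the ground truth needed to score downstream recovery.
#' Species-B probes are species-A probes mutated at `probe_divergence` per
#' base; genes selected for multiple probesets also carry a decoy probeset
#' pair mutated at a higher rate, so the intended pair is the one with the
#' lowest realized divergence (recomputed from the emitted sequences, not
#' assumed).
#'
#' @param design A [synth_design()].
#' @return A list with `orthologs` (data.frame `gene_a`, `gene_b`),
#'   `probes_a`, `probes_b` (data.frames with `probeset_id`, `probe_index`,
#'   `gene_id`, `sequence`), and `truth` (ground-truth list: per-tissue
#'   specific gene sets, housekeeping set, ortholog map, intended probeset
#'   pairs, and the design).
#' @export
generate_universe <- function(design) {
  if (!inherits(design, "synth_design")) {
    stop("`design` must be a synth_design object", call. = FALSE)
  }
  with_seed(design$seed, {
    ng <- design$n_genes
    gene_a <- sprintf("GA%04d", seq_len(ng))
    gene_b <- sprintf("GB%04d", seq_len(ng))
    n_multi <- floor(design$multi_probeset_fraction * ng)
    multi <- rep(FALSE, ng)
    if (n_multi > 0) multi[sample.int(ng, n_multi)] <- TRUE

    decoy_rate <- min(design$probe_divergence * design$decoy_divergence_factor,
                      0.75)
    k <- design$probes_per_probeset
    rows_a <- vector("list", ng)
    rows_b <- vector("list", ng)
    true_pairs <- data.frame(gene_a = gene_a, gene_b = gene_b,
                             probeset_a = NA_character_,
                             probeset_b = NA_character_,
                             stringsAsFactors = FALSE)
    for (i in seq_len(ng)) {
      n_ps <- if (multi[i]) 2L else 1L
      ga <- list(); gb <- list()
      for (j in seq_len(n_ps)) {
        ps_a <- sprintf("PSA%04d_%d", i, j)
        ps_b <- sprintf("PSB%04d_%d", i, j)
        base <- random_probe(k, design$probe_len)
        rate <- if (j == 1L) design$probe_divergence else decoy_rate
        mut <- vapply(base, mutate_probe, "", rate = rate, USE.NAMES = FALSE)
        ga[[j]] <- data.frame(probeset_id = ps_a, probe_index = seq_len(k),
                              gene_id = gene_a[i], sequence = base,
                              stringsAsFactors = FALSE)
        gb[[j]] <- data.frame(probeset_id = ps_b, probe_index = seq_len(k),
                              gene_id = gene_b[i], sequence = mut,
                              stringsAsFactors = FALSE)
      }
      rows_a[[i]] <- do.call(rbind, ga)
      rows_b[[i]] <- do.call(rbind, gb)
      # intended pair = lowest realized divergence over all combinations,
      # ties broken lexicographically
      combos <- expand.grid(a = seq_len(n_ps), b = seq_len(n_ps))
      div <- vapply(seq_len(nrow(combos)), function(r) {
        probeset_divergence(ga[[combos$a[r]]], gb[[combos$b[r]]])
      }, 0)
      best <- which(div == min(div))
      if (length(best) > 1L) best <- best[order(combos$a[best],
                                                combos$b[best])][1L]
      true_pairs$probeset_a[i] <- ga[[combos$a[best]]]$probeset_id[1L]
      true_pairs$probeset_b[i] <- gb[[combos$b[best]]]$probeset_id[1L]
    }

    # plant tissue-specific and housekeeping genes on disjoint index sets
    n_spec_total <- design$n_specific_per_tissue * length(design$tissues)
    planted <- sample.int(ng, n_spec_total + design$n_housekeeping)
    spec_idx <- planted[seq_len(n_spec_total)]
    hk_idx <- planted[seq_len(design$n_housekeeping) + n_spec_total]
    specific_genes <- split(
      gene_a[spec_idx],
      rep(design$tissues, each = design$n_specific_per_tissue)
    )[design$tissues]
    if (n_spec_total == 0L) {
      specific_genes <- stats::setNames(
        rep(list(character(0)), length(design$tissues)), design$tissues)
    }

    list(
      orthologs = data.frame(gene_a = gene_a, gene_b = gene_b,
                             stringsAsFactors = FALSE),
      probes_a = do.call(rbind, rows_a),
      probes_b = do.call(rbind, rows_b),
      truth = list(
        specific_genes = specific_genes,
        housekeeping_genes = gene_a[hk_idx],
        ortholog_map = data.frame(gene_a = gene_a, gene_b = gene_b,
                                  stringsAsFactors = FALSE),
        true_probeset_pairs = true_pairs,
        design = design
      )
    )
  })
}

#' Generate synthetic expression matrices and sample annotations
#'
#' Emits one probeset-by-sample matrix per species, on an RMA-like log2
#' scale. Baseline intensities are \eqn{8 + N(0, noise\_sd)}; planted
#' tissue-specific genes are shifted up by `effect_size` on average in their
#' tissue in both species (a conserved signal), with per-sample modulation
#' of the same magnitude so they are also the most variable genes within
#' that tissue; housekeeping genes have residual
#' standard deviation `noise_sd / 2` (variance at most a quarter of the
#' background) in every tissue; per-experiment gene-block batch effects and
#' a per-probeset species offset (species B) are added on top. All probesets
#' of a gene report that gene's signal plus their own noise.
#'
#' @param design A [synth_design()].
#' @param universe The output of [generate_universe()] for the same design.
#' @return A list with `expr_a`, `expr_b` (raw `expr_matrix` objects),
#'   `annot_a`, `annot_b` (data.frames with `sample_id`, `species`, `tissue`,
#'   `experiment`).
#' @export
generate_expression <- function(design, universe) {
  if (!inherits(design, "synth_design")) {
    stop("`design` must be a synth_design object", call. = FALSE)
  }
  if (is.null(universe$truth) ||
      !identical(universe$truth$design, design)) {
    stop("`universe` was not generated from this design", call. = FALSE)
  }
  truth <- universe$truth
  with_seed(design$seed + 1L, {
    ng <- design$n_genes
    gene_a <- truth$ortholog_map$gene_a
    spec_tissue <- stats::setNames(rep(NA_character_, ng), gene_a)
    for (t in names(truth$specific_genes)) {
      spec_tissue[truth$specific_genes[[t]]] <- t
    }
    is_hk <- gene_a %in% truth$housekeeping_genes

    # gene blocks for batch effects (blocks of ~50 genes)
    block_of <- ((seq_len(ng) - 1L) %/% 50L) + 1L
    n_blocks <- max(block_of)

    # conserved per-gene variability, identical in both species: each
    # signature gene has its own in-tissue modulation amplitude and each
    # background gene its own residual sd (orthologs inherit the same
    # values, which is what makes variance rankings comparable across
    # species)
    spec_idx <- which(!is.na(spec_tissue))
    amp <- rep(NA_real_, ng)
    amp[spec_idx] <- design$effect_size * runif(length(spec_idx), 0.75, 1.75)
    sd_gene <- design$noise_sd * exp(rnorm(ng, 0, 0.25))
    sd_gene[is_hk] <- design$noise_sd / 2

    make_species <- function(species, probes) {
      n_per <- design$samples_per_tissue_per_species
      tiss <- rep(design$tissues, each = n_per)
      sample_id <- sprintf("%s_%s_s%02d", species, tiss,
                           unlist(lapply(design$tissues,
                                         function(t) seq_len(n_per))))
      # two experiments per tissue (one when <4 samples), mimicking
      # multi-lab compendia
      experiment <- unlist(lapply(design$tissues, function(t) {
        n_exp <- if (n_per >= 4L) 2L else 1L
        sprintf("%s_exp_%s_%d", species, t,
                rep(seq_len(n_exp), length.out = n_per))
      }))
      annot <- data.frame(sample_id = sample_id, species = species,
                          tissue = tiss, experiment = experiment,
                          stringsAsFactors = FALSE)

      ns <- length(sample_id)
      # gene-level signal matrix
      g_mat <- matrix(rnorm(ng * ns, mean = 0, sd = 1), ng, ns) * sd_gene + 8
      for (i in spec_idx) {
        in_t <- tiss == spec_tissue[i]
        # signature genes are up-shifted by effect_size and modulated
        # across the conditions collected under one tissue category with
        # the gene's conserved amplitude
        g_mat[i, in_t] <- g_mat[i, in_t] + design$effect_size +
          amp[i] * rnorm(sum(in_t))
      }
      # batch: per (experiment, gene-block) additive scalar
      if (design$batch_sd > 0) {
        exps <- unique(experiment)
        batch <- matrix(rnorm(length(exps) * n_blocks, sd = design$batch_sd),
                        n_blocks, length(exps), dimnames = list(NULL, exps))
        g_mat <- g_mat + batch[block_of, experiment]
      }
      # map genes to probesets (all probesets of a gene share its signal)
      ps_ids <- unique(probes$probeset_id)
      ps_gene <- probes$gene_id[match(ps_ids, probes$probeset_id)]
      gene_key <- if (species == "speciesA") gene_a else truth$ortholog_map$gene_b
      idx <- match(ps_gene, gene_key)
      m <- g_mat[idx, , drop = FALSE]
      # probeset-level measurement noise (small, so probesets of one gene
      # are highly but not perfectly correlated)
      m <- m + matrix(rnorm(length(m), sd = design$noise_sd / 4), nrow(m))
      if (species == "speciesB" && design$species_shift_sd > 0) {
        m <- m + rnorm(nrow(m), sd = design$species_shift_sd)
      }
      dimnames(m) <- list(ps_ids, sample_id)
      list(expr = expr_matrix(m, "raw"), annot = annot)
    }

    a <- make_species("speciesA", universe$probes_a)
    b <- make_species("speciesB", universe$probes_b)
    list(expr_a = a$expr, expr_b = b$expr,
         annot_a = a$annot, annot_b = b$annot)
  })
}

#' Generate a synthetic per-array QC metrics table
#'
#' Passing arrays have all six metrics drawn strictly inside the default
#' acceptance ranges (see [qc_thresholds()]); failing arrays violate at
#' least one range. True labels are recorded in the `truth` column.
#'
#' @param n_arrays Number of arrays.
#' @param fail_fraction Proportion of arrays to plant as failures
#'   (`round(n_arrays * fail_fraction)` arrays fail).
#' @param seed Integer seed.
#' @return A data.frame with columns `array_id`, `AvgBg`, `PP`, `RNAdeg`,
#'   `sfs`, `nuse`, `rle`, `truth` (`"pass"`/`"fail"`).
#' @export
generate_qc_table <- function(n_arrays, fail_fraction, seed = 1L) {
  stop_if_not_count(n_arrays, "n_arrays")
  stop_if_not_prob(fail_fraction, "fail_fraction")
  th <- qc_thresholds()
  inner <- function(n, lo, hi) {
    pad <- 0.1 * (hi - lo)
    runif(n, lo + pad, hi - pad)
  }
  with_seed(seed, {
    n_fail <- round(n_arrays * fail_fraction)
    label <- rep("pass", n_arrays)
    if (n_fail > 0) label[sample.int(n_arrays, n_fail)] <- "fail"
    df <- data.frame(
      array_id = sprintf("array%04d", seq_len(n_arrays)),
      AvgBg = inner(n_arrays, th$avgbg_range[1], th$avgbg_range[2]),
      PP = inner(n_arrays, th$pp_range[1], th$pp_range[2]),
      RNAdeg = runif(n_arrays, 0.3, th$rnadeg_max - 0.1),
      sfs = inner(n_arrays, th$sfs_range[1], th$sfs_range[2]),
      nuse = inner(n_arrays, th$nuse_range[1], th$nuse_range[2]),
      rle = inner(n_arrays, th$rle_range[1], th$rle_range[2]),
      truth = label,
      stringsAsFactors = FALSE
    )
    # failures: push 1 or 2 randomly chosen metrics outside their range
    break_metric <- list(
      AvgBg = function() if (runif(1) < 0.5) runif(1, 0, 19) else runif(1, 151, 400),
      PP = function() if (runif(1) < 0.5) runif(1, 0, 24) else runif(1, 66, 100),
      RNAdeg = function() runif(1, th$rnadeg_max, 4),
      sfs = function() if (runif(1) < 0.5) runif(1, 0, 0.09) else runif(1, 2.6, 6),
      nuse = function() if (runif(1) < 0.5) runif(1, 0.8, 0.969) else runif(1, 1.051, 1.2),
      rle = function() if (runif(1) < 0.5) runif(1, -0.5, -0.151) else runif(1, 0.151, 0.5)
    )
    for (i in which(label == "fail")) {
      broken <- sample(names(break_metric), sample.int(2L, 1L))
      for (metric in broken) df[i, metric] <- break_metric[[metric]]()
    }
    df
  })
}
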