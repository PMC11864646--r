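# Seeded synthetic-data generators. Every generator is a pure function of
# (parameters, seed) built on R's default Mersenne-Twister RNG: the same seed
# reproduces the same output bit-exactly, and ground truth is returned beside
# the data so each pipeline stage can be tested without external downloads.
#
# Noise models: lognormal (normal in log2 units) for expression and ion
# abundances, matching the multiplicative error of both assays; normal in
# cycles for qPCR Ct values.

# Background sequences are drawn from the 20-letter alphabet minus {Q, K, R}:
# without Q or K no window has an anchor, and without K or R no body can meet
# the positive-residue quota, so the background is provably motif-free.
# Planted motifs get 4-residue glycine flanks, so every window overlapping
# (but not equal to) a planted motif contains a body glycine and is invalid.
.BACKGROUND_AA <- setdiff(AA_STANDARD, c("Q", "K", "R"))
.NEUTRAL_FLANK <- "GGGG"

# Exemplar motifs per class, each satisfying exactly one class (asserted in
# the test suite against the classifier).
.MOTIF_EXEMPLARS <- list(
  CANONICAL = c("KFERQ", "QKILD", "QRLDF", "DIKRQ"),
  PHOSPHO_GENERATED = c("QKSLV", "QRTFV", "VSRKQ"),
  ACETYL_GENERATED = c("KFERK", "KILDK", "DIRLK")
)

#' Generate a synthetic proteome with planted KFERQ-like motifs
#'
#' Background sequences are motif-free by construction (drawn from an
#' alphabet without anchor or positive residues); the requested number of
#' motifs of each class is planted at recorded positions with neutral
#' glycine flanks, so the scanner should find exactly the planted hits.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Length range (min, max) of the background before
#'   planting; every protein must be able to host its motifs (13 residues
#'   per planted motif).
#' @param planted Named numeric vector of total motif counts per class
#'   (names among `CANONICAL`, `PHOSPHO_GENERATED`, `ACETYL_GENERATED`);
#'   motifs are assigned to proteins uniformly at random.
#' @param seed Integer seed.
#' @return A list with `records` (protein data frame as from
#'   [read_fasta()]) and `truth` (data frame: `protein_id`, `start`,
#'   `pentapeptide`, `class` — one row per planted motif).
#' @export
generate_proteome <- function(n_proteins = 50,
                              length_range = c(60, 120),
                              planted = c(CANONICAL = 10,
                                          PHOSPHO_GENERATED = 10,
                                          ACETYL_GENERATED = 10),
                              seed = 1) {
  stopifnot(n_proteins >= 1, length_range[1] >= 5,
            length_range[2] >= length_range[1])
  if (length(planted) > 0 &&
      !all(names(planted) %in% MOTIF_CLASSES)) {
    stop("names of 'planted' must be motif classes")
  }
  with_seed(seed, {
    plan <- rep(names(planted), times = planted)
    host <- if (length(plan) > 0) {
      sample(n_proteins, length(plan), replace = TRUE)
    } else integer(0)
    per_protein <- split(plan, factor(host, levels = seq_len(n_proteins)))

    ids <- sprintf("synth_prot_%03d", seq_len(n_proteins))
    seqs <- character(n_proteins)
    truth_rows <- list()
    for (i in seq_len(n_proteins)) {
      classes_here <- per_protein[[i]]
      k <- length(classes_here)
      if (13L * k + 1L > length_range[2]) {
        stop("infeasible planting: protein ", ids[i], " would need ",
             13L * k + 1L, " residues for ", k, " motif(s), above the ",
             "declared maximum length ", length_range[2])
      }
      target_len <- if (length_range[1] == length_range[2]) {
        length_range[1]
      } else {
        sample(length_range[1]:length_range[2], 1L)
      }
      # k planted segments of 13 + k+1 background gaps
      gap_total <- max(target_len - 13L * k, k + 1L)
      cuts <- sort(sample(gap_total - 1L, k, replace = FALSE))
      gaps <- diff(c(0L, cuts, gap_total))
      pieces <- character(2L * k + 1L)
      pos <- 0L
      for (j in seq_len(k)) {
        bg <- paste(sample(.BACKGROUND_AA, gaps[j], replace = TRUE),
                    collapse = "")
        motif <- sample(.MOTIF_EXEMPLARS[[classes_here[j]]], 1L)
        pieces[2L * j - 1L] <- bg
        pieces[2L * j] <- paste0(.NEUTRAL_FLANK, motif, .NEUTRAL_FLANK)
        pos <- pos + gaps[j] + 4L
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          protein_id = ids[i], start = pos, pentapeptide = motif,
          class = classes_here[j], stringsAsFactors = FALSE)
        pos <- pos + 9L
      }
      pieces[2L * k + 1L] <- paste(
        sample(.BACKGROUND_AA, gaps[k + 1L], replace = TRUE), collapse = "")
      seqs[i] <- paste(pieces, collapse = "")
    }
    truth <- if (length(truth_rows) > 0) {
      do.call(rbind, c(truth_rows, list(make.row.names = FALSE)))
    } else {
      data.frame(protein_id = character(0), start = integer(0),
                 pentapeptide = character(0), class = character(0),
                 stringsAsFactors = FALSE)
    }
    records <- data.frame(id = ids,
                          description = "synthetic motif-planted protein",
                          sequence = seqs, stringsAsFactors = FALSE)
    cma_log("generate_proteome: %d proteins, %d planted motifs, seed %d",
            n_proteins, nrow(truth), seed)
    list(records = records, truth = truth)
  })
}

#' Generate a two-group CMA-network expression table
#'
#' Emulates the two study designs used with the CMA activation score: a
#' knockout (one network gene driven to 0/undetected in the treated group)
#' and an environmental stressor (a coordinated fold-change of the network's
#' positive elements). Control samples sit at baseline 1 with lognormal
#' noise of `noise_sd_log2` log2 units.
#'
#' @param network A `"cma_network"`; weighted with [assign_weights()] if
#'   not already.
#' @param design `"knockout"` or `"stressor"`.
#' @param gene Gene to knock out (knockout design); must be in the network.
#' @param fold Fold-change applied to the stressor's target genes.
#' @param targets Gene ids targeted by the stressor; default all
#'   positive-direction network genes.
#' @param n_per_group Samples per group (>= 2).
#' @param noise_sd_log2 Biological noise SD in log2 units.
#' @param seed Integer seed.
#' @return A list with `expr` (samples x genes matrix), `groups` (named
#'   vector, `"control"`/`"treated"`), and `truth`: the design, the
#'   expected sign of (treated - control) mean score, the closed-form
#'   expected difference and the transform under which it is exact
#'   (`"fold_change"` for a knockout — the only transform with a finite
#'   value for an undetected transcript — and `"log2_fold_change"` for a
#'   stressor).
#' @export
generate_network_expression <- function(network,
                                        design = c("knockout", "stressor"),
                                        gene = "lamp2a_c31", fold = 2,
                                        targets = NULL, n_per_group = 7,
                                        noise_sd_log2 = 0.3, seed = 1) {
  design <- match.arg(design)
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  net <- if (anyNA(network$weight)) assign_weights(network) else
    as.data.frame(network)
  genes <- net$gene_id
  if (design == "knockout" && !(gene %in% genes)) {
    stop("knockout gene '", gene, "' is not in the network")
  }
  if (design == "stressor") {
    if (is.null(targets)) targets <- genes[net$direction == 1L]
    if (!all(targets %in% genes)) stop("unknown stressor target gene(s)")
    if (fold <= 0) stop("fold must be positive")
  }
  with_seed(seed, {
    samples <- c(paste0("control_", seq_len(n_per_group)),
                 paste0("treated_", seq_len(n_per_group)))
    groups <- stats::setNames(rep(c("control", "treated"),
                                  each = n_per_group), samples)
    expr <- matrix(2^stats::rnorm(length(samples) * length(genes),
                                  sd = noise_sd_log2),
                   nrow = length(samples), ncol = length(genes),
                   dimnames = list(samples, genes))
    treated <- groups == "treated"
    if (design == "knockout") {
      expr[treated, gene] <- 0
      w <- net$weight[net$gene_id == gene]
      d <- net$direction[net$gene_id == gene]
      truth <- list(design = design, gene = gene,
                    expected_sign = -sign(w * d),
                    expected_difference = -w * d * 1,
                    exact_under_transform = "fold_change")
    } else {
      expr[treated, targets] <- expr[treated, targets] * fold
      sel <- net$gene_id %in% targets
      delta <- sum(net$weight[sel] * net$direction[sel]) * log2(fold)
      truth <- list(design = design, fold = fold, targets = targets,
                    expected_sign = sign(delta),
                    expected_difference = delta,
                    exact_under_transform = "log2_fold_change")
    }
    cma_log("generate_network_expression: %s design, %d+%d samples, seed %d",
            design, n_per_group, n_per_group, seed)
    list(expr = expr, groups = groups, truth = truth)
  })
}

# Connectivity of a protein's run graph under a candidate observation mask:
# runs are linked when they share at least one observed ion.
.mask_connected <- function(mask) {
  obs_runs <- which(colSums(mask) > 0L)
  if (length(obs_runs) <= 1L) return(TRUE)
  comp <- seq_along(obs_runs)
  for (i in seq_len(nrow(mask))) {
    on <- which(mask[i, obs_runs])
    if (length(on) > 1L) {
      old <- unique(comp[on])
      comp[comp %in% old] <- comp[on[1L]]
    }
  }
  length(unique(comp)) == 1L
}

#' Generate multi-run ion abundances with known protein run factors
#'
#' Each ion's abundance is `base_ion x factor[protein, run] x 2^noise`,
#' with lognormal base intensities and noise; a fraction of cells is then
#' removed at random subject to keeping every ion observed at least once
#' and every protein's run graph connected (so the quantification remains
#' well-posed).
#'
#' @param n_proteins,n_runs,ions_per_protein Dimensions.
#' @param true_run_factors Optional proteins-by-runs matrix of true relative
#'   abundances; default lognormal with SD 1 log2 unit.
#' @param noise_sd_log2 Ion-level noise SD in log2 units.
#' @param missing_rate Target fraction of removed cells in `[0, 1)`; the
#'   achieved rate can be lower when connectivity forbids removals.
#' @param seed Integer seed.
#' @return A list with `ions` (long table: `protein_id`, `ion_id`,
#'   `run_id`, `abundance`) and `truth` (list with `run_factors`, the
#'   proteins-by-runs matrix actually used).
#' @export
generate_ion_abundances <- function(n_proteins = 10, n_runs = 6,
                                    ions_per_protein = 5,
                                    true_run_factors = NULL,
                                    noise_sd_log2 = 0, missing_rate = 0,
                                    seed = 1) {
  stopifnot(ions_per_protein >= 1, missing_rate >= 0, missing_rate < 1)
  with_seed(seed, {
    prots <- sprintf("synth_prot_%03d", seq_len(n_proteins))
    runs <- sprintf("run_%d", seq_len(n_runs))
    if (is.null(true_run_factors)) {
      true_run_factors <- matrix(2^stats::rnorm(n_proteins * n_runs, sd = 1),
                                 nrow = n_proteins,
                                 dimnames = list(prots, runs))
    } else {
      stopifnot(nrow(true_run_factors) == n_proteins,
                ncol(true_run_factors) == n_runs,
                all(true_run_factors > 0))
      dimnames(true_run_factors) <- list(prots, runs)
    }
    rows <- list()
    for (p in seq_len(n_proteins)) {
      base <- 2^stats::rnorm(ions_per_protein, mean = 10, sd = 1.5)
      ab <- outer(base, true_run_factors[p, ]) *
        2^matrix(stats::rnorm(ions_per_protein * n_runs,
                              sd = noise_sd_log2),
                 nrow = ions_per_protein)
      mask <- matrix(TRUE, ions_per_protein, n_runs)
      if (missing_rate > 0) {
        n_remove <- floor(missing_rate * length(mask))
        order_cells <- sample(length(mask))
        removed <- 0L
        for (cell in order_cells) {
          if (removed >= n_remove) break
          trial <- mask
          trial[cell] <- FALSE
          i <- (cell - 1L) %% ions_per_protein + 1L
          if (sum(trial[i, ]) >= 1L && .mask_connected(trial)) {
            mask <- trial
            removed <- removed + 1L
          }
        }
      }
      obs <- which(mask, arr.ind = TRUE)
      rows[[p]] <- data.frame(
        protein_id = prots[p],
        ion_id = sprintf("%s_ion_%02d", prots[p], obs[, 1L]),
        run_id = runs[obs[, 2L]],
        abundance = ab[obs], stringsAsFactors = FALSE)
    }
    ions <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    cma_log(
      "generate_ion_abundances: %d proteins x %d runs x %d ions, seed %d",
      n_proteins, n_runs, ions_per_protein, seed)
    list(ions = ions, truth = list(run_factors = true_run_factors))
  })
}

#' Generate a qPCR Ct table with known fold changes
#'
#' The target gene's Ct is `ct_baseline - log2(true fold) + noise` (one
#' cycle earlier per doubling); the reference gene is held at the baseline
#' (plus the same noise model).
#'
#' @param groups Named integer vector: samples per group.
#' @param true_fold_changes Named positive vector, one fold per group
#'   (relative expression of the target gene vs the reference gene).
#' @param ct_baseline Baseline threshold cycle.
#' @param noise_sd_cycles Technical noise SD in cycles.
#' @param seed Integer seed.
#' @return A list with `table` (data frame: `sample_id`, `group`,
#'   `gene_id` in `target`/`reference`, `ct`, `efficiency` = 2) and `truth`
#'   (the fold-change vector).
#' @export
generate_qpcr_table <- function(groups = c(control = 4, treated = 4),
                                true_fold_changes = c(control = 1,
                                                      treated = 2),
                                ct_baseline = 20, noise_sd_cycles = 0.2,
                                seed = 1) {
  if (!setequal(names(groups), names(true_fold_changes))) {
    stop("'groups' and 'true_fold_changes' must share names")
  }
  if (any(true_fold_changes <= 0)) stop("fold changes must be positive")
  with_seed(seed, {
    rows <- list()
    for (g in names(groups)) {
      for (i in seq_len(groups[[g]])) {
        sid <- paste0(g, "_", i)
        ct_t <- ct_baseline - log2(true_fold_changes[[g]]) +
          stats::rnorm(1, sd = noise_sd_cycles)
        ct_r <- ct_baseline + stats::rnorm(1, sd = noise_sd_cycles)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, group = g,
          gene_id = c("target", "reference"), ct = c(ct_t, ct_r),
          efficiency = 2, stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    cma_log("generate_qpcr_table: %d samples, seed %d", sum(groups), seed)
    list(table = tab, truth = list(fold_changes = true_fold_changes))
  })
}
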