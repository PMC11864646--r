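# The CMA activation score: a weighted, signed aggregate of the expression of
# CMA network genes (effectors, positive and negative modulators), used as a
# transcriptional proxy for CMA activation status.
#
# Weighting: every gene in a paralog family of n copies carries weight 1/n,
# except the rate-limiting LAMP2A family, which carries a total weight of 2
# split across its paralogs in proportion to their measured contribution to
# CMA activity (equal split by default). Each weighted, transformed
# expression value is multiplied by the gene's direction (+1 positive
# impact on CMA, -1 negative) and summed per sample.

#' Build an in-code example CMA network
#'
#' A small CMA network shaped like the salmonid situation: duplicated
#' effector families (the lamp2a receptor pair, hspa8 and hsp90 chaperone
#' pairs), singleton positive modulators, and negative modulators including a
#' duplicated akt1 pair. Useful for examples and simulations.
#'
#' @return An unweighted `"cma_network"` data frame (see
#'   [read_network_config()]).
#' @export
example_cma_network <- function() {
  df <- data.frame(
    gene_id = c("lamp2a_c31", "lamp2a_c14", "hspa8a", "hspa8b",
                "hsp90aa1.1", "hsp90aa1.2", "phlpp1", "nfe2l2",
                "akt1a", "akt1b", "rictor", "ctsa"),
    functional_group = c(rep("effector", 6),
                         rep("positive_modulator", 2),
                         rep("negative_modulator", 4)),
    direction = c(rep(1L, 8), rep(-1L, 4)),
    paralog_family = c("lamp2a", "lamp2a", "hspa8", "hspa8",
                       "hsp90aa1", "hsp90aa1", "phlpp1", "nfe2l2",
                       "akt1", "akt1", "rictor", "ctsa"),
    stringsAsFactors = FALSE)
  df$n_paralogs <- as.integer(table(df$paralog_family)[df$paralog_family])
  df$weight <- NA_real_
  class(df) <- c("cma_network", "data.frame")
  df
}

#' Assign paralog-aware weights to a CMA network
#'
#' Every gene in a paralog family of `n` members gets weight `1/n`. The
#' LAMP2A family — the rate-limiting factor of CMA — gets a family total of
#' exactly 2, split across its paralogs in proportion to
#' `lamp2a_contributions` (equal split by default; measured relative
#' contributions from a reporter assay can be supplied). Explicit per-gene
#' weights already present in the network override the derived ones and are
#' logged.
#'
#' @param network A `"cma_network"` data frame ([read_network_config()],
#'   [example_cma_network()]).
#' @param lamp2a_family Name of the paralog family to treat as LAMP2A
#'   (default `"lamp2a"`); if absent from the network, all families get the
#'   plain 1/n rule.
#' @param lamp2a_contributions Optional numeric vector of per-paralog
#'   fractions, named by gene id or in network order of the family, positive
#'   and summing to 1 (tolerance 1e-9).
#' @return The network with `weight` filled and an `is_lamp2a_family`
#'   column.
#' @examples
#' net <- assign_weights(example_cma_network())
#' sum(net$weight[net$is_lamp2a_family])  # exactly 2
#' @export
assign_weights <- function(network, lamp2a_family = "lamp2a",
                           lamp2a_contributions = NULL) {
  stopifnot(inherits(network, "cma_network") || is.data.frame(network))
  net <- as.data.frame(network)
  fam <- net$paralog_family
  net$n_paralogs <- as.integer(table(fam)[fam])
  net$is_lamp2a_family <- fam == lamp2a_family
  explicit <- !is.na(net$weight)
  derived <- 1 / net$n_paralogs

  if (any(net$is_lamp2a_family)) {
    idx <- which(net$is_lamp2a_family)
    n <- length(idx)
    contrib <- lamp2a_contributions
    if (is.null(contrib)) {
      contrib <- rep(1 / n, n)
    } else {
      if (length(contrib) != n) {
        stop("lamp2a_contributions must have one entry per '",
             lamp2a_family, "' paralog (", n, ")")
      }
      if (!is.null(names(contrib))) {
        if (!setequal(names(contrib), net$gene_id[idx])) {
          stop("lamp2a_contributions names do not match the family's genes")
        }
        contrib <- contrib[net$gene_id[idx]]
      }
      if (any(contrib <= 0)) stop("lamp2a_contributions must be positive")
      if (abs(sum(contrib) - 1) > 1e-9) {
        stop("lamp2a_contributions must sum to 1 (tolerance 1e-9)")
      }
    }
    derived[idx] <- 2 * contrib
  } else if (!is.null(lamp2a_contributions)) {
    stop("lamp2a_contributions given but family '", lamp2a_family,
         "' is not in the network")
  }

  net$weight <- ifelse(explicit, net$weight, derived)
  if (any(explicit)) {
    cma_log("assign_weights: explicit weight override for %s",
            paste(net$gene_id[explicit], collapse = ", "))
  }
  class(net) <- c("cma_network", "data.frame")
  net
}

.transform_expression <- function(expr, genes, transform,
                                  reference_sample_ids) {
  vals <- expr[, genes, drop = FALSE]
  if (transform %in% c("log2_fold_change", "fold_change")) {
    if (is.null(reference_sample_ids) || length(reference_sample_ids) == 0L) {
      stop("fold-change transforms need a non-empty reference group")
    }
    if (!all(reference_sample_ids %in% rownames(expr))) {
      stop("unknown reference sample id(s): ",
           paste(setdiff(reference_sample_ids, rownames(expr)),
                 collapse = ", "))
    }
    ref <- vapply(genes, function(g) {
      v <- expr[reference_sample_ids, g]
      v <- v[!is.na(v) & v > 0]
      if (length(v) == 0L) return(NA_real_)
      geometric_mean(v)
    }, numeric(1))
    fc <- sweep(vals, 2L, ref, "/")
    if (transform == "log2_fold_change") {
      nonpos <- !is.na(fc) & fc <= 0
      if (any(nonpos)) {
        warning("undetected (zero) expression under log2 transform: ",
                sum(nonpos), " cell(s) excluded")
        fc[nonpos] <- NA_real_
      }
      fc <- log2(fc)
    }
    fc
  } else { # zscore
    mu <- colMeans(vals, na.rm = TRUE)
    sd_ <- apply(vals, 2L, stats::sd, na.rm = TRUE)
    sd_[!is.finite(sd_) | sd_ == 0] <- NA_real_
    sweep(sweep(vals, 2L, mu, "-"), 2L, sd_, "/")
  }
}

#' Compute the per-sample CMA activation score
#'
#' For each sample, the score is the sum over network genes of
#' `weight x direction x t(expression)`, where `t` is the chosen transform.
#' Genes absent from the table or missing in a sample are excluded (listed
#' per sample); with `missing_policy = "exclude_renormalize"` (default) the
#' weights actually used in a sample are rescaled so that their absolute sum
#' equals the full network's absolute weight sum, keeping scores comparable
#' across tissues with different detected gene subsets.
#'
#' @param expr Numeric samples-by-genes matrix ([read_expression_table()]).
#' @param network A weighted `"cma_network"` ([assign_weights()]).
#' @param transform `"log2_fold_change"` (default; per-gene log2 ratio to the
#'   reference group's geometric mean, so the reference group is centred at
#'   0 and the score is additive in log2 effect sizes), `"fold_change"`
#'   (plain ratio; the only transform with a finite value for an undetected
#'   transcript, which contributes 0), or `"zscore"` (per-gene
#'   standardisation over all samples).
#' @param reference_sample_ids Sample ids of the reference (e.g. wild-type or
#'   normoxia) group; required for the fold-change transforms.
#' @param missing_policy `"exclude_renormalize"` (default) or `"exclude"`.
#' @param average If `TRUE`, additionally divide the score by the network's
#'   total absolute weight (weighted average rather than weighted sum); both
#'   conventions appear in the field, the sum is the default.
#'
#' @return An object of class `"cma_score_result"`: a data frame with
#'   `sample_id`, `score`, `n_genes_used`, `transform`, plus attributes
#'   `genes_excluded` (per-sample list), `contributions` (samples x genes
#'   matrix of weight x direction x transformed value) and `network`.
#' @examples
#' net <- assign_weights(example_cma_network())
#' expr <- matrix(1, nrow = 4, ncol = nrow(net),
#'                dimnames = list(paste0("s", 1:4), net$gene_id))
#' expr[3:4, "hspa8a"] <- 2  # doubled in the treated samples
#' compute_cma_score(expr, net, reference_sample_ids = c("s1", "s2"))
#' @export
compute_cma_score <- function(expr, network,
                              transform = c("log2_fold_change",
                                            "fold_change", "zscore"),
                              reference_sample_ids = NULL,
                              missing_policy = c("exclude_renormalize",
                                                 "exclude"),
                              average = FALSE) {
  transform <- match.arg(transform)
  missing_policy <- match.arg(missing_policy)
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("'expr' needs sample row names and gene column names")
  }
  net <- as.data.frame(network)
  if (anyNA(net$weight)) {
    stop("network is unweighted; run assign_weights() first")
  }

  present <- intersect(net$gene_id, colnames(expr))
  absent <- setdiff(net$gene_id, colnames(expr))
  if (length(present) == 0L) stop("all network genes missing from the table")
  if (length(absent) > 0L) {
    cma_log("compute_cma_score: %d network gene(s) absent from table: %s",
            length(absent), paste(absent, collapse = ", "))
  }

  tmat <- .transform_expression(expr, present, transform,
                                reference_sample_ids)
  w <- net$weight[match(present, net$gene_id)]
  d <- net$direction[match(present, net$gene_id)]
  signed <- sweep(tmat, 2L, w * d, "*")
  total_abs_weight <- sum(abs(net$weight))

  samples <- rownames(expr)
  score <- numeric(length(samples))
  n_used <- integer(length(samples))
  excluded <- vector("list", length(samples))
  names(excluded) <- samples
  for (i in seq_along(samples)) {
    used <- !is.na(signed[i, ])
    n_used[i] <- sum(used)
    excluded[[i]] <- c(absent, present[!used])
    if (n_used[i] == 0L) {
      warning("sample '", samples[i], "': no usable network gene; score NA")
      score[i] <- NA_real_
      next
    }
    s <- sum(signed[i, used])
    if (missing_policy == "exclude_renormalize") {
      s <- s * total_abs_weight / sum(abs(w[used]))
    }
    if (average) s <- s / total_abs_weight
    score[i] <- s
  }

  res <- data.frame(sample_id = samples, score = score,
                    n_genes_used = n_used, transform = transform,
                    stringsAsFactors = FALSE)
  attr(res, "genes_excluded") <- excluded
  attr(res, "contributions") <- signed
  attr(res, "network") <- net
  attr(res, "average") <- average
  attr(res, "missing_policy") <- missing_policy
  class(res) <- c("cma_score_result", "data.frame")
  cma_log("compute_cma_score: %d samples, transform=%s, %s, sum|w|=%g",
          length(samples), transform, missing_policy, total_abs_weight)
  res
}

#' @export
print.cma_score_result <- function(x, ...) {
  cat("CMA activation scores (", attr(x, "transform") %||% x$transform[1],
      if (isTRUE(attr(x, "average"))) ", weighted average" else
        ", weighted sum", ")\n", sep = "")
  print(as.data.frame(x)[, c("sample_id", "score", "n_genes_used")],
        row.names = FALSE, ...)
  invisible(x)
}

#' Compare CMA scores between groups
#'
#' Two-group designs use a two-tailed Student t-test on the per-sample
#' scores; tissue-by-condition designs use a two-way ANOVA with tissue and
#' condition factors (with interaction). Tests are delegated to
#' [stats::t.test()] and [stats::aov()].
#'
#' @param results A `"cma_score_result"` (or data frame with `sample_id` and
#'   `score`).
#' @param group_labels For `two_group`: a vector of two group labels aligned
#'   with the samples (or named by sample id). For `tissue_by_condition`: a
#'   data frame with columns `tissue` and `condition` aligned the same way.
#' @param design `"two_group"` or `"tissue_by_condition"`.
#' @return A list of class `"cma_score_comparison"`: per-group means and SDs,
#'   the test used, statistic and p-value(s).
#' @export
compare_scores <- function(results, group_labels,
                           design = c("two_group", "tissue_by_condition")) {
  design <- match.arg(design)
  df <- as.data.frame(results)
  stopifnot(all(c("sample_id", "score") %in% names(df)))
  score <- df$score

  if (design == "two_group") {
    g <- group_labels
    if (!is.null(names(g))) g <- g[df$sample_id]
    g <- factor(g)
    if (nlevels(g) != 2L) stop("two_group design needs exactly 2 groups")
    if (any(table(g) < 2L)) stop("each group needs at least 2 samples")
    tt <- stats::t.test(score ~ g, var.equal = TRUE)
    means <- tapply(score, g, mean)
    out <- list(design = design, test = "two-tailed Student t-test",
                groups = levels(g), n = as.integer(table(g)),
                means = means, sds = tapply(score, g, stats::sd),
                mean_difference = unname(diff(means)),
                statistic = unname(tt$statistic), p_value = tt$p.value)
  } else {
    gl <- as.data.frame(group_labels)
    stopifnot(all(c("tissue", "condition") %in% names(gl)))
    if (!is.null(rownames(gl)) && all(df$sample_id %in% rownames(gl))) {
      gl <- gl[df$sample_id, ]
    }
    gl$tissue <- factor(gl$tissue)
    gl$condition <- factor(gl$condition)
    if (any(table(gl$tissue, gl$condition) < 2L)) {
      stop("each tissue x condition cell needs at least 2 samples")
    }
    fit <- stats::aov(score ~ tissue * condition, data = gl)
    tab <- summary(fit)[[1L]]
    pv <- tab[["Pr(>F)"]]
    names(pv) <- trimws(rownames(tab))
    out <- list(design = design, test = "two-way ANOVA (tissue x condition)",
                means = tapply(score, list(gl$tissue, gl$condition), mean),
                anova_table = tab,
                p_value = pv[["condition"]],
                p_values = pv[!is.na(pv)])
  }
  class(out) <- "cma_score_comparison"
  cma_log("compare_scores: %s, p=%g", out$test, out$p_value)
  out
}

#' @export
print.cma_score_comparison <- function(x, ...) {
  cat("CMA score comparison:", x$test, "\n")
  if (x$design == "two_group") {
    cat(sprintf("  %s: mean %.4g (sd %.3g, n=%d)\n", x$groups,
                x$means, x$sds, x$n), sep = "")
    cat(sprintf("  mean difference %.4g, t = %.3f, p = %.4g\n",
                x$mean_difference, x$statistic, x$p_value))
  } else {
    print(x$anova_table)
  }
  invisible(x)
}

#' @export
plot.cma_score_result <- function(x, groups = NULL, ...) {
  if (is.null(groups)) {
    graphics::barplot(x$score, names.arg = x$sample_id, las = 2,
                      ylab = "CMA score", ...)
  } else {
    if (!is.null(names(groups))) groups <- groups[x$sample_id]
    graphics::boxplot(x$score ~ factor(groups), ylab = "CMA score",
                      xlab = "", ...)
  }
  invisible(x)
}
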