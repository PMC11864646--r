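# Label-free protein quantification by median-ratio fitting.
#
# For each protein, an abundance ratio between every pair of runs is taken as
# the median over that protein's ions of the per-ion abundance ratio
# (pairwise-complete ions only). A least-squares fit in log2 space
# reconciles the pairwise ratios into one relative abundance per run, and the
# per-run abundances are finally rescaled so that their sum equals the
# protein's summed observed ion abundance across all runs. Differential
# abundance between two groups of runs is then assessed with a two-tailed
# equal-variance t-test on log2 abundances and classified with fold-change
# and p-value thresholds.

#' Pairwise median run-to-run ratios for one protein
#'
#' @param ion_mat Numeric matrix of ion abundances for a single protein:
#'   ions in rows, runs in columns, `NA` for missing. Zeros are treated as
#'   missing (log-space convention).
#'
#' @return A runs-by-runs matrix `M` with `M[r, s]` the median over ions
#'   observed in both runs of `abundance[ion, r] / abundance[ion, s]`
#'   (even counts: mean of the two middle values). `M[s, r] = 1 / M[r, s]`
#'   by construction, the diagonal is 1, and pairs with no shared ion are
#'   `NA` (flagged in the `"undefined_pairs"` attribute).
#' @export
pairwise_median_ratios <- function(ion_mat) {
  stopifnot(is.matrix(ion_mat), is.numeric(ion_mat))
  if (nrow(ion_mat) == 0L) stop("protein has zero ions")
  if (any(ion_mat < 0, na.rm = TRUE)) stop("negative ion abundance")
  ion_mat[ion_mat == 0] <- NA_real_
  runs <- colnames(ion_mat) %||% paste0("run", seq_len(ncol(ion_mat)))
  k <- ncol(ion_mat)
  M <- diag(1, k)
  dimnames(M) <- list(runs, runs)
  undefined <- character(0)
  if (k >= 2L) {
    for (r in 1:(k - 1L)) {
      for (s in (r + 1L):k) {
        shared <- !is.na(ion_mat[, r]) & !is.na(ion_mat[, s])
        if (!any(shared)) {
          M[r, s] <- M[s, r] <- NA_real_
          undefined <- c(undefined, paste0(runs[r], "/", runs[s]))
          next
        }
        m <- stats::median(ion_mat[shared, r] / ion_mat[shared, s])
        M[r, s] <- m
        M[s, r] <- 1 / m
      }
    }
  }
  attr(M, "undefined_pairs") <- undefined
  M
}

# Connected components of the defined-ratio graph, as a membership vector.
.ratio_components <- function(M) {
  k <- nrow(M)
  comp <- seq_len(k)
  for (r in seq_len(k)) {
    for (s in seq_len(k)) {
      if (r != s && !is.na(M[r, s])) {
        old <- comp[s]
        comp[comp == old] <- comp[r]
      }
    }
  }
  match(comp, unique(comp))
}

#' Fit per-run protein abundances from a pairwise ratio matrix
#'
#' Solves, in log2 space, the least-squares problem with one observation
#' `x_r - x_s = log2 M[r, s]` per defined unordered run pair. The additive
#' gauge freedom is fixed by rescaling so that the per-run abundances sum to
#' `ion_total`, the protein's summed observed ion abundance across all runs.
#'
#' @param M Ratio matrix from [pairwise_median_ratios()].
#' @param ion_total Positive scalar: the protein's total observed ion
#'   abundance over all runs.
#' @return Named numeric vector of per-run abundances summing to
#'   `ion_total`.
#' @examples
#' M <- matrix(c(1, 0.5, 2, 1), 2, 2,
#'             dimnames = list(c("r1", "r2"), c("r1", "r2")))
#' fit_protein_abundances(M, ion_total = 18)  # c(r1 = 12, r2 = 6)
#' @export
fit_protein_abundances <- function(M, ion_total) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  if (!is.numeric(ion_total) || length(ion_total) != 1L || ion_total <= 0) {
    stop("'ion_total' must be a positive scalar")
  }
  k <- nrow(M)
  runs <- rownames(M) %||% paste0("run", seq_len(k))
  if (k == 1L) {
    out <- ion_total
    names(out) <- runs
    return(out)
  }
  comp <- .ratio_components(M)
  if (length(unique(comp)) > 1L) {
    parts <- vapply(unique(comp), function(cc) {
      paste0("{", paste(runs[comp == cc], collapse = ", "), "}")
    }, character(1))
    stop("run graph is disconnected: components ",
         paste(parts, collapse = " "))
  }
  pairs <- which(upper.tri(M) & !is.na(M), arr.ind = TRUE)
  A <- matrix(0, nrow = nrow(pairs), ncol = k)
  b <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    r <- pairs[i, 1L]; s <- pairs[i, 2L]
    A[i, r] <- 1; A[i, s] <- -1
    b[i] <- log2(M[r, s])
  }
  # pin run 1 at log-abundance 0; the gauge is refixed by the rescaling
  x <- c(0, qr.coef(qr(A[, -1L, drop = FALSE]), b))
  x[is.na(x)] <- 0
  ab <- 2^x
  ab <- ab * ion_total / sum(ab)
  names(ab) <- runs
  ab
}

#' Quantify all proteins in a long ion table
#'
#' Runs [pairwise_median_ratios()] and [fit_protein_abundances()] per
#' protein. For each protein only the runs in which it has at least one
#' observed ion receive an abundance; other runs are `NA`.
#'
#' @param ion_df Long ion table ([read_ion_table()]): columns `protein_id`,
#'   `ion_id`, `run_id`, `abundance`.
#' @return Numeric proteins-by-runs matrix of fitted abundances; each row
#'   sums (over non-`NA` runs) to that protein's total observed ion
#'   abundance.
#' @export
quantify_proteins <- function(ion_df) {
  stopifnot(is.data.frame(ion_df),
            all(c("protein_id", "ion_id", "run_id", "abundance") %in%
                  names(ion_df)))
  runs <- unique(ion_df$run_id)
  prots <- unique(ion_df$protein_id)
  out <- matrix(NA_real_, nrow = length(prots), ncol = length(runs),
                dimnames = list(prots, runs))
  for (p in prots) {
    sub <- ion_df[ion_df$protein_id == p, ]
    ions <- unique(sub$ion_id)
    mat <- matrix(NA_real_, nrow = length(ions), ncol = length(runs),
                  dimnames = list(ions, runs))
    mat[cbind(match(sub$ion_id, ions), match(sub$run_id, runs))] <-
      sub$abundance
    mat[!is.na(mat) & mat == 0] <- NA_real_
    observed_runs <- colSums(!is.na(mat)) > 0L
    m <- mat[, observed_runs, drop = FALSE]
    M <- pairwise_median_ratios(m)
    ab <- fit_protein_abundances(M, ion_total = sum(m, na.rm = TRUE))
    out[p, observed_runs] <- ab
  }
  cma_log("quantify_proteins: %d proteins x %d runs", length(prots),
          length(runs))
  out
}

#' Differential abundance between two groups of runs
#'
#' Per protein: log2 fold change = mean log2 abundance in group 2 minus
#' group 1, and a two-tailed equal-variance Student t-test on the log2
#' abundances (delegated to [stats::t.test()]). Zero or missing abundances
#' are excluded per protein; proteins left with fewer than 2 runs in either
#' group are skipped (logged in the `"skipped"` attribute). Degenerate
#' zero-variance comparisons get `p_value = NA` and `degenerate = TRUE`.
#'
#' @param abundances Proteins-by-runs numeric matrix
#'   ([quantify_proteins()]).
#' @param groups Factor or character vector of two group labels, named by
#'   run id or aligned with the columns. The first level is the reference
#'   (fold changes are level 2 vs level 1).
#' @return A data frame of class `"cma_diff"`: `protein_id`,
#'   `log2_fold_change`, `p_value`, `n_g1`, `n_g2`, `degenerate`.
#' @export
differential_test <- function(abundances, groups) {
  stopifnot(is.matrix(abundances), is.numeric(abundances))
  g <- groups
  if (!is.null(names(g))) {
    if (!all(colnames(abundances) %in% names(g))) {
      stop("'groups' does not cover all runs")
    }
    g <- g[colnames(abundances)]
  }
  g <- factor(g)
  if (nlevels(g) != 2L) stop("exactly two groups are required")
  if (any(table(g) < 2L)) stop("each group needs at least 2 runs")
  lv <- levels(g)

  prots <- rownames(abundances) %||%
    paste0("protein", seq_len(nrow(abundances)))
  skipped <- character(0)
  rows <- vector("list", nrow(abundances))
  for (i in seq_len(nrow(abundances))) {
    a <- abundances[i, ]
    usable <- !is.na(a) & a > 0
    if (any(!is.na(a) & a == 0)) {
      cma_log("differential_test: zero abundance excluded for %s", prots[i])
    }
    x1 <- log2(a[usable & g == lv[1L]])
    x2 <- log2(a[usable & g == lv[2L]])
    if (length(x1) < 2L || length(x2) < 2L) {
      skipped <- c(skipped, prots[i])
      next
    }
    lfc <- mean(x2) - mean(x1)
    degenerate <- stats::sd(x1) == 0 && stats::sd(x2) == 0
    p <- if (degenerate) {
      if (lfc == 0) 1 else NA_real_
    } else {
      stats::t.test(x2, x1, var.equal = TRUE)$p.value
    }
    rows[[i]] <- data.frame(protein_id = prots[i], log2_fold_change = lfc,
                            p_value = p, n_g1 = length(x1),
                            n_g2 = length(x2), degenerate = degenerate,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows[!vapply(rows, is.null, logical(1))],
                          list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(protein_id = character(0),
                      log2_fold_change = numeric(0), p_value = numeric(0),
                      n_g1 = integer(0), n_g2 = integer(0),
                      degenerate = logical(0), stringsAsFactors = FALSE)
  }
  if (length(skipped) > 0L) {
    cma_log("differential_test: %d protein(s) skipped (group < 2 runs)",
            length(skipped))
  }
  attr(out, "groups") <- lv
  attr(out, "skipped") <- skipped
  class(out) <- c("cma_diff", "data.frame")
  out
}

#' Classify differential-abundance records as up/down/ns
#'
#' A protein is called `up` when `p < p_threshold` and its fold change
#' `2^log2_fold_change` exceeds `fc_threshold`, `down` when `p <
#' p_threshold` and the fold change is below `1/fc_threshold`, and `ns`
#' otherwise (including degenerate records with `NA` p). No multiple-testing
#' correction is applied by default (`p_adjust = "none"`); the defaults
#' (p < 0.05, fold change > 1.41) are the thresholds behind the headline
#' up/down percentages. A stricter fold-change cut of 2 is sometimes quoted
#' for the same kind of data and can be set via `fc_threshold`.
#'
#' @param records A `"cma_diff"` data frame ([differential_test()]).
#' @param p_threshold,fc_threshold Positive thresholds; defaults 0.05 and
#'   1.41.
#' @param p_adjust Multiple-testing correction passed to
#'   [stats::p.adjust()]; `"none"` by default.
#' @return `records` with a `call` column, plus a `"summary"` attribute
#'   (also returned by [summary.cma_diff()]): `n_identified`, `n_up`,
#'   `n_down`, `pct_up`, `pct_down` (percentages rounded to one decimal).
#' @export
classify_hits <- function(records, p_threshold = 0.05, fc_threshold = 1.41,
                          p_adjust = "none") {
  stopifnot(is.data.frame(records),
            all(c("protein_id", "log2_fold_change", "p_value") %in%
                  names(records)))
  if (p_threshold <= 0 || fc_threshold <= 0) stop("thresholds must be > 0")
  p <- stats::p.adjust(records$p_value, method = p_adjust)
  fc <- 2^records$log2_fold_change
  sig <- !is.na(p) & p < p_threshold
  call <- ifelse(sig & fc > fc_threshold, "up",
                 ifelse(sig & fc < 1 / fc_threshold, "down", "ns"))
  records$call <- call
  n <- nrow(records)
  smry <- list(n_identified = n, n_up = sum(call == "up"),
               n_down = sum(call == "down"),
               pct_up = round(100 * sum(call == "up") / n, 1),
               pct_down = round(100 * sum(call == "down") / n, 1),
               p_threshold = p_threshold, fc_threshold = fc_threshold,
               p_adjust = p_adjust)
  attr(records, "summary") <- smry
  class(records) <- c("cma_diff", "data.frame")
  cma_log("classify_hits: %d identified, %d up (%.1f%%), %d down (%.1f%%)",
          n, smry$n_up, smry$pct_up, smry$n_down, smry$pct_down)
  records
}

#' @export
summary.cma_diff <- function(object, ...) {
  smry <- attr(object, "summary")
  if (is.null(smry)) {
    stop("no classification yet; run classify_hits() first")
  }
  structure(smry, class = "summary.cma_diff")
}

#' @export
print.summary.cma_diff <- function(x, ...) {
  cat(sprintf(
    "%d proteins identified; %d up-regulated (%.1f%%), %d down-regulated (%.1f%%)\n",
    x$n_identified, x$n_up, x$pct_up, x$n_down, x$pct_down))
  cat(sprintf("thresholds: p < %g (%s correction), fold change > %g\n",
              x$p_threshold,
              if (x$p_adjust == "none") "no" else x$p_adjust,
              x$fc_threshold))
  invisible(x)
}

#' Volcano plot of a differential-abundance table
#'
#' @param x A classified `"cma_diff"` table ([classify_hits()]).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cma_diff <- function(x, ...) {
  col <- c(up = "red3", down = "blue3", ns = "grey60")
  cl <- if ("call" %in% names(x)) x$call else rep("ns", nrow(x))
  graphics::plot(x$log2_fold_change, -log10(x$p_value), col = col[cl],
                 pch = 16, cex = 0.6, xlab = "log2 fold change",
                 ylab = "-log10 p", ...)
  invisible(x)
}
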