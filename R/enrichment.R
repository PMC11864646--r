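# Motif-class enrichment between protein sets (e.g. up- vs down-regulated vs
# all identified proteins).

#' Motif-class prevalence across protein sets
#'
#' Tabulates, for each motif class, the proportion of proteins in each set
#' carrying at least one hit of that class, and the up-minus-down difference.
#'
#' @param report A `"motif_report"` ([summarize_motifs()]) whose
#'   `per_protein` table covers every id in `sets`.
#' @param sets Named list with elements `up`, `down` and `background`
#'   (character vectors of protein ids); `background` must contain both
#'   `up` and `down`, which are disjoint.
#' @return A list with `proportions` (data frame: `set`, `class`,
#'   `n_with_motif`, `n_total`, `proportion`) and `difference` (data frame:
#'   `class`, `up_minus_down`).
#' @export
motif_class_prevalence <- function(report, sets) {
  stopifnot(inherits(report, "motif_report"))
  need <- c("up", "down", "background")
  if (!all(need %in% names(sets))) {
    stop("'sets' must contain elements: ", paste(need, collapse = ", "))
  }
  for (nm in need) if (length(sets[[nm]]) == 0L) stop("empty set: ", nm)
  if (length(intersect(sets$up, sets$down)) > 0L) {
    stop("'up' and 'down' sets must be disjoint")
  }
  if (!all(c(sets$up, sets$down) %in% sets$background)) {
    stop("'background' must contain every protein in 'up' and 'down'")
  }
  pp <- report$per_protein
  unknown <- setdiff(sets$background, pp$protein_id)
  if (length(unknown) > 0L) {
    stop("unknown protein id(s) in sets: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }

  rows <- list()
  for (nm in need) {
    sel <- pp$protein_id %in% sets[[nm]]
    for (cl in MOTIF_CLASSES) {
      n_with <- sum(pp[sel, paste0("has_", tolower(cl))])
      rows[[length(rows) + 1L]] <- data.frame(
        set = nm, class = cl, n_with_motif = n_with,
        n_total = sum(sel), proportion = n_with / sum(sel),
        stringsAsFactors = FALSE)
    }
  }
  props <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  up <- props[props$set == "up", ]
  down <- props[props$set == "down", ]
  diff <- data.frame(class = up$class,
                     up_minus_down = up$proportion - down$proportion,
                     stringsAsFactors = FALSE)
  list(proportions = props, difference = diff)
}

#' Exact test of association for a 2x2 table
#'
#' For counts laid out as with-motif/without-motif by set1/set2
#' (`a` = set1 with, `b` = set2 with, `c` = set1 without, `d` = set2
#' without), reports the sample odds ratio `(a d)/(b c)` and the two-sided
#' exact p-value obtained by summing, over the hypergeometric distribution
#' conditional on the table margins, the probabilities of every table at
#' most as probable as the observed one (the common exact convention; no
#' continuity correction).
#'
#' @param table A 2x2 numeric matrix `rbind(c(a, b), c(c, d))`, or a length-4
#'   vector `c(a, b, c, d)` of nonnegative counts.
#' @return A list with `odds_ratio` (`Inf`, flagged via `infinite = TRUE`,
#'   when `b * c = 0`), `p_value`, and the counts.
#' @examples
#' fisher_association(c(10, 10, 5, 15))  # odds ratio 3
#' @export
fisher_association <- function(table) {
  x <- if (is.matrix(table)) as.vector(t(table)) else table
  if (length(x) != 4L || any(is.na(x)) || any(x < 0) ||
      any(x != round(x))) {
    stop("'table' must be four nonnegative integer counts")
  }
  a <- x[1L]; b <- x[2L]; c_ <- x[3L]; d <- x[4L]
  or <- if (b * c_ == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c_)
  }
  n1 <- a + c_   # set1 size
  n2 <- b + d    # set2 size
  k <- a + b     # total with motif
  if (n1 + n2 == 0L) stop("empty table")
  support <- max(0L, k - n2):min(k, n1)
  dens <- stats::dhyper(support, n1, n2, k)
  p_obs <- stats::dhyper(a, n1, n2, k)
  p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  p <- min(1, p)
  list(odds_ratio = or, infinite = is.infinite(or), p_value = p,
       counts = c(a = a, b = b, c = c_, d = d))
}
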