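# qPCR relative-expression arithmetic and the lysosomal binding/uptake
# arithmetic. Group-comparison statistics are delegated to stats::t.test and
# friends elsewhere; these are the closed-form expression formulas.

#' Relative expression by the delta-Ct method
#'
#' Assumes perfect doubling per cycle: returns
#' `2^-(ct_target - ct_reference)` — the expression of the target gene
#' relative to the reference gene in the same sample.
#'
#' @param ct_target,ct_reference Threshold cycles (positive, finite).
#'   Vectorised.
#' @return Dimensionless expression ratio(s).
#' @examples
#' relative_expression_dct(19, 20)  # one cycle earlier = twice the template
#' @export
relative_expression_dct <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference))) {
    stop("Ct values must be finite")
  }
  2^(-(ct_target - ct_reference))
}

#' Relative expression by the efficiency-corrected E-method
#'
#' Uses per-assay amplification efficiencies (factor per cycle, 2 = perfect
#' doubling): returns `e_target^(-ct_target) / e_reference^(-ct_reference)`,
#' computed in log space for numerical stability. With both efficiencies
#' equal to 2 this reduces exactly to [relative_expression_dct()].
#'
#' @param ct_target,ct_reference Threshold cycles (positive, finite).
#' @param e_target,e_reference Amplification efficiencies in (1, 2].
#' @return Dimensionless expression ratio(s).
#' @export
relative_expression_emethod <- function(ct_target, e_target,
                                        ct_reference, e_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference))) {
    stop("Ct values must be finite")
  }
  if (any(e_target <= 1 | e_target > 2) ||
      any(e_reference <= 1 | e_reference > 2)) {
    stop("efficiencies must lie in (1, 2]")
  }
  exp(ct_reference * log(e_reference) - ct_target * log(e_target))
}

#' Fold induction relative to a reference group
#'
#' Divides each value by the geometric mean of the reference group, so the
#' reference group's geometric mean of outputs is exactly 1. The geometric
#' (not arithmetic) mean is used because Ct-derived ratios are log-scale
#' quantities.
#'
#' @param values Positive expression ratios, one per sample; zeros are
#'   allowed for undetectable transcripts (e.g. a knocked-out gene) and give
#'   fold 0, flagged in the `"undetected"` attribute.
#' @param reference Indices, names or logical mask selecting the reference
#'   samples within `values`; reference values must be strictly positive.
#' @return Numeric vector of fold inductions (same names as `values`), with
#'   attribute `undetected` marking zero inputs.
#' @examples
#' fold_induction(c(wt1 = 1, wt2 = 4, ko = 8), reference = c("wt1", "wt2"))
#' @export
fold_induction <- function(values, reference) {
  if (!is.numeric(values) || length(values) == 0L) {
    stop("'values' must be a non-empty numeric vector")
  }
  ref_vals <- values[reference]
  if (length(ref_vals) == 0L) stop("empty reference group")
  if (anyNA(ref_vals) || any(ref_vals <= 0)) {
    stop("reference values must be positive and non-missing")
  }
  if (any(values < 0, na.rm = TRUE)) stop("negative expression value")
  undetected <- !is.na(values) & values == 0
  if (any(undetected)) {
    warning(sum(undetected), " undetected (zero) value(s); fold set to 0")
  }
  out <- values / geometric_mean(ref_vals)
  attr(out, "undetected") <- undetected
  out
}

#' Lysosomal uptake from the association/binding arithmetic
#'
#' In the isolated-lysosome GAPDH assay, "association" (substrate bound plus
#' taken up, protease inhibitors present) minus "binding" (substrate bound at
#' the membrane only) estimates the amount of substrate translocated into the
#' lysosomal lumen. Both are densitometric quantities in the same arbitrary
#' units.
#'
#' @param association,binding Nonnegative densitometric values (vectorised).
#' @return `association - binding`; negative results (binding exceeding
#'   association, a noise-dominated case) are returned but flagged with a
#'   warning and the `"negative"` attribute.
#' @export
uptake_from_association_binding <- function(association, binding) {
  if (any(association < 0, na.rm = TRUE) || any(binding < 0, na.rm = TRUE)) {
    stop("association and binding must be nonnegative")
  }
  uptake <- association - binding
  neg <- !is.na(uptake) & uptake < 0
  if (any(neg)) {
    warning(sum(neg), " negative uptake value(s): binding exceeded ",
            "association (noise-dominated measurement)")
  }
  attr(uptake, "negative") <- neg
  uptake
}
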