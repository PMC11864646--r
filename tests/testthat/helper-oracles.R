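# Independent oracles, written against the rule definitions rather than the
# package internals, used to cross-check the implementations.

# --- Motif rule oracle -----------------------------------------------------
# Brute-force evaluator of the KFERQ-like rule table. Works by explicit
# enumeration of the permitted body multisets (as sorted label strings)
# rather than the package's count-threshold logic.
.oracle_label <- c(F = "h", I = "h", L = "h", V = "h",
                   K = "p", R = "p",
                   D = "n", E = "n",
                   S = "s", T = "s", Y = "s")
.oracle_body_canonical <- c("hhnp", "hnpp") # 2H+1P+1N or 1H+2P+1N
.oracle_body_phospho <- c("hhps", "hpps")   # S/T/Y replaces the negative

motif_oracle <- function(chars) {
  classes <- character(0)
  for (anchor_pos in c(1L, 5L)) {
    anchor <- chars[anchor_pos]
    body_labels <- .oracle_label[chars[-anchor_pos]]
    if (anyNA(body_labels)) next # residue outside every class (incl. Q, X)
    key <- paste(sort(body_labels), collapse = "")
    if (anchor == "Q") {
      if (key %in% .oracle_body_canonical) classes <- c(classes, "CANONICAL")
      if (key %in% .oracle_body_phospho) {
        classes <- c(classes, "PHOSPHO_GENERATED")
      }
    }
    if (anchor == "K" && key %in% .oracle_body_canonical) {
      classes <- c(classes, "ACETYL_GENERATED")
    }
  }
  sort(unique(classes))
}

motif_oracle_str <- function(pent) {
  motif_oracle(strsplit(pent, "", fixed = TRUE)[[1L]])
}

# --- Exact-test oracle -----------------------------------------------------
# Two-sided Fisher p by exhaustive enumeration over all tables sharing the
# observed margins, with probabilities from binomial coefficients.
fisher_enum_oracle <- function(a, b, c_, d) {
  n1 <- a + c_; n2 <- b + d; k <- a + b; n <- n1 + n2
  support <- max(0, k - n2):min(k, n1)
  probs <- choose(n1, support) * choose(n2, k - support) / choose(n, k)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# --- Generic least-squares oracle ------------------------------------------
# Fits log2 run abundances from a ratio matrix with lm() over all defined
# pairs (run 1 as intercept reference), then applies the rescaling contract.
lsq_fit_oracle <- function(M, ion_total) {
  k <- nrow(M)
  pairs <- which(upper.tri(M) & !is.na(M), arr.ind = TRUE)
  y <- log2(M[pairs])
  X <- matrix(0, nrow(pairs), k)
  X[cbind(seq_len(nrow(pairs)), pairs[, 1])] <- 1
  X[cbind(seq_len(nrow(pairs)), pairs[, 2])] <- -1
  fit <- stats::lm.fit(X[, -1, drop = FALSE], y)
  x <- c(0, ifelse(is.na(fit$coefficients), 0, fit$coefficients))
  ab <- 2^x
  stats::setNames(ab * ion_total / sum(ab), rownames(M))
}

# --- Small fixture builders ------------------------------------------------
make_ion_matrix <- function(values, runs = NULL) {
  m <- do.call(rbind, values)
  colnames(m) <- runs %||% paste0("r", seq_len(ncol(m)))
  rownames(m) <- paste0("ion", seq_len(nrow(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
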