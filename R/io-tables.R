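# Tab-separated table IO. Dialect (fixed): UTF-8, header row required, "."
# decimal separator, empty cell = missing. Missing cells are preserved as NA,
# never silently zero: downstream stages decide policy.

.read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", check.names = FALSE, fill = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a samples-by-genes expression table
#'
#' The file is tab-separated with a header row; the first column holds sample
#' ids and the remaining columns hold one gene each. Empty cells are missing
#' values and stay missing (`NA`) — they are flagged, not imputed.
#'
#' @param path Path to the table.
#' @return A numeric matrix (samples in rows, genes in columns) with sample
#'   ids as row names and gene ids as column names.
#' @export
read_expression_table <- function(path) {
  df <- .read_tsv_strict(path)
  if (ncol(df) < 2L) stop("expression table needs a sample column and at ",
                          "least one gene column")
  samples <- df[[1L]]
  if (anyDuplicated(samples)) stop("duplicate sample id: ",
                                   samples[duplicated(samples)][1L])
  genes <- colnames(df)[-1L]
  if (anyDuplicated(genes)) stop("duplicate gene column: ",
                                 genes[duplicated(genes)][1L])
  mat <- matrix(NA_real_, nrow = nrow(df), ncol = length(genes),
                dimnames = list(samples, genes))
  for (j in seq_along(genes)) {
    raw <- df[[j + 1L]]
    empty <- is.na(raw) | raw == ""
    val <- suppressWarnings(as.numeric(raw))
    bad <- !empty & is.na(val)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop("non-numeric cell '", raw[i], "' at row ", i + 1L, " (sample '",
           samples[i], "'), column '", genes[j], "'")
    }
    mat[, j] <- val
  }
  cma_log("read_expression_table: %d samples x %d genes, %d missing cells",
          nrow(mat), ncol(mat), sum(is.na(mat)))
  mat
}

#' Write an expression matrix as a tab-separated table
#'
#' @param mat Numeric matrix, samples in rows, genes in columns.
#' @param path Output path. Missing values are written as empty cells.
#' @export
write_expression_table <- function(mat, path) {
  df <- data.frame(sample_id = rownames(mat), as.data.frame(mat),
                   check.names = FALSE)
  .write_tsv(df, path)
}

#' Read a CMA network definition
#'
#' Tab-separated with header; required columns `gene_id`, `group`,
#' `direction`, `paralog_family`; optional `weight` (empty = derive the
#' weight with [assign_weights()]). `direction` must be `+1`/`1` (positive
#' impact on CMA) or `-1` (negative impact).
#'
#' @param path Path to the network file.
#' @return An unweighted network: a data frame of class `"cma_network"` with
#'   columns `gene_id`, `functional_group`, `direction` (integer +1/-1),
#'   `paralog_family`, `n_paralogs`, `weight` (`NA` unless explicit).
#' @export
read_network_config <- function(path) {
  df <- .read_tsv_strict(path)
  need <- c("gene_id", "group", "direction", "paralog_family")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0L) stop("network file lacks column(s): ",
                              paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("empty network")
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene id: ", df$gene_id[duplicated(df$gene_id)][1L])
  }
  dir_tok <- trimws(df$direction)
  direction <- ifelse(dir_tok %in% c("+1", "1"), 1L,
                      ifelse(dir_tok == "-1", -1L, NA_integer_))
  if (anyNA(direction)) {
    i <- which(is.na(direction))[1L]
    stop("unknown direction token '", dir_tok[i], "' for gene '",
         df$gene_id[i], "' (must be +1 or -1)")
  }
  if (any(is.na(df$paralog_family) | trimws(df$paralog_family) == "")) {
    stop("paralog_family must be non-empty for every gene")
  }
  weight <- rep(NA_real_, nrow(df))
  if ("weight" %in% colnames(df)) {
    raw <- df$weight
    has <- !(is.na(raw) | raw == "")
    weight[has] <- suppressWarnings(as.numeric(raw[has]))
    if (anyNA(weight[has])) stop("non-numeric explicit weight")
    if (any(weight[has] <= 0)) stop("explicit weights must be positive")
  }
  fam <- df$paralog_family
  net <- data.frame(gene_id = df$gene_id, functional_group = df$group,
                    direction = direction, paralog_family = fam,
                    n_paralogs = as.integer(table(fam)[fam]),
                    weight = weight, stringsAsFactors = FALSE)
  class(net) <- c("cma_network", "data.frame")
  cma_log("read_network_config: %d genes, %d families", nrow(net),
          length(unique(fam)))
  net
}

#' Read a long-format ion abundance table
#'
#' Tab-separated with header columns `protein_id`, `ion_id`, `run_id`,
#' `abundance`. Empty abundance cells are missing. Each ion must belong to
#' exactly one protein; abundances must be nonnegative (zeros are treated as
#' missing by the log-space quantification steps).
#'
#' @param path Path to the table.
#' @return A data frame with the four columns, abundance numeric.
#' @export
read_ion_table <- function(path) {
  df <- .read_tsv_strict(path)
  need <- c("protein_id", "ion_id", "run_id", "abundance")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0L) stop("ion table lacks column(s): ",
                              paste(miss, collapse = ", "))
  raw <- df$abundance
  empty <- is.na(raw) | raw == ""
  ab <- suppressWarnings(as.numeric(raw))
  bad <- !empty & is.na(ab)
  if (any(bad)) stop("non-numeric abundance at row ",
                     which(bad)[1L] + 1L)
  if (any(ab < 0, na.rm = TRUE)) stop("negative abundance at row ",
                                      which(ab < 0)[1L] + 1L)
  out <- data.frame(protein_id = df$protein_id, ion_id = df$ion_id,
                    run_id = df$run_id, abundance = ab,
                    stringsAsFactors = FALSE)
  owner <- unique(out[, c("protein_id", "ion_id")])
  if (anyDuplicated(owner$ion_id)) {
    stop("ion '", owner$ion_id[duplicated(owner$ion_id)][1L],
         "' is assigned to more than one protein")
  }
  cma_log("read_ion_table: %d proteins, %d ions, %d runs",
          length(unique(out$protein_id)), length(unique(out$ion_id)),
          length(unique(out$run_id)))
  out
}
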