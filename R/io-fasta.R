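# Protein FASTA reading/writing. Parsing is delegated to Biostrings; the
# validation layer enforces the package's contracts: unique ids, non-empty
# sequences, and a 20-letter alphabet (plus X only when allowed).

#' Read a protein FASTA file
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @param allow_x Logical; accept `X` (unknown residue) in sequences. Motif
#'   rules are undefined for ambiguity codes, so any other non-standard
#'   letter is always rejected, and `X` only when `allow_x = TRUE` (the
#'   default; windows containing X are never motifs).
#'
#' @return A data frame with columns `id` (first whitespace-delimited token of
#'   the header), `description` (remainder of the header, possibly empty) and
#'   `sequence` (uppercased), one row per record, in file order.
#'
#' @details Headers must be unique by id; empty sequences and records with
#'   invalid characters are format errors reporting the offending record and
#'   header line.
#' @export
read_fasta <- function(path, allow_x = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  aas <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(aas) == 0L) {
    return(data.frame(id = character(0), description = character(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  headers <- names(aas)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  # header line numbers, for error messages
  header_lines <- grep("^>", readLines(path))

  if (anyDuplicated(ids)) {
    i <- which(duplicated(ids))[1L]
    stop("duplicate FASTA id '", ids[i], "' (line ", header_lines[i], ")")
  }
  seqs <- toupper(as.character(aas))
  widths <- nchar(seqs)
  if (any(widths == 0L)) {
    i <- which(widths == 0L)[1L]
    stop("empty sequence for '", ids[i], "' (line ", header_lines[i], ")")
  }
  alphabet <- if (allow_x) c(AA_STANDARD, "X") else AA_STANDARD
  ok <- grepl(paste0("^[", paste(alphabet, collapse = ""), "]+$"), seqs)
  if (!all(ok)) {
    i <- which(!ok)[1L]
    bad <- setdiff(strsplit(seqs[i], "")[[1L]], alphabet)
    stop("invalid character(s) ", paste(unique(bad), collapse = ", "),
         " in sequence '", ids[i], "' (line ", header_lines[i], ")")
  }
  cma_log("read_fasta: %d records from %s", length(ids), path)
  data.frame(id = ids, description = desc, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' Sequences are wrapped at 60 characters per line (fixed policy);
#' `write_fasta(read_fasta(f))` therefore reproduces ids, descriptions and
#' sequences exactly, and bytes exactly when `f` itself is 60-wrapped.
#'
#' @param records Data frame with columns `id`, `sequence` and optionally
#'   `description`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records),
            all(c("id", "sequence") %in% names(records)))
  if (anyDuplicated(records$id)) stop("duplicate record ids")
  headers <- records$id
  desc <- records$description %||% rep("", nrow(records))
  headers <- ifelse(is.na(desc) | desc == "", headers,
                    paste(headers, desc))
  x <- Biostrings::BStringSet(records$sequence)
  names(x) <- headers
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}
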