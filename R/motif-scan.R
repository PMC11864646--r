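# KFERQ-like motif detection and classification.
#
# A KFERQ-like motif is a pentapeptide read through an anchor residue at the
# first or fifth window position plus a composition constraint on the four
# remaining ("body") residues:
#
#   hydrophobic        H = {F, I, L, V}
#   positive           P = {K, R}
#   negative           N = {D, E}
#   phospho-acquirable S = {S, T, Y}
#
#   CANONICAL         anchor Q; body = 1-2 H, 1-2 P, exactly 1 N, nothing else
#   PHOSPHO_GENERATED anchor Q; body = 1-2 H, 1-2 P, exactly 1 S, no D/E,
#                     nothing else (the S/T/Y supplies the negative charge
#                     once phosphorylated)
#   ACETYL_GENERATED  anchor K standing in for Q (acetyl-lysine mimics the
#                     glutamine amide); body = the CANONICAL composition; the
#                     anchor K does not count toward the body's positive quota
#
# Both anchor readings (positions 1 and 5) are evaluated and every satisfied
# class is reported. A Q in a body position invalidates that reading, and any
# residue outside the 20-letter alphabet (including X) invalidates the whole
# window.

MOTIF_CLASSES <- c("CANONICAL", "PHOSPHO_GENERATED", "ACETYL_GENERATED")

.AA_HYDROPHOBIC <- c("F", "I", "L", "V")
.AA_POSITIVE    <- c("K", "R")
.AA_NEGATIVE    <- c("D", "E")
.AA_PHOSPHO     <- c("S", "T", "Y")

# Vectorised rule evaluation over a character matrix of windows (n x 5).
# Returns an n x 3 logical matrix with columns MOTIF_CLASSES.
.classify_window_matrix <- function(w) {
  stopifnot(is.matrix(w), ncol(w) == 5L)
  n <- nrow(w)
  valid <- matrix(w %in% AA_STANDARD, nrow = n)
  window_valid <- rowSums(valid) == 5L

  out <- matrix(FALSE, nrow = n, ncol = 3L,
                dimnames = list(NULL, MOTIF_CLASSES))
  if (n == 0L) return(out)

  for (anchor_pos in c(1L, 5L)) {
    anchor <- w[, anchor_pos]
    body <- w[, setdiff(1:5, anchor_pos), drop = FALSE]
    nh <- rowSums(matrix(body %in% .AA_HYDROPHOBIC, nrow = n))
    np <- rowSums(matrix(body %in% .AA_POSITIVE, nrow = n))
    nn <- rowSums(matrix(body %in% .AA_NEGATIVE, nrow = n))
    ns <- rowSums(matrix(body %in% .AA_PHOSPHO, nrow = n))

    # "nothing else" is enforced by requiring the class counts to exhaust all
    # four body positions; a body Q (or any other residue) breaks the total.
    body_canonical <- nh >= 1L & nh <= 2L & np >= 1L & np <= 2L & nn == 1L &
      (nh + np + nn) == 4L
    body_phospho <- nh >= 1L & nh <= 2L & np >= 1L & np <= 2L & nn == 0L &
      ns == 1L & (nh + np + ns) == 4L

    out[, "CANONICAL"] <- out[, "CANONICAL"] |
      (anchor == "Q" & body_canonical)
    out[, "PHOSPHO_GENERATED"] <- out[, "PHOSPHO_GENERATED"] |
      (anchor == "Q" & body_phospho)
    out[, "ACETYL_GENERATED"] <- out[, "ACETYL_GENERATED"] |
      (anchor == "K" & body_canonical)
  }
  out & window_valid
}

#' Tabulate KFERQ-like motif classes for a vector of pentapeptides
#'
#' Vectorised interface to the motif rule table: evaluates each pentapeptide
#' under both anchor readings (window positions 1 and 5) and reports which of
#' the three motif classes it satisfies.
#'
#' @param pentapeptides Character vector of 5-letter amino-acid strings.
#'
#' @return A logical matrix with one row per pentapeptide and columns
#'   `CANONICAL`, `PHOSPHO_GENERATED`, `ACETYL_GENERATED`.
#'
#' @examples
#' motif_class_table(c("KFERQ", "QKSLV", "KFERK", "MMMMM"))
#' @seealso [classify_pentapeptide()] for a single pentapeptide,
#'   [scan_protein()] to slide over a whole sequence.
#' @export
motif_class_table <- function(pentapeptides) {
  if (!is.character(pentapeptides)) {
    stop("'pentapeptides' must be a character vector")
  }
  if (length(pentapeptides) == 0L) {
    return(matrix(logical(0), nrow = 0, ncol = 3,
                  dimnames = list(NULL, MOTIF_CLASSES)))
  }
  if (anyNA(pentapeptides) || any(nchar(pentapeptides) != 5L)) {
    stop("every pentapeptide must be a non-NA string of length 5")
  }
  w <- matrix(unlist(strsplit(toupper(pentapeptides), "", fixed = TRUE),
                     use.names = FALSE),
              ncol = 5L, byrow = TRUE)
  bad <- !(w %in% c(AA_STANDARD, "X"))
  if (any(bad)) {
    stop("invalid amino-acid character(s): ",
         paste(unique(w[bad]), collapse = ", "))
  }
  m <- .classify_window_matrix(w)
  rownames(m) <- pentapeptides
  m
}

#' Classify one pentapeptide as KFERQ-like
#'
#' @param pentapeptide A single 5-letter amino-acid string.
#'
#' @return Character vector of satisfied motif classes (subset of
#'   `"CANONICAL"`, `"PHOSPHO_GENERATED"`, `"ACETYL_GENERATED"`); length zero
#'   when the window is not a KFERQ-like motif.
#'
#' @examples
#' classify_pentapeptide("KFERQ")  # the namesake canonical motif
#' classify_pentapeptide("QKSLV")  # phosphorylation-generated
#' classify_pentapeptide("QKILV")  # not a motif: three hydrophobics
#' @export
classify_pentapeptide <- function(pentapeptide) {
  if (length(pentapeptide) != 1L) {
    stop("'pentapeptide' must be a single string; see motif_class_table() ",
         "for the vectorised form")
  }
  m <- motif_class_table(pentapeptide)
  MOTIF_CLASSES[m[1L, ]]
}

#' Scan a protein sequence for KFERQ-like motifs
#'
#' Slides a 5-residue window over the sequence and reports every window that
#' satisfies at least one motif class. Overlapping hits are all reported.
#'
#' @param sequence Amino-acid sequence (single string), or a one-row slice of
#'   the data frame returned by [read_fasta()].
#' @param id Protein identifier attached to the hits (defaults to the record
#'   id when `sequence` is a record, otherwise `"protein"`).
#'
#' @return A data frame with columns `protein_id`, `start` (0-based offset),
#'   `pentapeptide`, and `classes` (comma-separated class labels), ordered by
#'   `start`. Zero rows when the sequence has no hit or is shorter than 5.
#'
#' @examples
#' scan_protein("AAKFERQAA", id = "p1")
#' @export
scan_protein <- function(sequence, id = NULL) {
  if (is.data.frame(sequence)) {
    stopifnot(nrow(sequence) == 1L, !is.null(sequence$sequence))
    id <- id %||% sequence$id
    sequence <- sequence$sequence
  }
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    stop("'sequence' must be a single amino-acid string")
  }
  id <- id %||% "protein"
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- !(chars %in% c(AA_STANDARD, "X"))
  if (any(bad)) {
    stop("invalid amino-acid character(s) in sequence '", id, "': ",
         paste(unique(chars[bad]), collapse = ", "))
  }
  len <- length(chars)
  empty <- data.frame(protein_id = character(0), start = integer(0),
                      pentapeptide = character(0), classes = character(0),
                      stringsAsFactors = FALSE)
  if (len < 5L) return(empty)
  n <- len - 4L
  w <- cbind(chars[1:n], chars[2:(n + 1L)], chars[3:(n + 2L)],
             chars[4:(n + 3L)], chars[5:(n + 4L)])
  m <- .classify_window_matrix(w)
  hit <- rowSums(m) > 0L
  if (!any(hit)) return(empty)
  idx <- which(hit)
  data.frame(
    protein_id = id,
    start = idx - 1L,
    pentapeptide = substring(sequence, idx, idx + 4L),
    classes = vapply(idx, function(i) {
      paste(MOTIF_CLASSES[m[i, ]], collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Scan a set of protein records for KFERQ-like motifs
#'
#' @param records Data frame of protein records as returned by [read_fasta()]
#'   (columns `id`, `sequence`).
#'
#' @return A single hit table (see [scan_protein()]) over all records, ordered
#'   by record then start.
#' @export
scan_proteins <- function(records) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in%
                                          names(records)))
  hits <- lapply(seq_len(nrow(records)), function(i) {
    scan_protein(records$sequence[i], id = records$id[i])
  })
  out <- do.call(rbind, c(hits, list(make.row.names = FALSE)))
  cma_log("scan: %d proteins, %d motif hits", nrow(records), nrow(out))
  out
}

#' Summarise motif hits per protein and per protein set
#'
#' Computes, per protein, the number of hits of each motif class and whether
#' the protein carries at least one hit of the class; and, per named protein
#' set, the proportion of proteins in the set with at least one hit of each
#' class (a protein with several hits of one class counts once).
#'
#' @param records Protein records ([read_fasta()]).
#' @param hits Hit table from [scan_proteins()].
#' @param protein_sets Named list of character vectors of protein ids; each
#'   must be a non-empty subset of `records$id`.
#'
#' @return An object of class `"motif_report"`: a list with `per_protein`
#'   (data frame: `protein_id`, `n_<class>`, `has_<class>`) and `per_set`
#'   (data frame: `set`, `class`, `n_with_motif`, `n_total`, `proportion`).
#' @export
summarize_motifs <- function(records, hits,
                             protein_sets = list(all = records$id)) {
  stopifnot(is.data.frame(records), is.data.frame(hits))
  if (!all(hits$protein_id %in% records$id)) {
    stop("hit table refers to protein ids absent from 'records'")
  }
  if (is.null(names(protein_sets)) || any(names(protein_sets) == "")) {
    stop("'protein_sets' must be a named list")
  }

  per_protein <- data.frame(protein_id = records$id,
                            stringsAsFactors = FALSE)
  hit_classes <- strsplit(hits$classes, ",", fixed = TRUE)
  for (cl in MOTIF_CLASSES) {
    carries <- vapply(hit_classes, function(x) cl %in% x, logical(1))
    counts <- table(factor(hits$protein_id[carries], levels = records$id))
    per_protein[[paste0("n_", tolower(cl))]] <- as.integer(counts)
    per_protein[[paste0("has_", tolower(cl))]] <- as.integer(counts) > 0L
  }

  rows <- list()
  for (set_name in names(protein_sets)) {
    ids <- protein_sets[[set_name]]
    if (length(ids) == 0L) stop("empty set: '", set_name, "'")
    unknown <- setdiff(ids, records$id)
    if (length(unknown) > 0L) {
      stop("set '", set_name, "' contains unknown protein id(s): ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
    sel <- per_protein$protein_id %in% ids
    for (cl in MOTIF_CLASSES) {
      n_with <- sum(per_protein[sel, paste0("has_", tolower(cl))])
      rows[[length(rows) + 1L]] <- data.frame(
        set = set_name, class = cl, n_with_motif = n_with,
        n_total = length(ids), proportion = n_with / length(ids),
        stringsAsFactors = FALSE)
    }
  }
  per_set <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(list(per_protein = per_protein, per_set = per_set),
            class = "motif_report")
}

#' @export
print.motif_report <- function(x, ...) {
  cat("KFERQ-like motif report:", nrow(x$per_protein), "proteins\n")
  print(x$per_set, row.names = FALSE)
  invisible(x)
}
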