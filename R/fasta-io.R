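# FASTA input and tab-separated score output.

#' Read a FASTA file of nucleotide sequences
#'
#' Reads plain or line-wrapped FASTA into a `DNAStringSet` in file order.
#' Lowercase bases are uppercased. Records with empty sequences are dropped
#' with a warning. Element names hold the full header line (without the
#' leading `>`); use [seq_ids()] for the whitespace-delimited id token.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet`, names = full headers.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  # cheap format check: first non-blank line must be a header
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) break  # empty file; let the parser report
    if (nzchar(trimws(line))) {
      if (!startsWith(trimws(line), ">"))
        stop("not a FASTA file (first non-blank line is not a '>' header): ",
             path)
      break
    }
  }
  x <- readDNAStringSet(path, format = "fasta")
  empty <- width(x) == 0L
  if (any(empty)) {
    warning("skipping ", sum(empty), " empty record(s): ",
            paste(utils::head(names(x)[empty], 5L), collapse = ", "))
    x <- x[!empty]
  }
  x
}

#' Sequence ids of a FASTA set
#'
#' First whitespace-delimited token of each header.
#'
#' @param x A `DNAStringSet` as returned by [read_fasta()].
#' @return Character vector of ids.
#' @export
seq_ids <- function(x) {
  ids <- sub("\\s.*$", "", names(x))
  ids
}

#' Write a FASTA file
#'
#' @param x A `DNAStringSet`.
#' @param path Output path.
#' @export
write_fasta <- function(x, path) {
  writeXStringSet(x, filepath = path, format = "fasta")
  invisible(path)
}

#' Write per-sequence classification scores
#'
#' One line per sequence, in input order: `<id>\t<probability>` with the
#' probability printed to 4 decimal places (fixed precision keeps output
#' files diffable).
#'
#' @param results Data frame with columns `id` and `probability`
#'   (as returned by [classify()]).
#' @param path Output path.
#' @param header Write a `id<TAB>probability` header line? Default `FALSE`.
#' @export
write_results <- function(results, path, header = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (header) writeLines("id\tprobability", con)
  if (nrow(results) > 0L)
    writeLines(sprintf("%s\t%.4f", results$id, results$probability), con)
  invisible(path)
}
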