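#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file into a tibble of sequence records. The header token up
#' to the first whitespace becomes the record id; sequence lines are
#' concatenated and uppercased. Records containing characters outside the
#' 20-letter amino-acid alphabet (plus `X` for unknown residues) are skipped
#' with a warning reporting how many were dropped.
#'
#' @param path Path to a FASTA text file.
#' @return A tibble with columns `id` (character) and `seq` (character,
#'   uppercase amino acids). The number of records skipped for illegal
#'   residues is attached as attribute `n_skipped`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACDE", ">b", "WY"), tf)
#' read_fasta(tf)
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) {
    abort(paste0("FASTA file contains no records: ", path))
  }
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0(
      "duplicate sequence id(s) in FASTA: ",
      paste(head(dup, 5), collapse = ", ")
    ))
  }
  seqs <- toupper(as.character(raw))
  ok <- !grepl(paste0("[^", paste(c(AA_LETTERS, "X"), collapse = ""), "]"), seqs) &
    nchar(seqs) >= 1
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    warn(paste0(
      n_skipped, " record(s) skipped for residues outside the amino-acid ",
      "alphabet: ", paste(head(ids[!ok], 5), collapse = ", ")
    ))
  }
  out <- tibble(id = unname(ids[ok]), seq = unname(seqs[ok]))
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write protein sequences to a FASTA file
#'
#' @param records A data frame with columns `id` and `seq`.
#' @param path Output file path.
#' @param width Line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  records <- validate_records(records, allow_empty = TRUE)
  set <- Biostrings::BStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# shared record-table validation: non-empty ids without whitespace, uppercase
# sequences over the amino-acid alphabet (+X)
validate_records <- function(records, allow_empty = FALSE) {
  if (!is.data.frame(records) || !all(c("id", "seq") %in% names(records))) {
    abort("`records` must be a data frame with columns `id` and `seq`")
  }
  records <- as_tibble(records)[, c("id", "seq")]
  if (nrow(records) == 0) {
    if (allow_empty) return(records)
    abort("`records` must contain at least one sequence")
  }
  if (any(is.na(records$id)) || any(records$id == "") ||
      any(grepl("\\s", records$id))) {
    abort("sequence ids must be non-empty and contain no whitespace")
  }
  if (anyDuplicated(records$id)) {
    abort("sequence ids must be unique")
  }
  bad <- grepl(paste0("[^", paste(c(AA_LETTERS, "X"), collapse = ""), "]"),
               records$seq) | nchar(records$seq) < 1
  if (any(bad)) {
    abort(paste0(
      "sequence(s) with illegal residues or zero length: ",
      paste(head(records$id[bad], 5), collapse = ", ")
    ))
  }
  records
}
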