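#' Read protein sequences from a FASTA file
#'
#' Reads a (possibly line-wrapped, multi-record) FASTA file of amino-acid
#' sequences into a tibble. Sequence letters are upper-cased; the record id
#' is the first whitespace-delimited token of the header line. No alphabet
#' validation happens here — use [filter_valid()] to drop sequences with
#' symbols outside the 20-letter alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (character), `sequence` (character,
#'   uppercase) and `length` (integer), one row per FASTA entry in file
#'   order.
#' @examples
#' fa <- system.file("extdata", "zig1_caeel.fasta", package = "trisense")
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: %s", path), class = "trisense_io_error")
  }
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) {
    return(tibble(id = character(), sequence = character(), length = integer()))
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  if (any(Biostrings::width(set) == 0L)) {
    bad <- ids[Biostrings::width(set) == 0L]
    abort(
      sprintf("FASTA entry with empty sequence: %s", paste(bad, collapse = ", ")),
      class = "trisense_format_error"
    )
  }
  seqs <- unname(toupper(as.character(set)))
  tibble(id = ids, sequence = seqs, length = nchar(seqs))
}

#' Write protein sequences to a FASTA file
#'
#' @param records A data frame with columns `id` and `sequence`.
#' @param path Output file path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  check_records(records)
  set <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Keep only sequences over the 20-letter amino-acid alphabet
#'
#' Applies the rejection rule used when assembling clean sequence sets:
#' any sequence containing a character outside [aa_alphabet] (ambiguity
#' codes such as `X` or `B`, non-standard residues, stops, gaps) is dropped
#' whole. Input order of the kept records is preserved and filtering is
#' idempotent.
#'
#' @param records A tibble as returned by [read_fasta()] (columns `id`,
#'   `sequence`; `length` is recomputed if absent).
#' @return The kept records, with a `filter_report` attribute (retrievable
#'   via [filter_report()]) listing input/kept/rejected tallies and the
#'   offending symbols per rejected id.
#' @examples
#' recs <- tibble::tibble(id = c("a", "b"), sequence = c("MKV", "MKX"))
#' kept <- filter_valid(recs)
#' filter_report(kept)
#' @export
filter_valid <- function(records) {
  check_records(records)
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", records$sequence)
  rejected <- records[!ok, , drop = FALSE]
  bad_symbols <- vapply(rejected$sequence, function(s) {
    chars <- unique(strsplit(s, "", fixed = TRUE)[[1]])
    paste(sort(setdiff(chars, aa_alphabet)), collapse = ",")
  }, character(1))
  report <- list(
    n_input = nrow(records),
    n_kept = sum(ok),
    n_rejected = sum(!ok),
    rejected = tibble(id = rejected$id, invalid_symbols = unname(bad_symbols))
  )
  kept <- records[ok, , drop = FALSE]
  if (!"length" %in% names(kept)) kept$length <- nchar(kept$sequence)
  attr(kept, "filter_report") <- report
  kept
}

#' Retrieve the report attached by [filter_valid()]
#'
#' @param records A tibble returned by [filter_valid()].
#' @return A list with elements `n_input`, `n_kept`, `n_rejected` and
#'   `rejected` (a tibble of rejected ids and their offending symbols), or
#'   `NULL` if `records` was not produced by [filter_valid()].
#' @export
filter_report <- function(records) {
  attr(records, "filter_report", exact = TRUE)
}

#' Read / write a two-column sequence label table
#'
#' Labels are stored as tab-separated text with a header line
#' `id<TAB>label`.
#'
#' @param path Path to the TSV file.
#' @return For `read_labels()`, a tibble with columns `id` and `label`.
#' @export
read_labels <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("id", "label") %in% names(tbl))) {
    abort("Label file must have columns 'id' and 'label'.", class = "trisense_format_error")
  }
  tbl[c("id", "label")]
}

#' @rdname read_labels
#' @param records A data frame with columns `id` and `label`.
#' @export
write_labels <- function(records, path) {
  if (!all(c("id", "label") %in% names(records))) {
    abort("`records` must have columns 'id' and 'label'.")
  }
  readr::write_tsv(records[c("id", "label")], path)
  invisible(path)
}

check_records <- function(records) {
  if (!is.data.frame(records) || !all(c("id", "sequence") %in% names(records))) {
    abort("`records` must be a data frame with columns 'id' and 'sequence'.")
  }
  invisible(records)
}
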