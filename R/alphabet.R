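#' The 20-letter amino-acid alphabet
#'
#' The canonical single-letter codes of the 20 proteinogenic amino acids in
#' alphabetical order. All indexing in the package (residue indices,
#' tripeptide tensor axes, signal flattening) refers to positions in this
#' vector. Ambiguity and non-standard codes (`B`, `J`, `O`, `U`, `X`, `Z`),
#' stop (`*`) and gap characters are deliberately excluded: sequences
#' containing them are rejected by [filter_valid()].
#'
#' @format A character vector of length 20.
#' @seealso [residue_index()], [filter_valid()]
#' @export
aa_alphabet <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' Zero-based index of a residue in the amino-acid alphabet
#'
#' Maps single-letter residue codes to their 0-based position in
#' [aa_alphabet] (`A` is 0, `C` is 1, ..., `Y` is 19). This is the index
#' convention used when flattening the tripeptide tensor to the length-8000
#' signal.
#'
#' @param symbol Character vector of single-letter residue codes.
#' @return Integer vector of the same length, values in `0:19`.
#' @examples
#' residue_index(c("A", "C", "Y"))
#' @export
residue_index <- function(symbol) {
  if (!is.character(symbol)) {
    abort("`symbol` must be a character vector of single letters.")
  }
  if (any(nchar(symbol) != 1L)) {
    abort("`symbol` must contain single characters only.")
  }
  idx <- match(symbol, aa_alphabet)
  if (anyNA(idx)) {
    bad <- unique(symbol[is.na(idx)])
    abort(
      sprintf(
        "Symbol(s) not in the 20-letter amino-acid alphabet: %s",
        paste(bad, collapse = ", ")
      ),
      class = "trisense_invalid_symbol"
    )
  }
  idx - 1L
}

# 1-based residue indices of a sequence string; aborts on invalid symbols.
seq_to_indices <- function(sequence, id = NULL) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  idx <- match(chars, aa_alphabet)
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    who <- if (is.null(id)) "sequence" else sprintf("sequence '%s'", id)
    abort(
      sprintf(
        "%s contains symbol(s) outside the amino-acid alphabet: %s",
        who, paste(bad, collapse = ", ")
      ),
      class = "trisense_invalid_symbol"
    )
  }
  idx
}
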