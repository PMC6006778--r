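#' Count overlapping tripeptides into a 20 x 20 x 20 transfer-frequency tensor
#'
#' Slides a window of three residues (stride 1) along the sequence and
#' counts each tripeptide `XYZ` into cell `[i, j, k]` of a 20 x 20 x 20
#' array, where `i`, `j`, `k` are the alphabet positions of `X`, `Y`, `Z`.
#' A sequence of length `L` contributes exactly `L - 2` counts, so the
#' tensor is very sparse relative to its 8000 cells — the property the
#' random-projection step exploits.
#'
#' @param sequence A single amino-acid sequence string over [aa_alphabet].
#' @param id Optional identifier used in error messages.
#' @return A `tripeptide_tensor`: a 20 x 20 x 20 integer array with residue
#'   dimnames and a `source_length` attribute.
#' @examples
#' m <- count_tripeptides("ACDACD")
#' sum(m) # L - 2 = 4
#' @export
count_tripeptides <- function(sequence, id = NULL) {
  if (!is.character(sequence) || length(sequence) != 1L) {
    abort("`sequence` must be a single character string.")
  }
  idx <- seq_to_indices(sequence, id = id)
  L <- length(idx)
  if (L < 3L) {
    abort(
      sprintf("Sequence%s of length %d is too short to encode (need L >= 3).",
              if (is.null(id)) "" else sprintf(" '%s'", id), L),
      class = "trisense_too_short"
    )
  }
  signal <- tripeptide_signal_from_indices(idx)
  unflatten_signal(signal, source_length = L)
}

# length-8000 integer count vector from 1-based residue indices
tripeptide_signal_from_indices <- function(idx) {
  L <- length(idx)
  i <- idx[seq_len(L - 2L)] - 1L
  j <- idx[seq(2L, L - 1L)] - 1L
  k <- idx[seq(3L, L)] - 1L
  tabulate(400L * i + 20L * j + k + 1L, nbins = 8000L)
}

#' Flatten a tripeptide tensor to the length-8000 sparse signal
#'
#' Linearizes the tensor in row-major order — first residue slowest, third
#' fastest — so that cell `(i, j, k)` (0-based alphabet indices) lands at
#' 0-based position `400 i + 20 j + k`. Total count and sparsity are
#' preserved; [unflatten_signal()] inverts the operation exactly.
#'
#' @param tensor A `tripeptide_tensor` (or any 20 x 20 x 20 array).
#' @return An integer vector of length 8000 carrying over the
#'   `source_length` attribute.
#' @export
flatten_signal <- function(tensor) {
  check_tensor(tensor)
  v <- as.vector(aperm(unclass(tensor), c(3L, 2L, 1L)))
  attr(v, "source_length") <- attr(tensor, "source_length", exact = TRUE)
  v
}

#' @rdname flatten_signal
#' @param signal A numeric vector of length 8000.
#' @param source_length Optional sequence length to record on the result.
#' @export
unflatten_signal <- function(signal, source_length = NULL) {
  if (length(signal) != 8000L) {
    abort("`signal` must have length 8000.", class = "trisense_dimension_error")
  }
  a <- aperm(array(as.vector(signal), dim = c(20L, 20L, 20L)), c(3L, 2L, 1L))
  dimnames(a) <- list(aa_alphabet, aa_alphabet, aa_alphabet)
  attr(a, "source_length") <- source_length %||% attr(signal, "source_length", exact = TRUE)
  class(a) <- c("tripeptide_tensor", class(a))
  a
}

#' Normalize a tripeptide frequency tensor to probabilities
#'
#' Divides every cell by the tensor total (`L - 2`), turning transfer
#' frequencies into an empirical tripeptide probability distribution. The
#' raw integer tensor — not this normalization — is what feeds the
#' compressive projection; the probability form is provided for inspection
#' and model comparison.
#'
#' @param tensor A `tripeptide_tensor` with positive total count.
#' @return A 20 x 20 x 20 numeric array summing to 1.
#' @export
to_probability <- function(tensor) {
  check_tensor(tensor)
  total <- sum(tensor)
  if (total <= 0) {
    abort("Cannot normalize a tensor with zero total count.",
          class = "trisense_degenerate_normalization")
  }
  unclass(tensor) / total
}

#' Amino-acid composition of a sequence
#'
#' The classical length-20 baseline feature: the relative frequency of each
#' residue, in alphabet order.
#'
#' @param sequence A single amino-acid sequence string (length >= 1).
#' @param id Optional identifier used in error messages.
#' @return A named numeric vector of length 20 summing to 1.
#' @examples
#' aac_vector("AAAA")
#' @export
aac_vector <- function(sequence, id = NULL) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L) {
    abort("`sequence` must be a single non-empty string.")
  }
  idx <- seq_to_indices(sequence, id = id)
  setNames(tabulate(idx, nbins = 20L) / length(idx), aa_alphabet)
}

check_tensor <- function(tensor) {
  if (!is.array(tensor) || !identical(dim(tensor), c(20L, 20L, 20L))) {
    abort("`tensor` must be a 20 x 20 x 20 array.", class = "trisense_dimension_error")
  }
  invisible(tensor)
}

#' @export
print.tripeptide_tensor <- function(x, ...) {
  L <- attr(x, "source_length", exact = TRUE)
  cat("<tripeptide_tensor> 20 x 20 x 20",
      if (!is.null(L)) sprintf("(source length %d)", L), "\n")
  cat("  total count:", sum(x), "  non-zero cells:", sum(x != 0), "\n")
  invisible(x)
}
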