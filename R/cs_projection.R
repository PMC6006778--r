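#' Seeded Gaussian measurement matrix
#'
#' Draws an `m` x 8000 matrix of i.i.d. zero-mean Gaussian entries with
#' standard deviation `scale` (default `1/sqrt(m)`, which keeps projected
#' Euclidean norms comparable to the original signal norms in expectation).
#' The matrix is the random-projection operator of the compressive feature
#' extractor: one matrix is drawn per experiment so features of different
#' sequences live in a common space. Generation is fully deterministic
#' given `(m, seed, scale)` and uses the Mersenne-Twister generator with
#' inversion sampling, recorded on the object, so matrices reproduce
#' bit-identically across machines.
#'
#' @param m Target feature dimension, `1 <= m < 8000`.
#' @param seed Integer seed.
#' @param scale Standard deviation of the entries.
#' @return An `m` x 8000 matrix of class `measurement_matrix` with
#'   attributes `m`, `seed`, `scale` and `prng`.
#' @examples
#' phi <- make_measurement_matrix(5, seed = 1)
#' dim(phi)
#' @export
make_measurement_matrix <- function(m, seed, scale = 1 / sqrt(m)) {
  if (!is.numeric(m) || length(m) != 1L || m != as.integer(m) || m < 1 || m >= 8000) {
    abort("`m` must be a single integer with 1 <= m < 8000.",
          class = "trisense_parameter_error")
  }
  m <- as.integer(m)
  entries <- withr::with_seed(
    seed,
    matrix(rnorm(m * 8000L, mean = 0, sd = scale), nrow = m, ncol = 8000L),
    .rng_kind = "Mersenne-Twister",
    .rng_normal_kind = "Inversion"
  )
  structure(
    entries,
    m = m, seed = seed, scale = scale,
    prng = "Mersenne-Twister/Inversion",
    class = c("measurement_matrix", "matrix", "array")
  )
}

#' @export
print.measurement_matrix <- function(x, ...) {
  cat(sprintf(
    "<measurement_matrix> %d x %d Gaussian (sd = %.4g, seed = %s, %s)\n",
    nrow(x), ncol(x), attr(x, "scale"), format(attr(x, "seed")), attr(x, "prng")
  ))
  invisible(x)
}

#' Project a sparse tripeptide signal to the compressed feature vector
#'
#' Computes `s = phi %*% x`: each compressed coordinate is the inner
#' product of one Gaussian measurement row with the length-8000 tripeptide
#' count signal.
#'
#' @param phi A [make_measurement_matrix()] matrix (or any `m` x 8000
#'   matrix).
#' @param x A numeric vector of length 8000 (see [flatten_signal()]).
#' @return A numeric vector of length `m`.
#' @export
project_signal <- function(phi, x) {
  if (!is.matrix(phi) || ncol(phi) != 8000L) {
    abort("`phi` must be an m x 8000 matrix.", class = "trisense_dimension_error")
  }
  if (length(x) != 8000L) {
    abort("`x` must have length 8000.", class = "trisense_dimension_error")
  }
  as.numeric(unclass(phi) %*% as.vector(x))
}

#' Extract a feature matrix from a set of sequences
#'
#' Batch front end of the feature pipeline. For `method = "cs"` every
#' sequence is encoded as its length-8000 tripeptide count signal and all
#' signals are projected with a single shared Gaussian measurement matrix,
#' giving `m` features per sequence. For `method = "aac"` the length-20
#' amino-acid composition is returned and `m`/`seed`/`phi` are ignored.
#'
#' @param records A tibble with columns `id` and `sequence`; all sequences
#'   must be valid over [aa_alphabet] (and of length >= 3 for `"cs"`) —
#'   run [filter_valid()] first.
#' @param method `"cs"` (compressive tripeptide features) or `"aac"`
#'   (composition baseline).
#' @param m Compressed dimension for `"cs"`.
#' @param seed Seed for the measurement matrix.
#' @param phi Optional pre-built measurement matrix overriding `m`/`seed`.
#' @return A tibble with column `id` followed by numeric feature columns
#'   (`f1..fm` for `"cs"`, residue letters for `"aac"`), with attributes
#'   `method`, `dim`, `seed`, `scale` and `prng` describing the extraction.
#' @examples
#' recs <- tibble::tibble(id = c("s1", "s2"), sequence = c("ACDACD", "MKVWYA"))
#' extract_features(recs, method = "cs", m = 5, seed = 1)
#' @export
extract_features <- function(records, method = c("cs", "aac"), m = 5L, seed = 1L,
                             phi = NULL) {
  check_records(records)
  method <- match.arg(method)
  if (nrow(records) == 0L) {
    abort("`records` is empty.", class = "trisense_empty_dataset")
  }
  if (method == "cs") {
    phi <- phi %||% make_measurement_matrix(m, seed)
    signals <- vapply(seq_len(nrow(records)), function(r) {
      idx <- seq_to_indices(records$sequence[r], id = records$id[r])
      if (length(idx) < 3L) {
        abort(
          sprintf("Sequence '%s' is too short to encode (L = %d < 3).",
                  records$id[r], length(idx)),
          class = "trisense_too_short"
        )
      }
      tripeptide_signal_from_indices(idx)
    }, numeric(8000L))
    feats <- t(signals) %*% t(unclass(phi))
    colnames(feats) <- paste0("f", seq_len(ncol(feats)))
    out <- dplyr::bind_cols(tibble(id = records$id), as_tibble(feats))
    attr(out, "method") <- "cs"
    attr(out, "feature_dim") <- ncol(feats)
    attr(out, "seed") <- attr(phi, "seed", exact = TRUE)
    attr(out, "scale") <- attr(phi, "scale", exact = TRUE)
    attr(out, "prng") <- attr(phi, "prng", exact = TRUE)
  } else {
    feats <- t(vapply(seq_len(nrow(records)), function(r) {
      aac_vector(records$sequence[r], id = records$id[r])
    }, numeric(20L)))
    out <- dplyr::bind_cols(tibble(id = records$id), as_tibble(feats))
    attr(out, "method") <- "aac"
    attr(out, "feature_dim") <- 20L
  }
  out
}

#' Numeric feature matrix of a feature tibble
#'
#' Drops the `id` column (using it for rownames) and returns the numeric
#' feature columns as a plain matrix, the form consumed by [fcm()] and the
#' evaluation indices.
#'
#' @param features A feature tibble (from [extract_features()]) or a
#'   numeric matrix, which is returned as is.
#' @return A numeric matrix with one row per sample.
#' @export
as_feature_matrix <- function(features) {
  if (is.matrix(features)) {
    storage.mode(features) <- "double"
    return(features)
  }
  if (!is.data.frame(features)) {
    abort("`features` must be a data frame or matrix.")
  }
  num <- vapply(features, is.numeric, logical(1))
  x <- as.matrix(features[num])
  if ("id" %in% names(features)) rownames(x) <- features$id
  x
}

#' Restrict a measurement matrix to its leading rows
#'
#' Returns the first `m` rows of a larger measurement matrix, rescaled to
#' the `1/sqrt(m)` entry convention. Because the rows of a Gaussian
#' measurement matrix are i.i.d., the prefix is itself a valid `m`-row
#' Gaussian measurement matrix; using prefixes of one master draw across a
#' sweep of dimensions pairs the randomness, so differences between
#' dimensions reflect the dimension and not draw-to-draw noise (see
#' [dimension_sweep()]).
#'
#' @param phi A [make_measurement_matrix()] matrix with `M` rows.
#' @param m Number of leading rows to keep, `1 <= m <= M`.
#' @return An `m` x 8000 `measurement_matrix`.
#' @export
prefix_measurement_matrix <- function(phi, m) {
  if (!is.matrix(phi) || ncol(phi) != 8000L) {
    abort("`phi` must be an M x 8000 measurement matrix.",
          class = "trisense_dimension_error")
  }
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m > nrow(phi)) {
    abort("`m` must satisfy 1 <= m <= nrow(phi).", class = "trisense_parameter_error")
  }
  m <- as.integer(m)
  old_scale <- attr(phi, "scale", exact = TRUE) %||% (1 / sqrt(nrow(phi)))
  new_scale <- 1 / sqrt(m)
  entries <- unclass(phi)[seq_len(m), , drop = FALSE] * (new_scale / old_scale)
  structure(
    entries,
    m = m, seed = attr(phi, "seed", exact = TRUE), scale = new_scale,
    prng = attr(phi, "prng", exact = TRUE),
    class = c("measurement_matrix", "matrix", "array")
  )
}
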