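#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fuzzy c-means fit
#'
#' @param x An `fcm_fit`.
#' @param ... Unused.
#' @return A tibble with one row per sample: `id` (rownames of the feature
#'   matrix, or row number), the hard `cluster`, and one membership column
#'   `u1..uC` per cluster.
#' @export
tidy.fcm_fit <- function(x, ...) {
  u <- x$membership
  ids <- rownames(u) %||% as.character(seq_len(nrow(u)))
  colnames(u) <- paste0("u", seq_len(ncol(u)))
  dplyr::bind_cols(
    tibble(id = ids, cluster = hard_labels(x)),
    as_tibble(u)
  )
}

#' Glance at a fuzzy c-means fit
#'
#' @param x An `fcm_fit`.
#' @param ... Unused.
#' @return A one-row tibble: sample count, cluster count, fuzzifier,
#'   iterations, convergence flag, final objective and partition entropy.
#' @export
glance.fcm_fit <- function(x, ...) {
  tibble(
    n = nrow(x$membership),
    clusters = ncol(x$membership),
    fuzzifier = x$config$fuzzifier,
    n_iter = x$n_iter,
    converged = x$converged,
    objective = x$objective[length(x$objective)],
    etp = partition_entropy(x)
  )
}
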