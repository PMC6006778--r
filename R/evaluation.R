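#' Within- and between-class scatter traces
#'
#' Computes the trace of the within-class scatter matrix
#' `Sw = sum_k sum_i (x_i^(k) - m_k)(x_i^(k) - m_k)^T`, the trace of the
#' between-class scatter `Sb = sum_k N_k (m_k - m)(m_k - m)^T`, and their
#' ratio. A smaller `tr(Sw)/tr(Sb)` means classes are tighter and farther
#' apart, i.e. the feature set is more discriminative. By convention the
#' traces are computed on the true class labels when comparing feature
#' sets; pass predicted labels for a post-clustering diagnostic.
#'
#' @param features A feature tibble or numeric matrix, one row per sample.
#' @param labels A vector of class labels, one per sample (factor,
#'   character or integer).
#' @return A one-row tibble with columns `tr_sw`, `tr_sb`, `ratio`.
#' @examples
#' x <- rbind(c(0, 0), c(0, 0), c(2, 0), c(2, 0))
#' scatter_traces(x, c("a", "a", "b", "b"))
#' @export
scatter_traces <- function(features, labels) {
  x <- as_feature_matrix(features)
  n <- nrow(x)
  if (length(labels) != n) {
    abort("`labels` must have one entry per row of `features`.",
          class = "trisense_parameter_error")
  }
  if (n < 2L) {
    abort("Need at least 2 samples.", class = "trisense_parameter_error")
  }
  f <- factor(labels)
  grand <- colMeans(x)
  tr_sw <- 0
  tr_sb <- 0
  for (lev in levels(f)) {
    xk <- x[f == lev, , drop = FALSE]
    mk <- colMeans(xk)
    tr_sw <- tr_sw + sum(sweep(xk, 2L, mk)^2)
    tr_sb <- tr_sb + nrow(xk) * sum((mk - grand)^2)
  }
  if (tr_sb == 0) {
    abort(
      sprintf("All class means coincide (tr_sb = 0, tr_sw = %.6g): separation is degenerate.", tr_sw),
      class = "trisense_degenerate_separation"
    )
  }
  tibble(tr_sw = tr_sw, tr_sb = tr_sb, ratio = tr_sw / tr_sb)
}

#' Partition entropy of a fuzzy membership matrix
#'
#' `Etp = -(1/n) sum_i sum_k u_ik log2(u_ik)`, with `0 log2 0 = 0`. The
#' index is 0 for a crisp partition and `log2(C)` for maximally ambiguous
#' memberships; smaller values indicate a more decisive clustering.
#'
#' @param membership An `fcm_fit` or an n x C row-stochastic matrix.
#' @return A single number in `[0, log2(C)]`.
#' @examples
#' partition_entropy(rbind(c(1, 0), c(0.5, 0.5)))
#' @export
partition_entropy <- function(membership) {
  u <- membership_matrix(membership)
  if (any(u < -1e-9) || any(u > 1 + 1e-9)) {
    abort("Membership values must lie in [0, 1].", class = "trisense_malformed_membership")
  }
  if (any(abs(rowSums(u) - 1) > 1e-6)) {
    abort("Membership rows must sum to 1.", class = "trisense_malformed_membership")
  }
  terms <- ifelse(u > 0, u * log2(pmax(u, .Machine$double.xmin)), 0)
  -sum(terms) / nrow(u)
}

#' Label-matched clustering accuracy
#'
#' Cluster indices are arbitrary, so accuracy is computed after aligning
#' clusters to classes with the one-to-one assignment that maximizes the
#' number of matches on the C x C confusion matrix (found by exhaustive
#' enumeration of bijections). Accuracy is the matched fraction of
#' samples.
#'
#' @param membership An `fcm_fit`, an n x C membership matrix, or an
#'   integer vector of hard cluster labels in `1:C`.
#' @param true_labels A vector of true class labels, one per sample, with
#'   exactly C distinct values.
#' @return A list with `accuracy` (fraction in `[0, 1]`) and `mapping` (a
#'   tibble mapping each cluster index to the class it was assigned to).
#' @examples
#' u <- rbind(c(1, 0), c(0, 1), c(0, 1), c(0, 1))
#' clustering_accuracy(u, c("x", "x", "y", "y"))$accuracy
#' @export
clustering_accuracy <- function(membership, true_labels) {
  hard <- if (is.numeric(membership) && is.null(dim(membership))) {
    as.integer(membership)
  } else {
    hard_labels(membership)
  }
  n <- length(hard)
  if (length(true_labels) != n) {
    abort("`true_labels` must have one entry per sample.",
          class = "trisense_parameter_error")
  }
  truth <- factor(true_labels)
  C <- nlevels(truth)
  n_clusters <- if (is.numeric(membership) && is.null(dim(membership))) {
    max(hard)
  } else {
    ncol(membership_matrix(membership))
  }
  if (n_clusters != C) {
    abort(sprintf("Cluster count (%d) must equal class count (%d).", n_clusters, C),
          class = "trisense_parameter_error")
  }
  if (C > 8L) {
    abort("Optimal cluster-class assignment by enumeration supports C <= 8.",
          class = "trisense_parameter_error")
  }
  confusion <- table(factor(hard, levels = seq_len(C)), truth)
  perms <- permutations(C)
  matches <- apply(perms, 1L, function(p) {
    sum(confusion[cbind(seq_len(C), p)])
  })
  best <- perms[which.max(matches), ]
  list(
    accuracy = max(matches) / n,
    mapping = tibble(cluster = seq_len(C), class = levels(truth)[best])
  )
}

# all permutations of 1:n as an (n!) x n matrix
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out[[i]] <- cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

#' Combined feature-quality report
#'
#' Convenience wrapper computing the three indices used to compare feature
#' sets: label-matched clustering accuracy, partition entropy of the fuzzy
#' memberships, and the scatter-trace ratio of the features under the true
#' labels.
#'
#' @param features A feature tibble or matrix.
#' @param fit An `fcm_fit` for the same samples.
#' @param true_labels True class labels, one per sample.
#' @param scatter_on `"true"` (default) to compute the scatter traces on
#'   the true labels, `"predicted"` to use the clustering's hard labels.
#' @return A one-row tibble with `accuracy`, `etp`, `tr_sw`, `tr_sb`,
#'   `ratio`.
#' @export
evaluate_features <- function(features, fit, true_labels,
                              scatter_on = c("true", "predicted")) {
  scatter_on <- match.arg(scatter_on)
  acc <- clustering_accuracy(fit, true_labels)
  etp <- partition_entropy(fit)
  lab <- if (scatter_on == "true") true_labels else hard_labels(fit)
  sc <- scatter_traces(features, lab)
  dplyr::bind_cols(tibble(accuracy = acc$accuracy, etp = etp), sc)
}
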