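#' Fuzzy c-means clustering
#'
#' Standard fuzzy c-means (Bezdek's alternating optimization): cluster
#' centers are membership-weighted means, memberships are inverse-distance
#' ratios, and the two updates alternate until the objective
#' `sum_i sum_k u_ik^fuzzifier * ||x_i - c_k||^2` decreases by less than
#' `tol` or `max_iter` is reached. The objective is non-increasing across
#' iterations; the full trajectory is stored so convergence can be
#' inspected (see [autoplot.fcm_fit()]).
#'
#' @param features A feature tibble (see [extract_features()]) or numeric
#'   matrix, one row per sample.
#' @param clusters Number of clusters `C >= 2` (and `<=` number of samples).
#' @param fuzzifier Fuzziness exponent `> 1`; 2 is the conventional choice.
#' @param tol Convergence tolerance on the objective decrease.
#' @param max_iter Iteration cap.
#' @param seed Integer seed for the random membership initialization.
#' @return An object of class `fcm_fit` with elements `membership` (n x C,
#'   rows sum to 1), `centers` (C x d), `objective` (per-iteration
#'   trajectory), `n_iter`, `converged` and `config`.
#' @examples
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 6), 20))
#' fit <- fcm(x, clusters = 2, seed = 1)
#' table(hard_labels(fit))
#' @export
fcm <- function(features, clusters, fuzzifier = 2, tol = 1e-5, max_iter = 300L,
                seed = 1L) {
  x <- as_feature_matrix(features)
  n <- nrow(x)
  if (!is.numeric(clusters) || length(clusters) != 1L || clusters < 2L) {
    abort("`clusters` must be a single integer >= 2.", class = "trisense_parameter_error")
  }
  clusters <- as.integer(clusters)
  if (n < clusters) {
    abort(sprintf("Need at least as many samples (%d) as clusters (%d).", n, clusters),
          class = "trisense_parameter_error")
  }
  if (!all(is.finite(x))) {
    abort("`features` contains non-finite values.", class = "trisense_data_error")
  }
  if (fuzzifier <= 1) abort("`fuzzifier` must be > 1.", class = "trisense_parameter_error")
  if (tol <= 0) abort("`tol` must be > 0.", class = "trisense_parameter_error")
  if (max_iter < 1L) abort("`max_iter` must be >= 1.", class = "trisense_parameter_error")

  u <- withr::with_seed(
    seed,
    matrix(runif(n * clusters), n, clusters),
    .rng_kind = "Mersenne-Twister", .rng_normal_kind = "Inversion"
  )
  u <- u / rowSums(u)

  x_sq <- rowSums(x^2)
  trajectory <- numeric(0)
  converged <- FALSE
  iter <- 0L
  j_prev <- Inf
  expo <- -1 / (fuzzifier - 1)
  for (iter in seq_len(max_iter)) {
    um <- u^fuzzifier
    centers <- (t(um) %*% x) / colSums(um)
    d2 <- outer(x_sq, rep(1, clusters)) - 2 * x %*% t(centers) +
      outer(rep(1, n), rowSums(centers^2))
    d2 <- pmax(d2, 0)
    j <- sum(um * d2)
    trajectory <- c(trajectory, j)
    if (j_prev - j < tol) {
      converged <- TRUE
      break
    }
    j_prev <- j
    # membership update, guarding samples that coincide with a center
    zero <- d2 < .Machine$double.eps
    inv <- d2^expo
    u <- inv / rowSums(inv)
    hit <- rowSums(zero) > 0L
    if (any(hit)) {
      u[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
    }
  }

  rownames(u) <- rownames(x)
  rownames(centers) <- paste0("cluster", seq_len(clusters))
  colnames(centers) <- colnames(x)
  structure(
    list(
      membership = u,
      centers = centers,
      objective = trajectory,
      n_iter = iter,
      converged = converged,
      config = list(
        clusters = clusters, fuzzifier = fuzzifier, tol = tol,
        max_iter = max_iter, seed = seed
      )
    ),
    class = "fcm_fit"
  )
}

#' @export
print.fcm_fit <- function(x, ...) {
  cat(sprintf(
    "<fcm_fit> %d samples, %d clusters, %d iterations (%s), objective %.6g\n",
    nrow(x$membership), ncol(x$membership), x$n_iter,
    if (x$converged) "converged" else "iteration cap reached",
    x$objective[length(x$objective)]
  ))
  invisible(x)
}

#' Hard cluster labels from fuzzy memberships
#'
#' Assigns every sample to its cluster of maximal membership; ties go to
#' the lowest cluster index.
#'
#' @param x An `fcm_fit` or an n x C membership matrix.
#' @return An integer vector of cluster indices in `1:C`.
#' @export
hard_labels <- function(x) {
  m <- membership_matrix(x)
  max.col(m, ties.method = "first")
}

membership_matrix <- function(x) {
  if (inherits(x, "fcm_fit")) {
    x$membership
  } else if (is.matrix(x) && is.numeric(x)) {
    x
  } else {
    abort("Expected an `fcm_fit` or a numeric membership matrix.")
  }
}
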