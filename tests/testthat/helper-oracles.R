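# Independent oracles and small fixture builders used across the suite.

# random valid amino-acid sequences (uniform residues)
random_records <- function(n, min_len = 10, max_len = 40, seed = 1) {
  withr::with_seed(seed, {
    lens <- sample(min_len:max_len, n, replace = TRUE)
    tibble::tibble(
      id = sprintf("seq%03d", seq_len(n)),
      sequence = vapply(lens, function(L) {
        paste(sample(aa_alphabet, L, replace = TRUE), collapse = "")
      }, character(1))
    )
  })
}

# brute-force tripeptide tensor: explicit sliding window, no index arithmetic
naive_tensor <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  M <- array(0L, dim = c(20, 20, 20))
  for (t in seq_len(length(chars) - 2)) {
    i <- match(chars[t], aa_alphabet)
    j <- match(chars[t + 1], aa_alphabet)
    k <- match(chars[t + 2], aa_alphabet)
    M[i, j, k] <- M[i, j, k] + 1L
  }
  M
}

# brute-force scatter traces via explicit double loops over samples
naive_scatter <- function(x, labels) {
  f <- factor(labels)
  grand <- colMeans(x)
  tr_sw <- 0
  tr_sb <- 0
  for (lev in levels(f)) {
    xk <- x[f == lev, , drop = FALSE]
    mk <- colMeans(xk)
    for (r in seq_len(nrow(xk))) {
      tr_sw <- tr_sw + sum((xk[r, ] - mk)^2)
    }
    tr_sb <- tr_sb + nrow(xk) * sum((mk - grand)^2)
  }
  c(tr_sw = tr_sw, tr_sb = tr_sb)
}

# exhaustive-bijection clustering accuracy, built from expand.grid rather
# than the package's permutation generator
naive_accuracy <- function(hard, truth) {
  truth <- factor(truth)
  C <- nlevels(truth)
  grids <- expand.grid(rep(list(seq_len(C)), C))
  bijections <- grids[apply(grids, 1, function(r) length(unique(r)) == C), , drop = FALSE]
  best <- 0
  for (r in seq_len(nrow(bijections))) {
    mapped <- levels(truth)[as.integer(bijections[r, ])][hard]
    best <- max(best, mean(mapped == as.character(truth)))
  }
  best
}

# crisp membership matrix from hard labels
crisp_membership <- function(labels, C = max(labels)) {
  u <- matrix(0, length(labels), C)
  u[cbind(seq_along(labels), labels)] <- 1
  u
}

# FCM result contract: row-stochastic memberships, non-increasing objective
expect_fcm_valid <- function(fit) {
  expect_true(all(abs(rowSums(fit$membership) - 1) < 1e-9))
  expect_true(all(fit$membership >= 0 & fit$membership <= 1 + 1e-12))
  expect_true(all(diff(fit$objective) <= 1e-9))
}
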