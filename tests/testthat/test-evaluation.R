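test_that("scatter traces match the hand-computed two-class example", {
  x <- rbind(c(0, 0), c(0, 0), c(2, 0), c(2, 0))
  st <- scatter_traces(x, c(0, 0, 1, 1))
  expect_equal(st$tr_sw, 0)
  expect_equal(st$tr_sb, 4) # each class: 2 samples at distance 1 from the grand mean
  expect_equal(st$ratio, 0)
})

test_that("coincident class means raise a degenerate-separation error", {
  x <- matrix(1, 4, 3)
  expect_error(scatter_traces(x, c(0, 0, 1, 1)),
               class = "trisense_degenerate_separation")
})

test_that("scatter traces agree with the brute-force double loop on random data", {
  withr::with_seed(12, {
    for (rep in 1:20) {
      n <- sample(6:20, 1)
      d <- sample(2:6, 1)
      C <- sample(2:4, 1)
      x <- matrix(rnorm(n * d), n, d)
      labels <- sample(seq_len(C), n, replace = TRUE)
      if (length(unique(labels)) < 2) labels[1:2] <- c(1, 2)
      st <- scatter_traces(x, labels)
      oracle <- naive_scatter(x, labels)
      expect_lt(abs(st$tr_sw - oracle["tr_sw"]), 1e-9)
      expect_lt(abs(st$tr_sb - oracle["tr_sb"]), 1e-9)
    }
  })
})

test_that("within + between scatter equals the total scatter trace", {
  withr::with_seed(14, {
    x <- matrix(rnorm(60), 20, 3)
    labels <- sample(1:3, 20, replace = TRUE)
  })
  st <- scatter_traces(x, labels)
  total <- sum(sweep(x, 2, colMeans(x))^2)
  expect_equal(st$tr_sw + st$tr_sb, total, tolerance = 1e-9)
})

test_that("partition entropy hits its closed-form extremes", {
  crisp <- crisp_membership(c(1, 2, 1, 2), 2)
  expect_equal(partition_entropy(crisp), 0)

  expect_equal(partition_entropy(matrix(0.5, 5, 2)), 1)
  expect_equal(partition_entropy(matrix(0.25, 5, 4)), 2)
})

test_that("partition entropy is bounded by [0, log2 C] on random memberships", {
  withr::with_seed(15, {
    for (rep in 1:10) {
      C <- sample(2:5, 1)
      u <- matrix(runif(12 * C), 12, C)
      u <- u / rowSums(u)
      etp <- partition_entropy(u)
      expect_gte(etp, 0)
      expect_lte(etp, log2(C) + 1e-12)
    }
  })
})

test_that("malformed memberships are rejected", {
  expect_error(partition_entropy(matrix(0.4, 3, 2)),
               class = "trisense_malformed_membership")
  bad <- rbind(c(1.5, -0.5), c(0.5, 0.5))
  expect_error(partition_entropy(bad), class = "trisense_malformed_membership")
})

test_that("clustering accuracy aligns clusters to classes optimally", {
  truth <- c("a", "a", "b", "b")

  ident <- crisp_membership(c(1, 1, 2, 2), 2)
  expect_equal(clustering_accuracy(ident, truth)$accuracy, 1)

  swapped <- crisp_membership(c(2, 2, 1, 1), 2)
  res <- clustering_accuracy(swapped, truth)
  expect_equal(res$accuracy, 1)
  expect_equal(res$mapping$class, c("b", "a"))

  # one sample of class a lands in the b-dominated cluster
  u <- crisp_membership(c(1, 2, 2, 2), 2)
  expect_equal(clustering_accuracy(u, truth)$accuracy, 0.75)
})

test_that("accuracy matches exhaustive bijection enumeration for C <= 4", {
  withr::with_seed(16, {
    for (rep in 1:12) {
      C <- sample(2:4, 1)
      n <- 30
      truth <- sample(seq_len(C), n, replace = TRUE)
      truth[seq_len(C)] <- seq_len(C)
      hard <- sample(seq_len(C), n, replace = TRUE)
      hard[seq_len(C)] <- seq_len(C)
      got <- clustering_accuracy(crisp_membership(hard, C), truth)$accuracy
      expect_equal(got, naive_accuracy(hard, truth))
    }
  })
})

test_that("accuracy is invariant to cluster relabeling and sample order", {
  withr::with_seed(17, {
    truth <- sample(1:3, 30, replace = TRUE)
    truth[1:3] <- 1:3
    hard <- sample(1:3, 30, replace = TRUE)
    hard[1:3] <- 1:3
  })
  base <- clustering_accuracy(crisp_membership(hard, 3), truth)$accuracy
  relab <- c(3L, 1L, 2L)[hard]
  expect_equal(clustering_accuracy(crisp_membership(relab, 3), truth)$accuracy, base)
  ord <- sample(30)
  expect_equal(clustering_accuracy(crisp_membership(hard[ord], 3), truth[ord])$accuracy, base)
})

test_that("cluster/class cardinality mismatches are rejected", {
  u <- crisp_membership(c(1, 2, 1, 2), 2)
  expect_error(clustering_accuracy(u, c("a", "b", "c", "a")),
               class = "trisense_parameter_error")
})
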