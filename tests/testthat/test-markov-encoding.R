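test_that("residue_index follows alphabetical order of the 20-letter alphabet", {
  expect_equal(residue_index("A"), 0L)
  expect_equal(residue_index("C"), 1L)
  expect_equal(residue_index("Y"), 19L)
  expect_equal(residue_index(aa_alphabet), 0:19)
  expect_error(residue_index("X"), "X", class = "trisense_invalid_symbol")
})

test_that("count_tripeptides places single windows at the forced cells", {
  m <- count_tripeptides("ACD")
  expect_equal(sum(m), 1L)
  expect_equal(m[1, 2, 3], 1L) # A, C, D at alphabet positions 1, 2, 3

  m2 <- count_tripeptides("AAAA")
  expect_equal(m2[1, 1, 1], 2L) # two overlapping AAA windows
  expect_equal(sum(m2), 2L)
})

test_that("count_tripeptides rejects short or invalid sequences", {
  expect_error(count_tripeptides("AC"), class = "trisense_too_short")
  expect_error(count_tripeptides("ACXDE"), class = "trisense_invalid_symbol")
})

test_that("tensor counts match a brute-force sliding-window oracle", {
  recs <- random_records(6, min_len = 5, max_len = 60, seed = 3)
  for (r in seq_len(nrow(recs))) {
    m <- count_tripeptides(recs$sequence[r])
    expect_equal(unclass(m), naive_tensor(recs$sequence[r]),
                 ignore_attr = TRUE)
  }
})

test_that("tensor total equals L - 2 and sparsity is bounded (conservation)", {
  recs <- random_records(20, min_len = 3, max_len = 120, seed = 5)
  for (r in seq_len(nrow(recs))) {
    L <- nchar(recs$sequence[r])
    m <- count_tripeptides(recs$sequence[r])
    v <- flatten_signal(m)
    expect_equal(sum(m), L - 2L)
    expect_equal(sum(v), L - 2L)
    expect_lte(sum(v != 0), min(L - 2L, 8000L))
    expect_true(all(v >= 0) && all(v == round(v)))
  }
})

test_that("flatten uses row-major order: cell (i,j,k) lands at 400i + 20j + k", {
  # tensor whose cell value encodes its own expected flat index
  idx <- expand.grid(k = 0:19, j = 0:19, i = 0:19)
  m <- unflatten_signal(numeric(8000))
  m[cbind(idx$i + 1, idx$j + 1, idx$k + 1)] <- 400 * idx$i + 20 * idx$j + idx$k
  v <- flatten_signal(m)
  expect_equal(as.numeric(v), 0:7999)

  # the single tripeptide ACD sits at index 0*400 + 1*20 + 2 = 22 (0-based)
  v_acd <- flatten_signal(count_tripeptides("ACD"))
  expect_equal(which(v_acd != 0) - 1L, 22L)
})

test_that("flatten / unflatten round-trips and the zero tensor maps to zeros", {
  recs <- random_records(5, min_len = 10, max_len = 50, seed = 9)
  for (r in seq_len(nrow(recs))) {
    m <- count_tripeptides(recs$sequence[r])
    expect_equal(unflatten_signal(flatten_signal(m)), m)
  }
  expect_equal(sum(flatten_signal(unflatten_signal(numeric(8000)))), 0)
  expect_equal(length(flatten_signal(unflatten_signal(numeric(8000)))), 8000L)
})

test_that("relabeling residues permutes the tensor axes identically", {
  withr::with_seed(21, {
    for (rep in 1:3) {
      seq0 <- paste(sample(aa_alphabet, 30, replace = TRUE), collapse = "")
      p <- sample(20)
      translated <- chartr(paste(aa_alphabet, collapse = ""),
                           paste(aa_alphabet[p], collapse = ""), seq0)
      m0 <- count_tripeptides(seq0)
      mp <- count_tripeptides(translated)
      expect_equal(unclass(mp)[p, p, p], unclass(m0), ignore_attr = TRUE)
    }
  })
})

test_that("to_probability normalizes by the total count", {
  m <- count_tripeptides("ACD")
  p <- to_probability(m)
  expect_equal(p[1, 2, 3], 1)
  expect_equal(sum(p), 1)

  p2 <- to_probability(count_tripeptides("AAAA"))
  expect_equal(p2[1, 1, 1], 1)

  recs <- random_records(3, min_len = 30, max_len = 80, seed = 2)
  for (s in recs$sequence) {
    expect_equal(sum(to_probability(count_tripeptides(s))), 1, tolerance = 1e-12)
  }
  expect_error(to_probability(unflatten_signal(numeric(8000))),
               class = "trisense_degenerate_normalization")
})

test_that("amino-acid composition is the normalized residue tally", {
  v <- aac_vector("AAAA")
  expect_equal(unname(v[1]), 1)
  expect_equal(sum(v), 1)

  u <- aac_vector(paste(aa_alphabet, collapse = ""))
  expect_equal(unname(u), rep(0.05, 20))

  recs <- random_records(5, seed = 4)
  for (s in recs$sequence) {
    expect_equal(sum(aac_vector(s)), 1, tolerance = 1e-12)
  }
  expect_error(aac_vector(""), "non-empty")
})
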