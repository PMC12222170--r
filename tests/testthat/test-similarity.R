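test_that("Smith-Waterman scorer matches the spec's hand examples", {
  sch <- scoring_scheme(1, -1, -1)
  expect_equal(smith_waterman_score("ACGU", "ACGU", sch), 4)
  expect_equal(smith_waterman_score("ACGU", "UGCA", sch), 1)
  expect_equal(smith_waterman_score("A", "A", sch), 1)
  expect_equal(smith_waterman_score("A", "A", scoring_scheme(2.5, -1, -1)),
               2.5)
  expect_error(smith_waterman_score("ACGT", "ACGU", sch), "A,C,G,U")
  expect_error(smith_waterman_score("", "A", sch), "empty")
})

test_that("scorer agrees with the matching-enumeration oracle on mixed-alphabet cases", {
  set.seed(42)
  sch <- scoring_scheme(1, -1, -1)
  for (rep in 1:25) {
    a <- paste(sample(c("A", "C", "G", "U"), sample(2:6, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "U"), sample(2:6, 1), TRUE),
               collapse = "")
    expect_equal(smith_waterman_score(a, b, sch),
                 oracle_local_score_general(a, b), info = paste(a, b))
  }
})

test_that("scorer agrees with pairwiseAlignment local scores", {
  # independent cross-check against the Biostrings aligner (linear gaps:
  # zero opening cost, per-base extension)
  set.seed(1)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  for (rep in 1:20) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(8:20, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(8:20, 1), TRUE),
               collapse = "")
    ref <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = 1,
                                         scoreOnly = TRUE)
    mine <- smith_waterman_score(chartr("T", "U", a), chartr("T", "U", b))
    expect_equal(mine, ref, info = paste(a, b))
  }
})

test_that("normalized similarity is 1 on self, symmetric, and matches hand values", {
  set.seed(3)
  expect_equal(normalized_sequence_similarity("ACGU", "UGCA"), 0.25)
  for (rep in 1:20) {
    a <- paste(sample(c("A", "C", "G", "U"), 15, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "U"), 15, TRUE), collapse = "")
    expect_equal(normalized_sequence_similarity(a, a), 1)
    expect_equal(normalized_sequence_similarity(a, b),
                 normalized_sequence_similarity(b, a))
  }
})

test_that("sequence network is symmetric, unit-diagonal, weighted in [0,1]", {
  seqs <- setNames(c("ACGUACGU", "ACGUACGU", "ACGUACGU"), c("a", "b", "c"))
  expect_equal(unname(unclass(build_sequence_network(seqs))[, ]),
               matrix(1, 3, 3))

  set.seed(9)
  seqs <- setNames(replicate(50, paste(sample(c("A", "C", "G", "U"),
                                              sample(18:25, 1), TRUE),
                                       collapse = "")),
                   sprintf("m%02d", 1:50))
  net <- build_sequence_network(seqs)
  expect_identical(unclass(net)[, ], t(unclass(net)[, ]))  # bit-exact
  expect_true(all(net >= 0 & net <= 1))
  expect_equal(unname(diag(net)), rep(1, 50))
})

test_that("GIP kernel matches its closed form and is a proper similarity", {
  p <- rbind(a = c(1, 0), b = c(0, 1))
  k <- gip_kernel(p)
  expect_equal(k["a", "b"], exp(-2))  # gamma = 1, squared distance 2
  expect_equal(diag(k), c(a = 1, b = 1))

  set.seed(5)
  p <- matrix(rbinom(200, 1, 0.3), 20,
              dimnames = list(sprintf("m%d", 1:20), NULL))
  k <- gip_kernel(p)
  expect_true(check_symmetric(k))
  expect_true(all(k > 0 & k <= 1))
  expect_equal(unname(diag(k)), rep(1, 20))
  expect_equal(gip_kernel(rbind(c(1, 1), c(1, 1)))[1, 2], 1)

  expect_error(gip_kernel(matrix(0, 3, 4)), "all-zero")
})

test_that("similarity fusion is exact at the boundaries and elementwise inside", {
  set.seed(2)
  fs <- matrix(runif(16), 4)
  fs <- (fs + t(fs)) / 2
  gip <- matrix(runif(16), 4)
  gip <- (gip + t(gip)) / 2
  expect_equal(fuse_similarity(fs, gip, 1)[, ], fs, ignore_attr = TRUE)
  expect_equal(fuse_similarity(fs, gip, 0)[, ], gip, ignore_attr = TRUE)
  expect_equal(fuse_similarity(matrix(0.4), matrix(0.8), 0.5)[1, 1], 0.6)
  fused <- fuse_similarity(fs, gip, 0.3)
  expect_true(check_symmetric(fused))
  expect_error(fuse_similarity(fs, matrix(0, 3, 3), 0.5), "shape")
})

test_that("binarization is strict, hollow, symmetric and monotone in T", {
  m <- matrix(c(1, 0.7, 0.7, 0.2), 2)
  expect_equal(unname(binarize(m, 0.6)[, ]), matrix(c(0, 1, 1, 0), 2),
               ignore_attr = TRUE)
  expect_equal(binarize(matrix(c(1, 0.6, 0.6, 1), 2), 0.6)[1, 2], 0)

  set.seed(4)
  s <- matrix(runif(400), 20)
  s <- (s + t(s)) / 2
  counts <- vapply(seq(0, 1, by = 0.1),
                   function(T) sum(binarize(s, T)), 0)
  expect_true(all(diff(counts) <= 0))
  a <- binarize(s, 0.3)
  expect_true(all(diag(a) == 0))
  expect_identical(unclass(a)[, ], t(unclass(a)[, ]))
  # edge-set nesting: everything present at the higher threshold is
  # present at the lower one
  expect_true(all(binarize(s, 0.3)[binarize(s, 0.7) == 1] == 1))
})
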