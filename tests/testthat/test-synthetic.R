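test_that("planted model validates its parameters", {
  expect_error(planted_model(n_groups = 1L), "n_groups")
  expect_error(planted_model(p_in = 0.1, p_out = 0.2), "p_in")
  expect_error(planted_model(motif_length = 10L), "motif_length")
  m <- planted_model()
  expect_equal(m$n_mirna, 300L)
  expect_equal(m$n_groups, 4L)
  expect_equal(dim(m$label_probs), c(4L, 7L))
})

test_that("sequences carry the group signal at the configured mutation rate", {
  m0 <- planted_model(n_mirna = 40L, n_disease = 12L, n_drug = 8L,
                      n_mrna = 20L, mutation_rate = 0, seed = 3)
  s0 <- generate_sequences(m0)
  expect_true(all(nchar(s0) >= 18 & nchar(s0) <= 25))
  # zero mutation: same-group sequences are prefixes of one motif
  g1 <- which(m0$groups == 1)
  sim <- normalized_sequence_similarity(s0[[g1[1]]], s0[[g1[2]]])
  l <- min(nchar(s0[[g1[1]]]), nchar(s0[[g1[2]]]))
  expect_gte(sim, l / sqrt(nchar(s0[[g1[1]]]) * nchar(s0[[g1[2]]])))

  expect_identical(generate_sequences(m0), generate_sequences(m0))

  within_between <- vapply(1:5, function(s) {
    m <- planted_model(n_mirna = 40L, n_disease = 12L, n_drug = 8L,
                       n_mrna = 20L, mutation_rate = 0.1, seed = s)
    net <- build_sequence_network(generate_sequences(m))
    same <- outer(m$groups, m$groups, "==") & upper.tri(net)
    diff_g <- !outer(m$groups, m$groups, "==") & upper.tri(net)
    c(mean(net[same]), mean(net[diff_g]))
  }, numeric(2))
  expect_true(all(within_between[1, ] > within_between[2, ]))
})

test_that("the disease DAG is a rooted tree with group-coherent subtrees", {
  m <- planted_model(n_mirna = 30L, n_disease = 25L, n_drug = 8L,
                     n_mrna = 20L, seed = 5)
  dd <- generate_disease_dag(m)
  expect_equal(nrow(dd$edges), 24L)  # tree: n - 1 edges
  # every node reaches the root
  root <- setdiff(dd$edges$parent, dd$edges$child)[1]
  for (d in dd$dag$nodes) {
    expect_true(root %in% names(dd$dag$ancestors[[d]]))
  }
  # group anchors partition the non-root diseases
  expect_setequal(unique(dd$disease_group), 0:4)
})

test_that("association densities concentrate around the block design", {
  m <- planted_model(n_mirna = 200L, n_disease = 40L, n_drug = 40L,
                     n_mrna = 80L, p_in = 0.3, p_out = 0.02, seed = 9)
  for (kind in c("mrna", "drug")) {
    a <- generate_associations(m, kind)
    expected <- (m$p_in + (m$n_groups - 1) * m$p_out) / m$n_groups
    n_cells <- length(a)
    se <- sqrt(expected * (1 - expected) / n_cells)
    expect_lt(abs(mean(a) - expected), 3 * se)
  }
  a1 <- generate_associations(m, "drug")
  expect_identical(a1, generate_associations(m, "drug"))

  m0 <- planted_model(n_mirna = 60L, n_disease = 20L, n_drug = 20L,
                      n_mrna = 20L, p_in = 0.5, p_out = 0, seed = 2)
  a0 <- generate_associations(m0, "mrna")
  egrp <- rep(1:4, length.out = 20)
  expect_true(all(a0[outer(m0$groups, egrp, "!=")] == 0))  # block diagonal
})

test_that("labels follow the group profile and its prevalence ranking", {
  m <- planted_model(seed = 13)  # defaults: deterministic 0/1 profile
  lab <- generate_labels(m)
  # group-deterministic: every miRNA matches its group's row exactly
  expect_equal(unname(unclass(lab)[, ]),
               unname(m$label_probs[m$groups, ]))
  prev <- colMeans(lab)
  expect_true(prev["exosome"] >= prev["nucleus"])
  expect_true(prev["microvesicle"] >= prev["cytoplasm"])
  expect_true(prev["nucleus"] >= prev["nucleolus"])

  # probabilistic profile: concentration within 3 binomial SEs
  probs <- matrix(0.5, 4, 7, dimnames = list(NULL, COMPARTMENTS))
  probs[, 1] <- c(0.9, 0.1, 0.9, 0.1)
  mp <- planted_model(label_probs = probs, seed = 21)
  labp <- generate_labels(mp)
  expect_lt(abs(mean(labp[, 2]) - 0.5), 3 * sqrt(0.25 / 300))

  expect_warning(generate_labels(
    planted_model(label_probs = matrix(c(rep(1, 4), rep(0, 24)), 4, 7),
                  seed = 2)), "zero expected")
})

test_that("generated bundles round-trip through the loaders", {
  dir <- withr::local_tempdir()
  m <- planted_model(n_mirna = 30L, n_disease = 12L, n_drug = 8L,
                     n_mrna = 16L, seed = 17)
  ds <- generate_dataset(m, dir)
  expect_true(all(file.exists(file.path(dir,
    c("mirnas.fasta", "mrna.tsv", "drug.tsv", "disease.tsv",
      "disease_dag.tsv", "labels.csv", "model.yaml")))))
  back <- load_dataset(dir)
  expect_identical(back$registry$ids, ds$registry$ids)
  expect_identical(as.character(back$sequences), as.character(ds$sequences))
  expect_identical(unclass(back$labels)[, ], unclass(ds$labels)[, ])
  for (k in c("mrna", "drug", "disease")) {
    nz <- colSums(ds$assoc[[k]]) > 0
    expect_identical(unclass(back$assoc[[k]])[, colnames(ds$assoc[[k]])[nz]],
                     unclass(ds$assoc[[k]])[, nz])
  }
  expect_setequal(back$dag$nodes, ds$dag$nodes)

  # different seeds give different bundles
  d2 <- withr::local_tempdir()
  generate_dataset(planted_model(n_mirna = 30L, n_disease = 12L,
                                 n_drug = 8L, n_mrna = 16L, seed = 18), d2)
  expect_false(identical(readLines(file.path(dir, "mirnas.fasta")),
                         readLines(file.path(d2, "mirnas.fasta"))))
})
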