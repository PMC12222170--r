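test_that("k-fold splits partition with near-equal sizes, seeded", {
  s <- kfold_split(10, 10, seed = 1)
  expect_true(all(lengths(s$folds) == 1))
  s2 <- kfold_split(11, 10, seed = 1)
  expect_equal(sort(lengths(s2$folds), decreasing = TRUE),
               c(2, rep(1, 9)))
  s3 <- kfold_split(57, 5, seed = 3)
  expect_equal(sort(unlist(s3$folds)), 1:57)
  expect_true(max(lengths(s3$folds)) - min(lengths(s3$folds)) <= 1)
  expect_identical(kfold_split(57, 5, seed = 3)$folds, s3$folds)
  expect_error(kfold_split(4, 5), "exceed")
})

test_that("ROC AUC matches hand cases and the brute-force oracle", {
  expect_equal(roc_auc(c(0.9, 0.1), c(1, 0)), 1)
  expect_equal(roc_auc(c(0.1, 0.9), c(1, 0)), 0)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_true(is.nan(roc_auc(c(0.2, 0.8), c(1, 1))))

  set.seed(17)
  for (rep in 1:100) {
    scores <- round(runif(20), 2)  # rounding forces ties
    labels <- rbinom(20, 1, 0.4)
    if (sum(labels) %in% c(0, 20)) next
    expect_equal(roc_auc(scores, labels), brute_roc_auc(scores, labels),
                 tolerance = 1e-9)
  }
})

test_that("PR AUC matches hand cases and the threshold-sweep oracle", {
  expect_equal(pr_auc(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1)
  expect_equal(pr_auc(rep(0.3, 10), c(rep(1, 3), rep(0, 7))), 0.3)
  expect_true(is.nan(pr_auc(c(0.2, 0.8), c(0, 0))))

  set.seed(23)
  for (rep in 1:100) {
    scores <- round(runif(20), 2)
    labels <- rbinom(20, 1, 0.4)
    if (sum(labels) == 0) next
    expect_equal(pr_auc(scores, labels), brute_pr_auc(scores, labels),
                 tolerance = 1e-9)
  }
})

test_that("metric implementations agree with pROC on untied scores", {
  skip_if_not_installed("pROC")
  set.seed(5)
  scores <- runif(50)
  labels <- rbinom(50, 1, 0.5)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<",
                                        levels = c(0, 1))))
  expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-12)
})

test_that("top-k ranking is prefix-stable with registry-order ties", {
  probs <- matrix(c(0.9, 0.5, 0.5, 0.1,
                    0.2, 0.8, 0.8, 0.8), 4,
                  dimnames = list(sprintf("m%d", 1:4), NULL))
  probs <- cbind(probs, matrix(0.5, 4, 5))
  colnames(probs) <- COMPARTMENTS
  pred <- structure(list(probabilities = probs,
                         calls = (probs > 0.5) * 1, threshold = 0.5),
                    class = "gtmaloc_prediction")
  top <- top_k_per_compartment(pred, 3)
  expect_equal(top$cytoplasm, c("m1", "m2", "m3"))  # tie broken by order
  expect_equal(top$nucleus, c("m2", "m3", "m4"))
  expect_equal(top_k_per_compartment(pred, 1)$cytoplasm, "m1")
  top4 <- top_k_per_compartment(pred, 4)
  expect_equal(top4$cytoplasm[1:3], top$cytoplasm)  # prefix stability
  expect_error(top_k_per_compartment(pred, 9), "exceeds")
})

test_that("cross-validation reports are complete, leakage-free and class-order invariant", {
  ds <- tiny_dataset(seed = 19, n = 48)
  cfg <- tiny_config(graph_transformer = list(enabled = FALSE))
  feats <- gtmaloc_features(ds, cfg)
  cv <- cross_validate(feats, k = 4, seed = 2)
  expect_equal(dim(cv$auc), c(4L, 7L))
  expect_equal(dim(cv$aupr), c(4L, 7L))
  ok <- !is.nan(cv$auc)
  expect_true(all(cv$auc[ok] >= 0 & cv$auc[ok] <= 1))
  # folds partition and no test row was trained on
  expect_equal(sort(unlist(cv$folds)), 1:48)
  for (i in 1:4) {
    expect_length(intersect(cv$train_rows[[i]], cv$folds[[i]]), 0)
    expect_setequal(union(cv$train_rows[[i]], cv$folds[[i]]), 1:48)
  }
  # macro average is the unweighted mean over class fold-means,
  # invariant to class order
  expect_equal(cv$macro_auc, mean(colMeans(cv$auc, na.rm = TRUE),
                                  na.rm = TRUE))
  perm <- c(3, 1, 7, 2, 6, 4, 5)
  expect_equal(mean(colMeans(cv$auc[, perm], na.rm = TRUE), na.rm = TRUE),
               cv$macro_auc)
})

test_that("degenerate single-class folds yield flagged NaN cells, never numbers", {
  ds <- tiny_dataset(seed = 19, n = 48)
  cfg <- tiny_config(graph_transformer = list(enabled = FALSE))
  feats <- gtmaloc_features(ds, cfg)
  labels <- feats$labels
  labels[, "nucleolus"] <- 0
  labels[1, "nucleolus"] <- 1  # a single positive: most folds see none
  cv <- cross_validate(feats, k = 4, seed = 2, labels = labels)
  expect_equal(sum(is.nan(cv$auc[, "nucleolus"])), 3L)
  expect_false(is.nan(cv$macro_auc))
})

test_that("ablations drop exactly the targeted component", {
  ds <- tiny_dataset(seed = 29, n = 48)
  cfg <- tiny_config(graph_transformer = list(enabled = FALSE))
  feats <- gtmaloc_features(ds, cfg)
  cv_full <- run_ablation(feats, "none", k = 3, seed = 4)
  cv_dis <- run_ablation(feats, "disease_net", k = 3, seed = 4)
  expect_setequal(cv_dis$sources, c("seq", "mrna", "drug"))
  expect_identical(cv_dis$folds, cv_full$folds)  # shared split
  cv_mha <- run_ablation(feats, "mha", k = 3, seed = 4)
  expect_false(isTRUE(cv_mha$config$fusion$use_mha))
  expect_identical(cv_mha$folds, cv_full$folds)
  expect_error(run_ablation(feats, "everything"), "unknown ablation")

  # mha ablation touches only the fusion attention block: the attention
  # parameters stay at their initial values while the rest still train
  fit_full <- gtmaloc(feats$tokens, feats$labels, config = cfg)
  cfg_no <- cfg
  cfg_no$fusion$use_mha <- FALSE
  fit_no <- gtmaloc(feats$tokens, feats$labels, config = cfg_no)
  init <- gtmaloc:::fusion_init(lapply(feats$tokens, ncol),
                                cfg$fusion$width, cfg$fusion$heads,
                                cfg$fusion$ffn_hidden, 7L, cfg$seed)
  expect_identical(fit_no$params$H1_WQ, init$H1_WQ)
  expect_identical(fit_no$params$WO, init$WO)
  expect_false(identical(fit_full$params$H1_WQ, init$H1_WQ))
  expect_false(identical(fit_no$params$ffn_W1, init$ffn_W1))
})

test_that("head-count study shares splits and validates divisibility", {
  ds <- tiny_dataset(seed = 37, n = 40)
  cfg <- tiny_config(graph_transformer = list(enabled = FALSE))
  feats <- gtmaloc_features(ds, cfg)
  res <- head_count_study(feats, c(2L, 4L), k = 3, seed = 6)
  expect_named(res, c("2", "4"))
  expect_true(all(res >= 0 & res <= 1))
  reports <- attr(res, "reports")
  expect_identical(reports[[1]]$folds, reports[[2]]$folds)
  expect_error(head_count_study(feats, c(3L), k = 3), "not dividing")
})
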