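make_fusion_fixture <- function(n = 5, width = 8, heads = 2, seed = 21) {
  set.seed(seed)
  tabs <- list(seq = matrix(rnorm(n * 4), n), mrna = matrix(rnorm(n * 6), n),
               drug = matrix(rnorm(n * 6), n),
               disease = matrix(rnorm(n * 6), n))
  tabs <- lapply(tabs, function(m) {
    rownames(m) <- sprintf("m%d", seq_len(n))
    m
  })
  params <- gtmaloc:::fusion_init(lapply(tabs, ncol), width, heads,
                                  10L, 7L, seed = seed)
  list(tabs = tabs, params = params, heads = heads)
}

test_that("source projection produces the 4-token sequence and flags missing sources", {
  fx <- make_fusion_fixture()
  tok <- project_sources(fx$tabs, fx$params)
  expect_named(tok, c("seq", "mrna", "drug", "disease"))
  expect_true(all(vapply(tok, function(t) all(dim(t) == c(5, 8)), TRUE)))
  # zero input row maps to the ReLU'd bias image
  tabs0 <- fx$tabs
  tabs0$seq[1, ] <- 0
  tok0 <- project_sources(tabs0, fx$params)
  expect_equal(tok0$seq[1, ],
               pmax(fx$params$proj_seq_b, 0), ignore_attr = TRUE)
  expect_error(project_sources(fx$tabs[1:3], fx$params["proj_seq_W"]),
               "missing projection")
})

test_that("scaled dot-product attention rows are stochastic; degenerate cases uniform", {
  fx <- make_fusion_fixture()
  tok <- project_sources(fx$tabs, fx$params)
  att <- scaled_dot_attention(tok, fx$params, head = 1)
  expect_equal(dim(att$attention), c(5L, 4L, 4L))
  expect_equal(apply(att$attention, c(1, 2), sum),
               matrix(1, 5, 4), tolerance = 1e-12)

  # identical tokens -> uniform 1/4 attention
  tok_same <- rep(tok[1], 4)
  names(tok_same) <- names(tok)
  att_same <- scaled_dot_attention(tok_same, fx$params, head = 1)
  expect_equal(att_same$attention, array(0.25, c(5, 4, 4)))

  # zero query/key maps -> uniform regardless of tokens
  p0 <- fx$params
  p0$H1_WQ <- p0$H1_WQ * 0
  p0$H1_WK <- p0$H1_WK * 0
  att0 <- scaled_dot_attention(tok, p0, head = 1)
  expect_equal(att0$attention, array(0.25, c(5, 4, 4)))
})

test_that("MHA block preserves shape, normalizes per token, and is deterministic at inference", {
  fx <- make_fusion_fixture()
  tok <- project_sources(fx$tabs, fx$params)
  h1a <- mha_block(tok, fx$params, fx$heads, dropout = 0.5,
                   training = FALSE)
  h1b <- mha_block(tok, fx$params, fx$heads, dropout = 0.5,
                   training = FALSE)
  expect_identical(h1a, h1b)  # dropout off at inference
  expect_true(all(vapply(h1a, function(t) all(dim(t) == c(5, 8)), TRUE)))

  # LayerNorm pre-scale/shift statistics: recover z from (out - b) / g
  p <- fx$params
  z <- sweep(sweep(h1a[[1]], 2, p$ln1_b, "-"), 2, p$ln1_g, "/")
  expect_equal(unname(rowMeans(z)), rep(0, 5), tolerance = 1e-10)
  expect_equal(unname(apply(z, 1, function(r) mean(r^2))), rep(1, 5),
               tolerance = 1e-3)  # biased variance, eps-regularized

  # training mode is stochastic
  set.seed(1)
  t1 <- mha_block(tok, fx$params, fx$heads, dropout = 0.5, training = TRUE)
  t2 <- mha_block(tok, fx$params, fx$heads, dropout = 0.5, training = TRUE)
  expect_false(identical(t1, t2))
})

test_that("FFN block reduces to LayerNorm when zeroed and keeps shapes", {
  fx <- make_fusion_fixture()
  tok <- project_sources(fx$tabs, fx$params)
  h1 <- mha_block(tok, fx$params, fx$heads)
  p0 <- fx$params
  p0$ffn_W1 <- p0$ffn_W1 * 0
  p0$ffn_b1 <- p0$ffn_b1 * 0
  p0$ffn_W2 <- p0$ffn_W2 * 0
  p0$ffn_b2 <- p0$ffn_b2 * 0
  out <- ffn_block(h1, p0)
  ref <- lapply(h1, function(h)
    gtmaloc:::ln_forward(h, p0$ln2_g, p0$ln2_b)$out)
  expect_equal(out, ref)
  out_full <- ffn_block(h1, fx$params)
  expect_true(all(vapply(out_full, function(t) all(dim(t) == c(5, 8)),
                         TRUE)))
  # first-layer ReLU output is non-negative
  pre <- sweep(h1[[1]] %*% fx$params$ffn_W1, 2, fx$params$ffn_b1, "+")
  expect_true(all(gtmaloc:::relu(pre) >= 0))
})

test_that("classification head is sigmoid-monotone with strict thresholding", {
  fx <- make_fusion_fixture()
  tok <- project_sources(fx$tabs, fx$params)
  hf <- ffn_block(mha_block(tok, fx$params, fx$heads), fx$params)
  p0 <- fx$params
  p0$cls_W <- p0$cls_W * 0
  p0$cls_b <- p0$cls_b * 0
  pred <- classify(hf, p0, threshold = 0.5)
  expect_true(all(pred$probabilities == 0.5))
  expect_true(all(pred$calls == 0))  # strict >

  pred1 <- classify(hf, fx$params)
  expect_true(all(pred1$probabilities >= 0 & pred1$probabilities <= 1))
  p_up <- fx$params
  p_up$cls_b[3] <- p_up$cls_b[3] + 1
  pred2 <- classify(hf, p_up)
  expect_true(all(pred2$probabilities[, 3] >= pred1$probabilities[, 3]))
})

test_that("fusion gradients match finite differences on a 3-miRNA micro-batch", {
  set.seed(2)
  tabs <- list(seq = matrix(rnorm(6), 3), disease = matrix(rnorm(9), 3))
  Y <- matrix(rbinom(21, 1, 0.5), 3)
  params <- gtmaloc:::fusion_init(lapply(tabs, ncol), 8L, 2L, 10L, 7L,
                                  seed = 5)
  l2 <- 1e-3
  for (use_mha in c(TRUE, FALSE)) {
    fn <- function(p) {
      fw <- gtmaloc:::fusion_forward(tabs, p, 2L, 0, FALSE, use_mha)
      gtmaloc:::fusion_loss(fw$probs, fw$logits, Y, p, names(tabs), l2)
    }
    fw <- gtmaloc:::fusion_forward(tabs, params, 2L, 0, FALSE, use_mha)
    analytic <- gtmaloc:::fusion_backward((fw$probs - Y) / 3, fw, tabs,
                                          params, 2L, l2)
    numeric <- numerical_gradient(fn, params)
    keep <- if (use_mha) names(params) else {
      setdiff(names(params),
              grep("^(H[0-9]+_|WO|bO|ln1)", names(params), value = TRUE))
    }
    expect_lt(max_rel_err(analytic[keep], numeric[keep]), 1e-4)
  }
})

test_that("training is seeded-deterministic, starts at the 7 ln 2 anchor, and fits a separable toy", {
  # labels a linear function of one informative source
  set.seed(31)
  n <- 40
  info <- matrix(rnorm(n * 4), n)
  tabs <- list(seq = matrix(rnorm(n * 4), n), disease = info)
  w_true <- matrix(rnorm(4 * 7), 4)
  Y <- (info %*% w_true > 0) * 1
  colnames(Y) <- COMPARTMENTS
  rownames(Y) <- sprintf("m%d", 1:n)
  cfg <- gtmaloc_config("fast",
                        fusion = list(width = 16L, ffn_hidden = 16L,
                                      epochs = 200L, dropout = 0,
                                      lr = 5e-3, l2 = 0))
  fit <- gtmaloc(tabs, Y, config = cfg, seed = 3)
  expect_equal(fit$loss_curve[1], 7 * log(2), tolerance = 0.15)
  expect_lt(fit$loss_curve[length(fit$loss_curve)], 0.1)

  fit2 <- gtmaloc(tabs, Y, config = cfg, seed = 3)
  expect_identical(fit$params, fit2$params)

  pred <- predict(fit, tabs)
  expect_identical(predict(fit, tabs), pred)  # deterministic inference
  expect_gt(mean((pred$probabilities > 0.5) == (Y == 1)), 0.95)
})
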