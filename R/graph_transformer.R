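# Structure-aware graph transformer: masked multi-head attention layers
# with Pre-LN and residuals, trained unsupervised on an edge-reconstruction
# loss over the functional similarity graph.  Gradients are analytic
# (hand-derived backward pass), verified against finite differences in the
# test suite.

#' Attention mask from a functional adjacency matrix
#'
#' Adds self-loops so every node attends at least to itself.
#' @param adjacency binary symmetric adjacency.
#' @return binary mask with unit diagonal.
#' @export
attention_mask <- function(adjacency) {
  m <- (adjacency > 0) * 1
  diag(m) <- 1
  m
}

gt_init_params <- function(d_in, hidden, layers, heads, seed) {
  set.seed(seed)
  p <- list(W_in = xavier(d_in, hidden) * 0.1)
  for (l in seq_len(layers)) {
    p[[sprintf("L%d_gamma", l)]] <- rep(1, hidden)
    p[[sprintf("L%d_beta", l)]] <- rep(0, hidden)
    for (k in seq_len(heads)) {
      p[[sprintf("L%d_H%d_W", l, k)]] <- xavier(hidden, hidden) * 0.1
      p[[sprintf("L%d_H%d_a1", l, k)]] <- rnorm(hidden, 0, 0.1)
      p[[sprintf("L%d_H%d_a2", l, k)]] <- rnorm(hidden, 0, 0.1)
    }
  }
  p
}

#' Masked attention weights of one head
#'
#' GAT-style logits `LeakyReLU(a^T [W h_i || W h_j])` (the spliced form
#' separates into a per-source and a per-target term), soft-maxed over the
#' masked-in neighbors of each row.  Masked-out entries are exactly zero
#' and every row sums to one.
#'
#' @param h_prev node features `[N x d]`.
#' @param W head weight matrix; `a1`, `a2` the two halves of the attention
#'   vector (source/target).
#' @param mask binary mask with unit diagonal.
#' @param slope LeakyReLU negative slope.
#' @return row-stochastic matrix `[N x N]`.
#' @export
attention_weights <- function(h_prev, W, a1, a2, mask, slope = 0.2) {
  P <- h_prev %*% W
  f <- drop(P %*% a1)
  g <- drop(P %*% a2)
  logits <- leaky_relu(outer(f, g, "+"), slope)
  masked_softmax(logits, mask)
}

masked_softmax <- function(logits, mask) {
  neg <- logits
  neg[mask == 0] <- -Inf
  m <- neg[cbind(seq_len(nrow(neg)), max.col(neg, ties.method = "first"))]
  e <- exp(neg - m)
  e[mask == 0] <- 0
  e / rowSums(e)
}

# Edge-restricted attention: only the masked-in (i, j) pairs are touched,
# so a layer costs O(E) elementwise work instead of O(N^2).  Every node
# carries a self-loop, so each row group is non-empty and rowsum() over
# the edge lists returns all N rows in order.
mask_edges <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  o <- order(idx[, 1L], idx[, 2L])
  list(i = idx[o, 1L], j = idx[o, 2L])
}

# One Pre-LN masked multi-head layer; caches everything for backward.
gt_layer_forward <- function(H, params, l, me, heads, slope) {
  ln <- ln_forward(H, params[[sprintf("L%d_gamma", l)]],
                   params[[sprintf("L%d_beta", l)]])
  Z <- ln$out
  hc <- vector("list", heads)
  acc <- 0
  for (k in seq_len(heads)) {
    W <- params[[sprintf("L%d_H%d_W", l, k)]]
    a1 <- params[[sprintf("L%d_H%d_a1", l, k)]]
    a2 <- params[[sprintf("L%d_H%d_a2", l, k)]]
    P <- Z %*% W
    f <- drop(P %*% a1)
    g <- drop(P %*% a2)
    lg <- leaky_relu(f[me$i] + g[me$j], slope)
    mx <- rowsum_max(lg, me$i)
    ex <- exp(lg - mx[me$i])
    a_e <- ex / drop(rowsum(ex, me$i))[me$i]
    M <- rowsum(a_e * P[me$j, , drop = FALSE], me$i)
    S <- elu(M)
    acc <- acc + S
    hc[[k]] <- list(P = P, pre = f[me$i] + g[me$j], a_e = a_e, M = M)
  }
  out <- H + acc / heads
  if (any(!is.finite(out))) stop("non-finite activations in layer ", l)
  list(out = out, ln = ln, Z = Z, heads = hc)
}

rowsum_max <- function(x, g) {
  # max per group; groups are 1..N, each non-empty (self-loops)
  o <- order(g, -x)
  keep <- !duplicated(g[o])
  out <- x[o][keep]
  out[order(g[o][keep])]
}

gt_layer_backward <- function(dH_next, cache, params, l, me, heads, slope,
                              grads) {
  Z <- cache$Z
  dZ <- 0
  dH <- dH_next  # residual branch
  for (k in seq_len(heads)) {
    hd <- cache$heads[[k]]
    W <- params[[sprintf("L%d_H%d_W", l, k)]]
    a1 <- params[[sprintf("L%d_H%d_a1", l, k)]]
    a2 <- params[[sprintf("L%d_H%d_a2", l, k)]]
    dM <- (dH_next / heads) * elu_grad(hd$M)
    dMi <- dM[me$i, , drop = FALSE]
    dA <- rowSums(dMi * hd$P[me$j, , drop = FALSE])
    dP <- rowsum(hd$a_e * dMi, me$j)
    s_i <- drop(rowsum(hd$a_e * dA, me$i))
    dlg <- hd$a_e * (dA - s_i[me$i])
    dpre <- dlg * leaky_relu_grad(hd$pre, slope)
    df <- drop(rowsum(dpre, me$i))
    dg <- drop(rowsum(dpre, me$j))
    grads[[sprintf("L%d_H%d_a1", l, k)]] <-
      grads[[sprintf("L%d_H%d_a1", l, k)]] + drop(crossprod(hd$P, df))
    grads[[sprintf("L%d_H%d_a2", l, k)]] <-
      grads[[sprintf("L%d_H%d_a2", l, k)]] + drop(crossprod(hd$P, dg))
    dP <- dP + outer(df, a1) + outer(dg, a2)
    grads[[sprintf("L%d_H%d_W", l, k)]] <-
      grads[[sprintf("L%d_H%d_W", l, k)]] + crossprod(Z, dP)
    dZ <- dZ + tcrossprod(dP, W)
  }
  lb <- ln_backward(dZ, cache$ln, params[[sprintf("L%d_gamma", l)]])
  grads[[sprintf("L%d_gamma", l)]] <-
    grads[[sprintf("L%d_gamma", l)]] + lb$dg
  grads[[sprintf("L%d_beta", l)]] <-
    grads[[sprintf("L%d_beta", l)]] + lb$db
  list(dH = dH + lb$dx, grads = grads)
}

gt_forward <- function(X, params, mask, layers, heads, slope) {
  me <- if (is.list(mask)) mask else mask_edges(mask)
  H <- X %*% params$W_in
  caches <- vector("list", layers)
  for (l in seq_len(layers)) {
    cl <- gt_layer_forward(H, params, l, me, heads, slope)
    caches[[l]] <- c(cl, list(H_in = H))
    H <- cl$out
  }
  list(H = H, caches = caches, me = me)
}

gt_backward <- function(dH, fw, X, params, mask, layers, heads, slope) {
  me <- fw$me
  grads <- zeros_like(params)
  for (l in rev(seq_len(layers))) {
    bk <- gt_layer_backward(dH, fw$caches[[l]], params, l, me, heads,
                            slope, grads)
    dH <- bk$dH
    grads <- bk$grads
  }
  grads$W_in <- crossprod(X, dH)
  grads
}

#' Layer forward pass of the graph transformer
#'
#' Pre-LN, K-head masked attention averaged over heads with an ELU
#' activation, and a residual connection from the layer input.  Exposed
#' for inspection and the permutation-equivariance audit.
#'
#' @param h_prev node features `[N x hidden]`.
#' @param params flat parameter list (see [train_graph_transformer()]).
#' @param l layer index.
#' @param mask binary attention mask with unit diagonal.
#' @param heads number of attention heads.
#' @param slope LeakyReLU negative slope.
#' @return updated node features `[N x hidden]`.
#' @export
layer_forward <- function(h_prev, params, l, mask, heads, slope = 0.2) {
  gt_layer_forward(h_prev, params, l, mask_edges(mask), heads, slope)$out
}

#' Structural reconstruction similarity of two embeddings
#'
#' Logistic of the dot product, in `(0, 1)`.
#' @param h_i,h_j equal-length numeric vectors.
#' @export
reconstruction_similarity <- function(h_i, h_j) {
  stopifnot(length(h_i) == length(h_j))
  sigmoid(sum(h_i * h_j))
}

#' Edge-reconstruction loss
#'
#' `-sum_{E+} log sigma(h_i . h_j) - sum_{E-} log(1 - sigma(h_i . h_j))`.
#'
#' @param H embedding matrix `[N x d]`.
#' @param samples an `edge_samples` object (see [sample_negatives()]).
#' @return non-negative scalar.
#' @export
reconstruction_loss <- function(H, samples) {
  dp <- rowSums(H[samples$pos[, 1L], , drop = FALSE] *
                  H[samples$pos[, 2L], , drop = FALSE])
  dn <- if (nrow(samples$neg) > 0L) {
    rowSums(H[samples$neg[, 1L], , drop = FALSE] *
              H[samples$neg[, 2L], , drop = FALSE])
  } else numeric(0)
  sum(softplus(-dp)) + sum(softplus(dn))
}

reconstruction_grad <- function(H, samples) {
  ep <- sigmoid(rowSums(H[samples$pos[, 1L], , drop = FALSE] *
                          H[samples$pos[, 2L], , drop = FALSE])) - 1
  en <- if (nrow(samples$neg) > 0L) {
    sigmoid(rowSums(H[samples$neg[, 1L], , drop = FALSE] *
                      H[samples$neg[, 2L], , drop = FALSE]))
  } else numeric(0)
  I <- c(samples$pos[, 1L], samples$neg[, 1L],
         samples$pos[, 2L], samples$neg[, 2L])
  J <- c(samples$pos[, 2L], samples$neg[, 2L],
         samples$pos[, 1L], samples$neg[, 1L])
  e <- c(ep, en, ep, en)
  contrib <- e * H[J, , drop = FALSE]
  agg <- rowsum(contrib, group = I)
  dH <- matrix(0, nrow(H), ncol(H))
  dH[as.integer(rownames(agg)), ] <- agg
  dH
}

#' Sample non-edges for the reconstruction loss
#'
#' Uniform without replacement over the unordered non-edges (diagonal
#' excluded).  If fewer non-edges exist than requested, all are taken with
#' a warning.
#'
#' @param adjacency binary symmetric adjacency.
#' @param ratio negatives per positive edge.
#' @param seed integer seed.
#' @return object of class `edge_samples`: integer matrices `pos`, `neg`
#'   (two columns, `i < j`).
#' @export
sample_negatives <- function(adjacency, ratio = 1, seed = 42L) {
  n <- nrow(adjacency)
  up <- upper.tri(adjacency)
  pos_idx <- which(up & adjacency > 0, arr.ind = TRUE)
  non_idx <- which(up & adjacency == 0, arr.ind = TRUE)
  want <- round(ratio * nrow(pos_idx))
  if (nrow(non_idx) < want) {
    warning("fewer non-edges (", nrow(non_idx), ") than requested (",
            want, "); sampling all", call. = FALSE)
    pick <- seq_len(nrow(non_idx))
  } else {
    set.seed(seed)
    pick <- sample.int(nrow(non_idx), want)
  }
  structure(list(pos = unname(pos_idx),
                 neg = unname(non_idx[pick, , drop = FALSE]),
                 ratio = ratio, seed = seed),
            class = "edge_samples")
}

#' Rebuild the attention mask from current embeddings
#'
#' Optional inter-layer refresh: scores are `h h^T`; each row keeps its
#' `top_k` highest-scoring partners (self excluded, ties broken by lowest
#' index), the mask is symmetrized by union and self-loops re-added.
#'
#' @param h embedding matrix.
#' @param top_k partners kept per row (< N).
#' @return binary mask with unit diagonal.
#' @export
rebuild_adjacency <- function(h, top_k) {
  n <- nrow(h)
  if (top_k >= n) stop("top_k must be smaller than the number of nodes")
  s <- tcrossprod(h)
  diag(s) <- -Inf
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    keep <- order(-s[i, ], seq_len(n))[seq_len(top_k)]
    m[i, keep] <- 1
  }
  m <- pmax(m, t(m))
  diag(m) <- 1
  m
}

#' Train the graph transformer on one feature source
#'
#' Runs `layers` Pre-LN masked multi-head attention layers over the
#' functional-similarity adjacency and optimizes the edge-reconstruction
#' loss with Adam (full batch, negatives resampled every epoch).  Returns
#' L2-normalized per-node embeddings; the training curve (epoch 0 is the
#' loss before the first update) is stored in attribute `loss_curve`.
#'
#' @param features input table `[N x d_in]` (one node2vec source).
#' @param functional_adjacency binary symmetric adjacency over the same
#'   miRNAs.
#' @param config a [gtmaloc_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return embedding matrix `[N x hidden]` with unit-norm rows.
#' @export
train_graph_transformer <- function(features, functional_adjacency,
                                    config = gtmaloc_config(),
                                    seed = config$seed) {
  cfg <- config$graph_transformer
  mask <- attention_mask(functional_adjacency)
  if (sum(functional_adjacency) == 0) {
    stop("functional adjacency has no edges; nothing to reconstruct")
  }
  params <- gt_init_params(ncol(features), cfg$hidden, cfg$layers,
                           cfg$heads, seed)
  opt <- adam_init(params)
  # the logged curve is evaluated on one fixed edge sample so successive
  # entries are comparable; training resamples negatives every epoch
  eval_samples <- sample_negatives(functional_adjacency, cfg$neg_ratio,
                                   seed * 1000L)
  curve <- numeric(cfg$epochs + 1L)
  for (ep in seq_len(cfg$epochs)) {
    samples <- sample_negatives(functional_adjacency, cfg$neg_ratio,
                                seed * 1000L + ep)
    fw <- gt_forward(features, params, mask, cfg$layers, cfg$heads,
                     cfg$leaky_slope)
    loss <- reconstruction_loss(fw$H, samples)
    if (!is.finite(loss)) {
      stop("graph transformer diverged (non-finite loss); ",
           "try a smaller learning rate")
    }
    curve[ep] <- reconstruction_loss(fw$H, eval_samples)
    dH <- reconstruction_grad(fw$H, samples)
    grads <- gt_backward(dH, fw, features, params, mask, cfg$layers,
                         cfg$heads, cfg$leaky_slope)
    st <- adam_step(opt, params, grads, cfg$lr)
    opt <- st$state
    params <- st$params
    if (isTRUE(cfg$rebuild_adjacency)) {
      mask <- rebuild_adjacency(gt_forward(features, params, mask,
                                           cfg$layers, cfg$heads,
                                           cfg$leaky_slope)$H,
                                cfg$rebuild_top_k)
    }
  }
  fw <- gt_forward(features, params, mask, cfg$layers, cfg$heads,
                   cfg$leaky_slope)
  curve[cfg$epochs + 1L] <- reconstruction_loss(fw$H, eval_samples)
  H <- fw$H
  nrm <- sqrt(rowSums(H * H))
  zero <- nrm == 0
  if (any(zero)) {
    gt_log("%d node(s) have zero embeddings after refinement", sum(zero))
    nrm[zero] <- 1
  }
  H <- H / nrm
  rownames(H) <- rownames(features)
  structure(H, loss_curve = curve)
}
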