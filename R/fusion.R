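# Multi-head attention fusion + sigmoid multi-label classification head.
# Each miRNA is a 4-token sequence (seq, mrna, drug, disease), one token
# per feature source, projected to a common width; scaled dot-product
# attention mixes the sources, a position-wise FFN refines them, and a
# linear head on the flattened tokens emits 7 localization logits.
# Backward pass is analytic and checked against finite differences.

fusion_init <- function(d_in, width, heads, ffn_hidden, n_labels, seed) {
  set.seed(seed)
  dk <- width %/% heads
  p <- list()
  for (s in names(d_in)) {
    p[[paste0("proj_", s, "_W")]] <- xavier(d_in[[s]], width)
    p[[paste0("proj_", s, "_b")]] <- rep(0, width)
  }
  for (k in seq_len(heads)) {
    p[[sprintf("H%d_WQ", k)]] <- xavier(width, dk)
    p[[sprintf("H%d_WK", k)]] <- xavier(width, dk)
    p[[sprintf("H%d_WV", k)]] <- xavier(width, dk)
  }
  p$WO <- xavier(width, width)
  p$bO <- rep(0, width)
  p$ln1_g <- rep(1, width)
  p$ln1_b <- rep(0, width)
  p$ffn_W1 <- xavier(width, ffn_hidden)
  p$ffn_b1 <- rep(0, ffn_hidden)
  p$ffn_W2 <- xavier(ffn_hidden, width)
  p$ffn_b2 <- rep(0, width)
  p$ln2_g <- rep(1, width)
  p$ln2_b <- rep(0, width)
  # small head init keeps initial logits near zero (loss starts near the
  # 7*ln(2) chance anchor) and lets the fusion trunk shape early training
  p$cls_W <- xavier(length(d_in) * width, n_labels) * 0.1
  p$cls_b <- rep(0, n_labels)
  p
}

drop_mask <- function(n, d, rate, training) {
  if (!training || rate <= 0) return(1)
  matrix((runif(n * d) >= rate) / (1 - rate), n, d)
}

# Full forward pass with caches. tables: named list of [N x d_s] matrices.
fusion_forward <- function(tables, params, heads, dropout = 0,
                           training = FALSE, use_mha = TRUE) {
  srcs <- names(tables)
  S <- length(srcs)
  N <- nrow(tables[[1L]])
  width <- length(params$bO)
  dk <- width %/% heads
  pre0 <- T0 <- vector("list", S)
  for (t in seq_len(S)) {
    pre0[[t]] <- sweep(tables[[t]] %*% params[[paste0("proj_", srcs[t], "_W")]],
                       2L, params[[paste0("proj_", srcs[t], "_b")]], "+")
    T0[[t]] <- relu(pre0[[t]])
  }
  cache <- list(srcs = srcs, S = S, N = N, width = width, dk = dk,
                pre0 = pre0, T0 = T0, use_mha = use_mha)
  if (use_mha) {
    Q <- K <- V <- A <- vector("list", heads)
    U <- lapply(seq_len(S), function(t) matrix(0, N, width))
    for (k in seq_len(heads)) {
      Q[[k]] <- lapply(T0, function(x) x %*% params[[sprintf("H%d_WQ", k)]])
      K[[k]] <- lapply(T0, function(x) x %*% params[[sprintf("H%d_WK", k)]])
      V[[k]] <- lapply(T0, function(x) x %*% params[[sprintf("H%d_WV", k)]])
      A[[k]] <- array(0, c(N, S, S))
      for (t1 in seq_len(S)) {
        sc <- vapply(seq_len(S), function(t2)
          rowSums(Q[[k]][[t1]] * K[[k]][[t2]]) / sqrt(dk), numeric(N))
        if (N == 1L) sc <- matrix(sc, 1L)
        m <- do.call(pmax, as.data.frame(sc))
        e <- exp(sc - m)
        A[[k]][, t1, ] <- e / rowSums(e)
        O_t1 <- matrix(0, N, dk)
        for (t2 in seq_len(S)) {
          O_t1 <- O_t1 + A[[k]][, t1, t2] * V[[k]][[t2]]
        }
        U[[t1]][, (k - 1L) * dk + seq_len(dk)] <- O_t1
      }
    }
    M <- D1 <- R1 <- ln1 <- H1 <- vector("list", S)
    for (t in seq_len(S)) {
      M[[t]] <- sweep(U[[t]] %*% params$WO, 2L, params$bO, "+")
      D1[[t]] <- drop_mask(N, width, dropout, training)
      R1[[t]] <- T0[[t]] + M[[t]] * D1[[t]]
      ln1[[t]] <- ln_forward(R1[[t]], params$ln1_g, params$ln1_b)
      H1[[t]] <- ln1[[t]]$out
    }
    cache <- c(cache, list(Q = Q, K = K, V = V, A = A, U = U, M = M,
                           D1 = D1, ln1 = ln1))
  } else {
    H1 <- T0
  }
  pre1 <- F1 <- F2 <- D2 <- R2 <- ln2 <- H2 <- vector("list", S)
  for (t in seq_len(S)) {
    pre1[[t]] <- sweep(H1[[t]] %*% params$ffn_W1, 2L, params$ffn_b1, "+")
    F1[[t]] <- relu(pre1[[t]])
    F2[[t]] <- sweep(F1[[t]] %*% params$ffn_W2, 2L, params$ffn_b2, "+")
    D2[[t]] <- drop_mask(N, width, dropout, training)
    R2[[t]] <- H1[[t]] + F2[[t]] * D2[[t]]
    ln2[[t]] <- ln_forward(R2[[t]], params$ln2_g, params$ln2_b)
    H2[[t]] <- ln2[[t]]$out
  }
  Z <- do.call(cbind, H2)
  logits <- sweep(Z %*% params$cls_W, 2L, params$cls_b, "+")
  c(cache, list(H1 = H1, pre1 = pre1, F1 = F1, F2 = F2, D2 = D2,
                ln2 = ln2, H2 = H2, Z = Z, logits = logits,
                probs = sigmoid(logits)))
}

fusion_backward <- function(dlogits, cache, tables, params, heads, l2 = 0) {
  srcs <- cache$srcs
  S <- cache$S
  dk <- cache$dk
  g <- zeros_like(params)
  g$cls_W <- crossprod(cache$Z, dlogits)
  g$cls_b <- colSums(dlogits)
  dZ <- tcrossprod(dlogits, params$cls_W)
  width <- cache$width
  dH1 <- vector("list", S)
  for (t in seq_len(S)) {
    dH2 <- dZ[, (t - 1L) * width + seq_len(width), drop = FALSE]
    lb <- ln_backward(dH2, cache$ln2[[t]], params$ln2_g)
    g$ln2_g <- g$ln2_g + lb$dg
    g$ln2_b <- g$ln2_b + lb$db
    dR2 <- lb$dx
    dF2 <- dR2 * cache$D2[[t]]
    g$ffn_W2 <- g$ffn_W2 + crossprod(cache$F1[[t]], dF2)
    g$ffn_b2 <- g$ffn_b2 + colSums(dF2)
    dpre1 <- tcrossprod(dF2, params$ffn_W2) * (cache$pre1[[t]] > 0)
    g$ffn_W1 <- g$ffn_W1 + crossprod(cache$H1[[t]], dpre1)
    g$ffn_b1 <- g$ffn_b1 + colSums(dpre1)
    dH1[[t]] <- dR2 + tcrossprod(dpre1, params$ffn_W1)
  }
  if (cache$use_mha) {
    dT0 <- vector("list", S)
    dU <- vector("list", S)
    for (t in seq_len(S)) {
      lb <- ln_backward(dH1[[t]], cache$ln1[[t]], params$ln1_g)
      g$ln1_g <- g$ln1_g + lb$dg
      g$ln1_b <- g$ln1_b + lb$db
      dR1 <- lb$dx
      dT0[[t]] <- dR1
      dM <- dR1 * cache$D1[[t]]
      g$bO <- g$bO + colSums(dM)
      g$WO <- g$WO + crossprod(cache$U[[t]], dM)
      dU[[t]] <- tcrossprod(dM, params$WO)
    }
    for (k in seq_len(heads)) {
      Qk <- cache$Q[[k]]
      Kk <- cache$K[[k]]
      Vk <- cache$V[[k]]
      Ak <- cache$A[[k]]
      dQ <- lapply(seq_len(S), function(t) matrix(0, cache$N, dk))
      dK <- dV <- dQ
      for (t1 in seq_len(S)) {
        dO <- dU[[t1]][, (k - 1L) * dk + seq_len(dk), drop = FALSE]
        dA <- vapply(seq_len(S), function(t2)
          rowSums(dO * Vk[[t2]]), numeric(cache$N))
        if (cache$N == 1L) dA <- matrix(dA, 1L)
        for (t2 in seq_len(S)) {
          dV[[t2]] <- dV[[t2]] + Ak[, t1, t2] * dO
        }
        blockA <- Ak[, t1, , drop = FALSE]
        dim(blockA) <- c(cache$N, S)
        dSC <- blockA * (dA - rowSums(blockA * dA))
        for (t2 in seq_len(S)) {
          dQ[[t1]] <- dQ[[t1]] + dSC[, t2] * Kk[[t2]] / sqrt(dk)
          dK[[t2]] <- dK[[t2]] + dSC[, t2] * Qk[[t1]] / sqrt(dk)
        }
      }
      for (t in seq_len(S)) {
        g[[sprintf("H%d_WQ", k)]] <- g[[sprintf("H%d_WQ", k)]] +
          crossprod(cache$T0[[t]], dQ[[t]])
        g[[sprintf("H%d_WK", k)]] <- g[[sprintf("H%d_WK", k)]] +
          crossprod(cache$T0[[t]], dK[[t]])
        g[[sprintf("H%d_WV", k)]] <- g[[sprintf("H%d_WV", k)]] +
          crossprod(cache$T0[[t]], dV[[t]])
        dT0[[t]] <- dT0[[t]] + tcrossprod(dQ[[t]], params[[sprintf("H%d_WQ", k)]]) +
          tcrossprod(dK[[t]], params[[sprintf("H%d_WK", k)]]) +
          tcrossprod(dV[[t]], params[[sprintf("H%d_WV", k)]])
      }
    }
  } else {
    dT0 <- dH1
  }
  for (t in seq_len(S)) {
    dpre0 <- dT0[[t]] * (cache$pre0[[t]] > 0)
    wname <- paste0("proj_", srcs[t], "_W")
    g[[wname]] <- g[[wname]] + crossprod(tables[[t]], dpre0) +
      2 * l2 * params[[wname]]
    g[[paste0("proj_", srcs[t], "_b")]] <-
      g[[paste0("proj_", srcs[t], "_b")]] + colSums(dpre0)
  }
  g
}

# mean-per-sample BCE (summed over the 7 labels) + L2 on projection maps
fusion_loss <- function(probs, logits, Y, params, srcs, l2) {
  n <- nrow(Y)
  bce <- sum(softplus(logits) - Y * logits) / n
  pen <- 0
  for (s in srcs) pen <- pen + sum(params[[paste0("proj_", s, "_W")]]^2)
  bce + l2 * pen
}

#' Project the per-source feature tables to tokens
#'
#' Per-source affine map plus ReLU to the common fusion width; the result
#' is the 4-token sequence (one token per source) fed to the attention
#' block.
#'
#' @param tables named list of feature matrices aligned to the registry.
#' @param params fusion parameter list (see [gtmaloc()]).
#' @return named list of `[N x width]` token matrices, in table order.
#' @export
project_sources <- function(tables, params) {
  missing_w <- setdiff(paste0("proj_", names(tables), "_W"), names(params))
  if (length(missing_w) > 0L) {
    stop("missing projection for source(s): ",
         paste(sub("^proj_(.*)_W$", "\\1", missing_w), collapse = ", "))
  }
  out <- lapply(names(tables), function(s) {
    relu(sweep(tables[[s]] %*% params[[paste0("proj_", s, "_W")]],
               2L, params[[paste0("proj_", s, "_b")]], "+"))
  })
  names(out) <- names(tables)
  out
}

#' Scaled dot-product attention of one head over the source tokens
#'
#' @param tokens named list of `[N x width]` token matrices.
#' @param params fusion parameter list.
#' @param head head index.
#' @return list with `attention` (`[N x S x S]`, rows soft-maxed over the
#'   last dimension) and `values` (list of `[N x d_k]` value matrices).
#' @export
scaled_dot_attention <- function(tokens, params, head) {
  S <- length(tokens)
  N <- nrow(tokens[[1L]])
  dk <- ncol(params[[sprintf("H%d_WQ", head)]])
  Q <- lapply(tokens, function(x) x %*% params[[sprintf("H%d_WQ", head)]])
  K <- lapply(tokens, function(x) x %*% params[[sprintf("H%d_WK", head)]])
  V <- lapply(tokens, function(x) x %*% params[[sprintf("H%d_WV", head)]])
  A <- array(0, c(N, S, S))
  for (t1 in seq_len(S)) {
    sc <- vapply(seq_len(S), function(t2)
      rowSums(Q[[t1]] * K[[t2]]) / sqrt(dk), numeric(N))
    if (N == 1L) sc <- matrix(sc, 1L)
    e <- exp(sc - do.call(pmax, as.data.frame(sc)))
    A[, t1, ] <- e / rowSums(e)
  }
  list(attention = A, values = V)
}

#' Multi-head attention block over the source tokens
#'
#' Concatenated heads, output map `W_0`, dropout (training only), residual
#' and LayerNorm.
#'
#' @inheritParams scaled_dot_attention
#' @param heads number of heads.
#' @param dropout dropout rate (applied only when `training = TRUE`).
#' @param training logical.
#' @return named list of fused token matrices `H1`.
#' @export
mha_block <- function(tokens, params, heads, dropout = 0, training = FALSE) {
  N <- nrow(tokens[[1L]])
  width <- length(params$bO)
  dk <- width %/% heads
  S <- length(tokens)
  U <- lapply(seq_len(S), function(t) matrix(0, N, width))
  for (k in seq_len(heads)) {
    att <- scaled_dot_attention(tokens, params, k)
    for (t1 in seq_len(S)) {
      O <- matrix(0, N, dk)
      for (t2 in seq_len(S)) O <- O + att$attention[, t1, t2] * att$values[[t2]]
      U[[t1]][, (k - 1L) * dk + seq_len(dk)] <- O
    }
  }
  out <- lapply(seq_len(S), function(t) {
    M <- sweep(U[[t]] %*% params$WO, 2L, params$bO, "+")
    ln_forward(tokens[[t]] + M * drop_mask(N, width, dropout, training),
               params$ln1_g, params$ln1_b)$out
  })
  names(out) <- names(tokens)
  out
}

#' Position-wise feed-forward block
#'
#' Two-layer ReLU FFN with dropout, residual and LayerNorm, applied to
#' each token independently.
#'
#' @param H1 named list of token matrices (output of [mha_block()]).
#' @inheritParams mha_block
#' @return named list of token matrices `H_fusion`.
#' @export
ffn_block <- function(H1, params, dropout = 0, training = FALSE) {
  out <- lapply(H1, function(h) {
    f <- sweep(relu(sweep(h %*% params$ffn_W1, 2L, params$ffn_b1, "+")) %*%
                 params$ffn_W2, 2L, params$ffn_b2, "+")
    ln_forward(h + f * drop_mask(nrow(h), ncol(h), dropout, training),
               params$ln2_g, params$ln2_b)$out
  })
  names(out) <- names(H1)
  out
}

#' Classification head
#'
#' Flattens the fused tokens per miRNA, applies the linear map and sigmoid,
#' and binarizes with a strict `>` threshold.
#'
#' @param H_fusion named list of fused token matrices.
#' @param params fusion parameter list.
#' @param threshold probability threshold (default 0.5).
#' @return object of class `gtmaloc_prediction`: `probabilities` and
#'   binary `calls` (`[N x 7]`), plus the threshold.
#' @export
classify <- function(H_fusion, params, threshold = 0.5) {
  Z <- do.call(cbind, H_fusion)
  probs <- sigmoid(sweep(Z %*% params$cls_W, 2L, params$cls_b, "+"))
  colnames(probs) <- COMPARTMENTS[seq_len(ncol(probs))]
  rownames(probs) <- rownames(H_fusion[[1L]])
  structure(list(probabilities = probs,
                 calls = (probs > threshold) * 1L,
                 threshold = threshold),
            class = "gtmaloc_prediction")
}

#' @export
print.gtmaloc_prediction <- function(x, ...) {
  cat("gtmaloc prediction:", nrow(x$probabilities), "miRNAs x",
      ncol(x$probabilities), "compartments (threshold",
      x$threshold, ")\n")
  cat("calls per compartment:\n")
  print(colSums(x$calls))
  invisible(x)
}
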