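# Independent oracles and small fixture builders shared across tests.

# ---- exhaustive local-alignment oracle (matching enumeration, not DP) ----
# A local alignment is an order-preserving matching between a substring of
# each sequence: choose k positions in each (k >= 1), pair them in order,
# score matched pairs and penalize the skipped positions between the first
# and last chosen index on each side.  Enumerating all position subsets is
# exhaustive and shares nothing with the dynamic-programming scorer.

oracle_combs <- function(max_len) {
  lapply(seq_len(max_len), function(l) lapply(seq_len(l), function(k) {
    m <- utils::combn(l, k)
    if (k == 1L) m <- matrix(m, 1L)
    m
  }))
}

# binary position-code matrices for a 2-letter alphabet sequence
oracle_prep <- function(s, combs, one = "C") {
  x <- as.numeric(strsplit(s, "")[[1L]] == one)
  lapply(seq_along(x), function(k) {
    Ia <- combs[[length(x)]][[k]]
    X <- matrix(x[Ia], k)
    list(X = X, cs = colSums(X), gap = Ia[k, ] - Ia[1L, ] + 1L - k)
  })
}

oracle_local_score <- function(pa, pb, match = 1, mismatch = -1, gap = -1) {
  best <- 0
  for (k in seq_len(min(length(pa), length(pb)))) {
    A <- pa[[k]]
    B <- pb[[k]]
    H <- outer(A$cs, B$cs, "+") - 2 * crossprod(A$X, B$X)
    sc <- (k - H) * match + H * mismatch + gap * outer(A$gap, B$gap, "+")
    m <- max(sc)
    if (m > best) best <- m
  }
  best
}

# general (any alphabet) slow variant for spot checks
oracle_local_score_general <- function(a, b, match = 1, mismatch = -1,
                                       gap = -1) {
  xa <- strsplit(a, "")[[1L]]
  xb <- strsplit(b, "")[[1L]]
  best <- 0
  for (k in seq_len(min(length(xa), length(xb)))) {
    Ia <- utils::combn(length(xa), k)
    Ib <- utils::combn(length(xb), k)
    if (k == 1L) {
      Ia <- matrix(Ia, 1L)
      Ib <- matrix(Ib, 1L)
    }
    for (u in seq_len(ncol(Ia))) {
      for (v in seq_len(ncol(Ib))) {
        nm <- sum(xa[Ia[, u]] == xb[Ib[, v]])
        sc <- nm * match + (k - nm) * mismatch +
          gap * ((Ia[k, u] - Ia[1L, u] + 1L - k) +
                   (Ib[k, v] - Ib[1L, v] + 1L - k))
        if (sc > best) best <- sc
      }
    }
  }
  best
}

# ---- brute-force threshold-sweep metric oracles ----

brute_roc_auc <- function(scores, labels) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  if (length(pos) == 0L || length(neg) == 0L) return(NaN)
  tot <- 0
  for (i in pos) {
    for (j in neg) {
      tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  tot / (length(pos) * length(neg))
}

brute_pr_auc <- function(scores, labels) {
  np <- sum(labels == 1)
  if (np == 0L) return(NaN)
  ths <- sort(unique(scores), decreasing = TRUE)
  rec_prev <- 0
  ap <- 0
  for (t in ths) {
    sel <- scores >= t
    prec <- sum(labels[sel] == 1) / sum(sel)
    rec <- sum(labels[sel] == 1) / np
    ap <- ap + (rec - rec_prev) * prec
    rec_prev <- rec
  }
  ap
}

# ---- numerical gradient helper ----

numerical_gradient <- function(fn, params, eps = 1e-5) {
  g <- lapply(params, function(p) p * 0)
  for (nm in names(params)) {
    for (i in seq_along(params[[nm]])) {
      p1 <- params
      p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- params
      p2[[nm]][i] <- p2[[nm]][i] - eps
      g[[nm]][i] <- (fn(p1) - fn(p2)) / (2 * eps)
    }
  }
  g
}

max_rel_err <- function(analytic, numeric) {
  a <- unlist(analytic)
  b <- unlist(numeric)
  max(abs(a - b)) / max(abs(b), 1e-8)
}

# ---- small graph/dataset fixtures ----

# planted two-block undirected graph; returns adjacency + block labels
planted_blocks <- function(n, p_in, p_out, seed) {
  set.seed(seed)
  block <- rep(1:2, each = n %/% 2)
  pm <- ifelse(outer(block, block, "=="), p_in, p_out)
  up <- upper.tri(pm)
  adj <- matrix(0, n, n)
  adj[up] <- (runif(sum(up)) < pm[up]) * 1
  adj <- adj + t(adj)
  rownames(adj) <- colnames(adj) <- sprintf("n%03d", seq_len(n))
  list(adj = adj, block = block)
}

# tiny full dataset for integration-style tests
tiny_dataset <- function(seed = 7, n = 60) {
  model <- planted_model(n_mirna = n, n_disease = 24L, n_drug = 16L,
                         n_mrna = 40L, seed = seed)
  generate_dataset(model)
}

tiny_config <- function(...) {
  gtmaloc_config("fast",
                 node2vec = list(walk_length = 20L, num_walks = 3L,
                                 epochs = 2L),
                 graph_transformer = list(epochs = 30L, hidden = 16L),
                 fusion = list(width = 32L, ffn_hidden = 32L,
                               epochs = 40L),
                 ...)
}

# chain DAG fixture: d -> p -> r  (child -> parent edges)
chain_dag <- function() {
  disease_dag(data.frame(child = c("d", "p"), parent = c("p", "r")))
}

# diamond DAG fixture: d -> {p1, p2} -> r
diamond_dag <- function() {
  disease_dag(data.frame(child = c("d", "d", "p1", "p2"),
                         parent = c("p1", "p2", "r", "r")))
}
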