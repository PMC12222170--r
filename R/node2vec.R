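# node2vec: (p,q)-biased random walks + skip-gram with negative sampling.
# Walk generation and skip-gram training run in compiled code,
# single-threaded, so a seed gives bit-reproducible embeddings.

#' Build a walkable graph from a weighted adjacency matrix
#'
#' Nodes are the matrix rows; edges are the non-zero off-diagonal entries,
#' used as first-order transition weights.
#'
#' @param adj symmetric non-negative matrix with dimnames.
#' @return object of class `walk_graph` (CSR neighbor lists).
#' @export
graph_from_adjacency <- function(adj) {
  n <- nrow(adj)
  if (is.null(n) || n == 0L) stop("empty graph")
  diag(adj) <- 0
  nbr <- vector("list", n)
  wt <- vector("list", n)
  for (i in seq_len(n)) {
    js <- which(adj[i, ] > 0)
    nbr[[i]] <- js - 1L
    wt[[i]] <- adj[i, js]
  }
  deg <- lengths(nbr)
  structure(list(n = n,
                 indptr = c(0L, cumsum(deg)),
                 nbr = as.integer(unlist(nbr, use.names = FALSE)),
                 wt = as.numeric(unlist(wt, use.names = FALSE)),
                 node_ids = rownames(adj)),
            class = "walk_graph")
}

#' Build a walkable graph from a bipartite association matrix
#'
#' miRNA rows and entity columns become one node set (miRNAs first, in
#' registry order), with unweighted edges for each association, so walks
#' traverse multi-hop miRNA-entity-miRNA paths.
#'
#' @param assoc binary miRNA x entity matrix with dimnames.
#' @return a `walk_graph`; miRNA nodes are the first `nrow(assoc)` nodes.
#' @export
graph_from_bipartite <- function(assoc) {
  n <- nrow(assoc)
  m <- ncol(assoc)
  if (n + m == 0L) stop("empty graph")
  full <- matrix(0, n + m, n + m)
  full[seq_len(n), n + seq_len(m)] <- assoc
  full[n + seq_len(m), seq_len(n)] <- t(assoc)
  rownames(full) <- c(rownames(assoc), colnames(assoc))
  g <- graph_from_adjacency(full)
  g$n_mirna <- n
  g
}

#' Second-order node2vec transition distribution
#'
#' Unnormalized weight of moving to neighbor `x` of `cur` given the walk
#' came from `prev`: `w(cur, x) * alpha` with `alpha = 1/p` for returning
#' to `prev`, 1 when `x` is adjacent to `prev`, `1/q` otherwise.
#'
#' @param prev,cur node indices (1-based); `prev` adjacent to `cur`.
#' @param graph a `walk_graph`.
#' @param p return parameter. @param q in-out parameter.
#' @return named probability vector over the neighbors of `cur` (empty if
#'   `cur` has none).
#' @export
second_order_transition <- function(prev, cur, graph, p = 1, q = 1) {
  lo <- graph$indptr[cur] + 1L
  hi <- graph$indptr[cur + 1L]
  if (hi < lo) return(numeric(0))
  nbrs <- graph$nbr[lo:hi] + 1L
  w <- graph$wt[lo:hi]
  plo <- graph$indptr[prev] + 1L
  phi <- graph$indptr[prev + 1L]
  prev_nbrs <- if (phi < plo) integer(0) else graph$nbr[plo:phi] + 1L
  alpha <- ifelse(nbrs == prev, 1 / p,
                  ifelse(nbrs %in% prev_nbrs, 1, 1 / q))
  out <- w * alpha
  out <- out / sum(out)
  names(out) <- if (is.null(graph$node_ids)) nbrs else graph$node_ids[nbrs]
  out
}

#' Generate a node2vec walk corpus
#'
#' `num_walks` passes over all nodes (shuffled each pass); the first step
#' of every walk is first-order weight-proportional, later steps apply the
#' `(p, q)` bias.  Isolated nodes emit length-1 walks.  Deterministic for
#' a given seed.
#'
#' @param graph a `walk_graph`.
#' @param p,q node2vec bias parameters.
#' @param walk_length maximum walk length in nodes.
#' @param num_walks walks started per node.
#' @param seed integer seed.
#' @return object of class `walk_corpus`: integer matrix `walks`
#'   (1-based node ids, NA padded) plus the parameters.
#' @export
generate_walks <- function(graph, p = 1, q = 1, walk_length = 80L,
                           num_walks = 10L, seed = 42L) {
  if (graph$n == 0L) stop("empty graph")
  w <- .node2vec_walks_cpp(graph$indptr, graph$nbr, graph$wt, graph$n,
                           p, q, as.integer(walk_length),
                           as.integer(num_walks), as.integer(seed))
  w[w < 0L] <- NA_integer_
  structure(list(walks = w + 1L, n_nodes = graph$n,
                 params = list(p = p, q = q, walk_length = walk_length,
                               num_walks = num_walks, seed = seed)),
            class = "walk_corpus")
}

#' Train skip-gram embeddings on a walk corpus
#'
#' Skip-gram with negative sampling, single-threaded and deterministic for
#' a given seed.  Nodes that never co-occur with a context (isolated
#' nodes) keep near-zero vectors.
#'
#' @param corpus a `walk_corpus`.
#' @param d embedding dimension.
#' @param window context window size.
#' @param epochs training passes over the corpus.
#' @param negative negatives per positive pair.
#' @param seed integer seed.
#' @param alpha initial learning rate.
#' @return numeric matrix `[n_nodes x d]`.
#' @export
train_skipgram <- function(corpus, d, window = 10L, epochs = 5L,
                           negative = 5L, seed = 42L, alpha = 0.025) {
  if (d <= 0) stop("embedding dimension must be positive")
  if (nrow(corpus$walks) == 0L) stop("empty walk corpus")
  w <- corpus$walks - 1L
  w[is.na(w)] <- -1L
  .skipgram_cpp(w, corpus$n_nodes, as.integer(d), as.integer(window),
                as.integer(epochs), as.integer(negative), alpha,
                as.integer(seed))
}

# node2vec on one graph; returns rows for the first n_keep nodes
node2vec_embed <- function(graph, d, cfg_n2v, seed, n_keep = graph$n) {
  corpus <- generate_walks(graph, cfg_n2v$p, cfg_n2v$q, cfg_n2v$walk_length,
                           cfg_n2v$num_walks, seed)
  emb <- train_skipgram(corpus, d, cfg_n2v$window, cfg_n2v$epochs,
                        cfg_n2v$negative, seed)
  deg <- diff(graph$indptr)
  isolated <- which(deg == 0L & seq_len(graph$n) <= n_keep)
  if (length(isolated) > 0L) {
    emb[isolated, ] <- 0
    gt_log("%d node(s) have no edges; their embeddings are zero vectors",
           length(isolated))
  }
  out <- emb[seq_len(n_keep), , drop = FALSE]
  rownames(out) <- graph$node_ids[seq_len(n_keep)]
  out
}

#' Embed all four miRNA networks with node2vec
#'
#' Sequence similarity network at `dim_seq` (64 by default), the three
#' bipartite association networks at `dim_assoc` (128): the dimension
#' policy trades fine-grained sequence patterns against the higher
#' capacity needed for multi-hop association structure.  Only the miRNA
#' rows of the bipartite graphs are retained.
#'
#' @param seq_net weighted sequence similarity matrix.
#' @param assoc_nets named list of binary association matrices
#'   (`mrna`, `drug`, `disease`).
#' @param config a [gtmaloc_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return named list of embedding tables
#'   (`seq`, `mrna`, `drug`, `disease`), one row per registry miRNA.
#' @export
embed_all_networks <- function(seq_net, assoc_nets, config = gtmaloc_config(),
                               seed = config$seed) {
  cfg <- config$node2vec
  out <- list()
  g <- graph_from_adjacency(seq_net)
  out$seq <- node2vec_embed(g, cfg$dim_seq, cfg, seed)
  for (k in names(assoc_nets)) {
    g <- graph_from_bipartite(assoc_nets[[k]])
    out[[k]] <- node2vec_embed(g, cfg$dim_assoc, cfg,
                               seed + match(k, names(assoc_nets)),
                               n_keep = g$n_mirna)
  }
  out
}
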