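# Disease DAG semantics: depth-discounted ancestor contributions,
# semantic values, Wang-style pairwise overlap, and the best-match-average
# functional similarity between miRNA disease sets.

#' Build a disease DAG from child -> parent edges
#'
#' Precomputes, for every disease, its ancestor closure `S(d)` (the disease
#' itself plus everything reachable via parent edges) together with the
#' shortest ancestor-path length in edges.  The hierarchical depth used by
#' the contribution formula is `edges + 1`, so `Depth(d, d) = 1`.
#'
#' @param edges data frame (or 2-column matrix) of `child`, `parent`
#'   identifier pairs.
#' @param nodes optional full node set (to include isolated diseases).
#' @return object of class `disease_dag`.
#' @export
disease_dag <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop("edges must have child and parent columns")
  child <- as.character(edges[[1L]])
  parent <- as.character(edges[[2L]])
  all_nodes <- unique(c(child, parent, as.character(nodes)))
  parents_of <- split(parent, factor(child, levels = all_nodes))

  # BFS up the parent edges; also an acyclicity check (a node reappearing
  # at a later depth on its own upward closure is fine, but reaching the
  # start node again is a cycle).
  anc <- vector("list", length(all_nodes))
  names(anc) <- all_nodes
  for (d in all_nodes) {
    depth <- c(0L)
    names(depth) <- d
    frontier <- d
    lvl <- 0L
    while (length(frontier) > 0L) {
      lvl <- lvl + 1L
      if (lvl > length(all_nodes)) stop("cycle detected in disease DAG")
      nxt <- unique(unlist(parents_of[frontier], use.names = FALSE))
      nxt <- nxt[!nxt %in% names(depth)]
      if (d %in% unlist(parents_of[frontier], use.names = FALSE)) {
        stop("cycle detected in disease DAG at node ", d)
      }
      if (length(nxt) > 0L) {
        add <- rep(lvl, length(nxt))
        names(add) <- nxt
        depth <- c(depth, add)
      }
      frontier <- nxt
    }
    anc[[d]] <- depth
  }
  structure(list(nodes = all_nodes, edges = data.frame(child = child,
                                                       parent = parent),
                 ancestors = anc),
            class = "disease_dag")
}

#' @export
print.disease_dag <- function(x, ...) {
  cat("disease DAG:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Depth-discounted contribution of an ancestor disease
#'
#' `C(d_t, d_i) = a / Depth(d_t, d_i)` where the depth is the shortest
#' ancestor-path length in edges plus one (`Depth(d, d) = 1`).
#'
#' @param dag a [disease_dag()].
#' @param d_t ancestor (or self) of `d_i`.
#' @param d_i query disease.
#' @param a adjustment parameter (default 0.5).
#' @return contribution in `(0, a]`.
#' @export
disease_contribution <- function(dag, d_t, d_i, a = 0.5) {
  depth <- dag$ancestors[[d_i]][d_t]
  if (is.null(dag$ancestors[[d_i]]) || is.na(depth)) {
    stop(d_t, " is not an ancestor-or-self of ", d_i)
  }
  unname(a / (depth + 1))
}

#' Semantic value of a disease
#'
#' Sum of the depth-discounted contributions over the ancestor closure.
#'
#' @inheritParams disease_contribution
#' @return semantic value, at least `a`.
#' @export
semantic_value <- function(dag, d_i, a = 0.5) {
  depths <- dag$ancestors[[d_i]]
  if (is.null(depths)) stop("unknown disease: ", d_i)
  sum(a / (depths + 1))
}

#' Semantic similarity between two diseases
#'
#' Wang-style overlap: shared-ancestor contributions from both sides over
#' the sum of the two semantic values.  1 for identical diseases, 0 for
#' disjoint ancestries.
#'
#' @inheritParams disease_contribution
#' @param d_j second disease.
#' @return similarity in `[0, 1]`.
#' @export
disease_pair_similarity <- function(dag, d_i, d_j, a = 0.5) {
  di <- dag$ancestors[[d_i]]
  dj <- dag$ancestors[[d_j]]
  if (is.null(di) || is.null(dj)) stop("unknown disease")
  shared <- intersect(names(di), names(dj))
  if (length(shared) == 0L) return(0)
  num <- sum(a / (di[shared] + 1)) + sum(a / (dj[shared] + 1))
  num / (sum(a / (di + 1)) + sum(a / (dj + 1)))
}

#' miRNA functional similarity from disease sets
#'
#' Symmetric best-match-average of pairwise disease semantic similarities:
#' each disease of one miRNA is matched to its most similar disease of the
#' other, and the matched similarities are averaged over both directions.
#' The similarity is 0 when either disease set is empty and 1 between
#' miRNAs with identical non-empty sets.
#'
#' @param dag a [disease_dag()].
#' @param disease_sets named list mapping each miRNA to a character vector
#'   of associated diseases (possibly empty).
#' @param a adjustment parameter.
#' @return symmetric similarity matrix (`kind = "functional_raw"`).
#' @export
functional_similarity <- function(dag, disease_sets, a = 0.5) {
  n <- length(disease_sets)
  used <- unique(unlist(disease_sets, use.names = FALSE))
  used <- used[used %in% dag$nodes]
  nd <- length(used)
  simd <- matrix(0, nd, nd, dimnames = list(used, used))
  if (nd > 0L) {
    for (i in seq_len(nd)) {
      simd[i, i] <- 1
      for (j in seq_len(i - 1L)) {
        s <- disease_pair_similarity(dag, used[i], used[j], a)
        simd[i, j] <- s
        simd[j, i] <- s
      }
    }
  }
  sets <- lapply(disease_sets, function(d) intersect(d, used))
  fs <- matrix(0, n, n, dimnames = list(names(disease_sets),
                                        names(disease_sets)))
  for (i in seq_len(n)) {
    d1 <- sets[[i]]
    if (length(d1) == 0L) next
    fs[i, i] <- 1
    for (j in seq_len(i - 1L)) {
      d2 <- sets[[j]]
      if (length(d2) == 0L) next
      block <- simd[d1, d2, drop = FALSE]
      v <- (sum(apply(block, 1L, max)) + sum(apply(block, 2L, max))) /
        (length(d1) + length(d2))
      fs[i, j] <- v
      fs[j, i] <- v
    }
  }
  structure(fs, kind = "functional_raw")
}
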