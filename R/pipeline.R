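# Pipeline assembly: networks -> node2vec embeddings -> graph-transformer
# refinement.  The whole stage is transductive (it uses graph structure of
# all miRNAs, never labels); only the supervised fusion stage respects
# cross-validation fold boundaries.

#' Build the five miRNA networks from a dataset bundle
#'
#' Sequence similarity (weighted, unit diagonal), raw functional
#' similarity from disease semantics, GIP kernel over disease profiles,
#' their lambda-fusion, and the thresholded functional adjacency.
#'
#' @param dataset a `mirna_dataset` (see [load_dataset()] /
#'   [generate_dataset()]).
#' @param config a [gtmaloc_config()].
#' @return list with `seq_sim`, `fs_raw`, `gip`, `fs_fused`, `adjacency`
#'   and the three bipartite `assoc` matrices.
#' @export
build_networks <- function(dataset, config = gtmaloc_config()) {
  scheme <- do.call(scoring_scheme, config$scoring)
  seq_sim <- build_sequence_network(dataset$sequences, scheme)
  disease_sets <- apply(dataset$assoc$disease, 1L, function(r)
    colnames(dataset$assoc$disease)[r == 1], simplify = FALSE)
  fs_raw <- functional_similarity(dataset$dag, disease_sets,
                                  config$semantic_a)
  gip <- gip_kernel(dataset$assoc$disease)
  fs_fused <- fuse_similarity(fs_raw, gip, config$lambda)
  adjacency <- binarize(fs_fused, config$threshold)
  list(seq_sim = seq_sim, fs_raw = fs_raw, gip = gip, fs_fused = fs_fused,
       adjacency = adjacency, assoc = dataset$assoc)
}

#' Prepare all per-source feature tables for the classifier
#'
#' Builds the networks, embeds the four feature networks with node2vec
#' (64-d sequence, 128-d associations by default) and, unless disabled,
#' refines each source with the graph transformer over the functional
#' adjacency.  Everything here is unsupervised and built once per run.
#'
#' @param dataset a `mirna_dataset`.
#' @param config a [gtmaloc_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return object of class `gtmaloc_features`: `networks`, `tokens_raw`
#'   (node2vec tables), `tokens` (refined tables, or the raw ones when the
#'   graph transformer is disabled), `labels`, `registry`, `config`.
#' @export
gtmaloc_features <- function(dataset, config = gtmaloc_config(),
                             seed = config$seed) {
  networks <- build_networks(dataset, config)
  gt_verbose("networks built (functional adjacency: %d edges)",
             sum(networks$adjacency) / 2)
  tokens_raw <- embed_all_networks(networks$seq_sim, networks$assoc,
                                   config, seed)
  if (isTRUE(config$graph_transformer$enabled)) {
    if (sum(networks$adjacency) == 0) {
      gt_log(paste("functional adjacency has no edges;",
                   "skipping graph-transformer refinement"))
      tokens <- tokens_raw
    } else {
      tokens <- lapply(seq_along(tokens_raw), function(i) {
        gt_verbose("refining source '%s'", names(tokens_raw)[i])
        train_graph_transformer(tokens_raw[[i]], networks$adjacency,
                                config, seed + 100L * i)
      })
      names(tokens) <- names(tokens_raw)
    }
  } else {
    tokens <- tokens_raw
  }
  structure(list(networks = networks, tokens_raw = tokens_raw,
                 tokens = tokens, labels = dataset$labels,
                 registry = dataset$registry, config = config, seed = seed),
            class = "gtmaloc_features")
}

#' @export
print.gtmaloc_features <- function(x, ...) {
  cat("gtmaloc feature bundle:", length(x$registry$ids), "miRNAs\n")
  cat("  sources:", paste(names(x$tokens), collapse = ", "), "\n")
  cat("  dims:", paste(vapply(x$tokens, ncol, 0L), collapse = "/"),
      "(refined)", paste(vapply(x$tokens_raw, ncol, 0L), collapse = "/"),
      "(node2vec)\n")
  cat("  functional adjacency edges:", sum(x$networks$adjacency) / 2, "\n")
  invisible(x)
}
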