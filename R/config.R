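#' Run configuration
#'
#' Collects every tunable of the pipeline with its default, serializable to
#' and from YAML.  Defaults follow the published setting where one is stated
#' (fusion weight `lambda = 0.5`, binarization threshold `threshold = 0.6`,
#' embedding dimensions 64/128, 4 attention heads, classification threshold
#' 0.5) and standard conventions elsewhere (node2vec p = q = 1, walk length
#' 80, 10 walks per node, window 10; graph transformer with 2 Pre-LN layers;
#' Adam at 1e-3).
#'
#' The `"fast"` preset shrinks the stochastic training stages (shorter
#' walks, 32-d transformer, 64-d fusion width, fewer epochs) for test-suite
#' and demonstration work at n of a few hundred miRNAs; the model family is
#' unchanged.
#'
#' @param preset `"default"` or `"fast"`.
#' @param ... named overrides of top-level sections, e.g.
#'   `node2vec = list(num_walks = 5)`; merged recursively.
#' @return A nested list of class `gtmaloc_config`.
#' @export
gtmaloc_config <- function(preset = c("default", "fast"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    seed = 42L,
    scoring = list(match = 1, mismatch = -1, gap = -1),
    semantic_a = 0.5,
    lambda = 0.5,
    threshold = 0.6,
    node2vec = list(p = 1, q = 1, walk_length = 80L, num_walks = 10L,
                    window = 10L, epochs = 5L, negative = 5L, alpha = 0.025,
                    dim_seq = 64L, dim_assoc = 128L),
    graph_transformer = list(enabled = TRUE, layers = 2L, hidden = 128L,
                             heads = 4L, leaky_slope = 0.2, lr = 1e-3,
                             epochs = 200L, neg_ratio = 1,
                             rebuild_adjacency = FALSE, rebuild_top_k = 10L),
    fusion = list(width = 128L, heads = 4L, ffn_hidden = 256L,
                  dropout = 0.1, lr = 1e-3, epochs = 300L, l2 = 1e-4,
                  threshold = 0.5, use_mha = TRUE)
  )
  if (preset == "fast") {
    cfg$node2vec <- modifyList(cfg$node2vec, list(
      walk_length = 40L, num_walks = 5L, window = 5L, epochs = 3L))
    cfg$graph_transformer <- modifyList(cfg$graph_transformer, list(
      hidden = 32L, epochs = 80L))
    cfg$fusion <- modifyList(cfg$fusion, list(
      width = 64L, ffn_hidden = 128L, epochs = 120L))
  }
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      cfg[[nm]] <- modifyList(cfg[[nm]], over[[nm]])
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  stopifnot(cfg$lambda >= 0, cfg$lambda <= 1,
            cfg$threshold >= 0, cfg$threshold <= 1,
            cfg$fusion$width %% cfg$fusion$heads == 0)
  structure(cfg, class = "gtmaloc_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path file path.
#' @return `read_config()` returns a `gtmaloc_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(gtmaloc_config, c(list(preset = "default"), raw))
}

#' @rdname read_config
#' @param config a `gtmaloc_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
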