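# The fitting front end: gtmaloc() trains the multi-head attention fusion
# classifier on prepared per-source feature tables and returns a classed
# model object with predict/print/summary/plot methods.

#' Fit the miRNA localization fusion classifier
#'
#' Trains the multi-head attention fusion block and the sigmoid
#' classification head on the supplied per-source feature tables with
#' full-batch Adam, minimizing mean per-sample binary cross-entropy over
#' the 7 compartments plus an L2 penalty on the source projection maps.
#' Feature construction (networks, node2vec, graph transformer) happens
#' upstream in [gtmaloc_features()]; this function only ever sees the rows
#' in `train_index`, so cross-validation folds stay leakage-free at the
#' supervised stage.
#'
#' @param features named list of per-source feature matrices (all with the
#'   same rows, aligned to the registry), e.g. the `tokens` element of a
#'   [gtmaloc_features()] object.
#' @param labels binary label matrix `[N x 7]` in [COMPARTMENTS] order.
#' @param train_index integer rows used for training (default: all rows).
#' @param config a [gtmaloc_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return object of class `gtmaloc` with elements `params`, `sources`,
#'   `loss_curve`, `config`, `train_index`, `threshold`.
#' @seealso [predict.gtmaloc()], [cross_validate()]
#' @examples
#' model <- planted_model(n_mirna = 60, n_disease = 20, n_drug = 10,
#'                        n_mrna = 30, seed = 7)
#' ds <- generate_dataset(model)
#' cfg <- gtmaloc_config("fast",
#'                       graph_transformer = list(enabled = FALSE),
#'                       fusion = list(epochs = 30L))
#' feats <- gtmaloc_features(ds, cfg)
#' fit <- gtmaloc(feats$tokens, ds$labels, config = cfg)
#' predict(fit, feats$tokens)
#' @export
gtmaloc <- function(features, labels, train_index = NULL,
                    config = gtmaloc_config(), seed = config$seed) {
  cfg <- config$fusion
  stopifnot(is.list(features), length(features) >= 1L)
  n <- nrow(features[[1L]])
  if (is.null(train_index)) train_index <- seq_len(n)
  if (nrow(labels) != n) stop("labels and features disagree on row count")
  d_in <- lapply(features, ncol)
  params <- fusion_init(d_in, cfg$width, cfg$heads, cfg$ffn_hidden,
                        ncol(labels), seed)
  opt <- adam_init(params)
  Xtr <- lapply(features, function(f) f[train_index, , drop = FALSE])
  Ytr <- labels[train_index, , drop = FALSE]
  curve <- numeric(cfg$epochs)
  set.seed(seed + 1L)  # dropout stream
  for (ep in seq_len(cfg$epochs)) {
    fw <- fusion_forward(Xtr, params, cfg$heads, cfg$dropout,
                         training = TRUE, use_mha = isTRUE(cfg$use_mha))
    curve[ep] <- fusion_loss(fw$probs, fw$logits, Ytr, params,
                             names(features), cfg$l2)
    if (!is.finite(curve[ep])) {
      stop("fusion training diverged (non-finite loss) at epoch ", ep)
    }
    dlogits <- (fw$probs - Ytr) / nrow(Ytr)
    grads <- fusion_backward(dlogits, fw, Xtr, params, cfg$heads, cfg$l2)
    st <- adam_step(opt, params, grads, cfg$lr)
    opt <- st$state
    params <- st$params
  }
  structure(list(params = params, sources = names(features),
                 loss_curve = curve, config = config, seed = seed,
                 train_index = train_index, threshold = cfg$threshold,
                 compartments = colnames(labels)),
            class = "gtmaloc")
}

#' Predict localization probabilities from a fitted model
#'
#' Deterministic inference pass (dropout disabled); probabilities are
#' binarized with a strict `>` threshold.
#'
#' @param object a fitted [gtmaloc()] model.
#' @param features named list of per-source feature matrices with the same
#'   sources the model was trained on.
#' @param rows optional row subset to score.
#' @param ... unused.
#' @return a `gtmaloc_prediction` (probabilities, calls, threshold).
#' @export
predict.gtmaloc <- function(object, features, rows = NULL, ...) {
  if (!setequal(names(features), object$sources)) {
    stop("feature sources differ from the fitted model (",
         paste(object$sources, collapse = ", "), ")")
  }
  features <- features[object$sources]
  if (!is.null(rows)) {
    features <- lapply(features, function(f) f[rows, , drop = FALSE])
  }
  fw <- fusion_forward(features, object$params,
                       object$config$fusion$heads, 0, training = FALSE,
                       use_mha = isTRUE(object$config$fusion$use_mha))
  probs <- fw$probs
  dimnames(probs) <- list(rownames(features[[1L]]), object$compartments)
  structure(list(probabilities = probs,
                 calls = (probs > object$threshold) * 1L,
                 threshold = object$threshold),
            class = "gtmaloc_prediction")
}

#' @export
print.gtmaloc <- function(x, ...) {
  cat("gtmaloc fusion classifier\n")
  cat("  sources:", paste(x$sources, collapse = ", "), "\n")
  cat("  fusion width:", x$config$fusion$width,
      "| heads:", x$config$fusion$heads,
      "| MHA:", isTRUE(x$config$fusion$use_mha), "\n")
  cat("  trained on", length(x$train_index), "miRNAs for",
      length(x$loss_curve), "epochs; final loss",
      format(x$loss_curve[length(x$loss_curve)], digits = 4), "\n")
  invisible(x)
}

#' @export
summary.gtmaloc <- function(object, ...) {
  n_par <- sum(vapply(object$params, length, 0L))
  cat("gtmaloc fusion classifier\n")
  cat("  sources:         ", paste(object$sources, collapse = ", "), "\n")
  cat("  parameters:      ", n_par, "\n")
  cat("  epochs:          ", length(object$loss_curve), "\n")
  cat("  initial loss:    ", format(object$loss_curve[1L], digits = 5), "\n")
  cat("  final loss:      ",
      format(object$loss_curve[length(object$loss_curve)], digits = 5), "\n")
  cat("  call threshold:  ", object$threshold, "\n")
  invisible(object)
}

#' Plot the training loss curve of a fitted model
#'
#' @param x a fitted [gtmaloc()] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gtmaloc <- function(x, ...) {
  graphics::plot(seq_along(x$loss_curve), x$loss_curve, type = "l",
                 xlab = "epoch", ylab = "training loss",
                 main = "gtmaloc fusion training", ...)
  invisible(x)
}
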