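# Evaluation: k-fold cross-validation with per-class AUC/AUPR, ablation
# runner, attention-head study, per-compartment ranking.

#' k-fold split
#'
#' Seeded shuffle followed by contiguous chunking (no stratification);
#' fold sizes differ by at most one.
#'
#' @param n number of items.
#' @param k number of folds (`2 <= k <= n`).
#' @param seed integer seed.
#' @return object of class `fold_split`: list of test index vectors.
#' @export
kfold_split <- function(n, k, seed = 42L) {
  if (k > n) stop("k must not exceed n")
  if (k < 2L) stop("k must be at least 2")
  set.seed(seed)
  perm <- sample.int(n)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  ends <- cumsum(sizes)
  folds <- lapply(seq_len(k), function(i) {
    sort(perm[(ends[i] - sizes[i] + 1L):ends[i]])
  })
  structure(list(k = k, folds = folds, seed = seed), class = "fold_split")
}

#' Area under the ROC curve
#'
#' Mann-Whitney form: the probability that a random positive outscores a
#' random negative, ties counted 1/2.  Returns `NaN` when only one class
#' is present (the degenerate cell is excluded from averages, never
#' imputed).
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels.
#' @return AUC in `[0, 1]`, or `NaN` for single-class labels.
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == 1
  np <- sum(pos)
  nn <- sum(!pos)
  if (np == 0L || nn == 0L) return(NaN)
  r <- rank(scores)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve
#'
#' Average-precision form: the step-wise integral of precision over
#' recall, with tied scores grouped into a single threshold step.
#' Returns `NaN` when there are no positives.
#'
#' @inheritParams roc_auc
#' @return AUPR in `(0, 1]`, or `NaN` without positives.
#' @export
pr_auc <- function(scores, labels) {
  np <- sum(labels == 1)
  if (np == 0L) return(NaN)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  grp_end <- which(s != c(s[-1L], NA) | seq_along(s) == length(s))
  tp <- cumsum(y)[grp_end]
  n_at <- grp_end
  prec <- tp / n_at
  rec <- tp / np
  sum(diff(c(0, rec)) * prec)
}

#' Rank miRNAs per compartment
#'
#' Top-k identifiers by predicted probability per compartment, ties broken
#' by registry (row) order.
#'
#' @param prediction a `gtmaloc_prediction`.
#' @param k list length per compartment.
#' @return named list mapping compartment to `k` miRNA ids.
#' @export
top_k_per_compartment <- function(prediction, k = 5L) {
  p <- prediction$probabilities
  if (k > nrow(p)) stop("k exceeds the number of miRNAs")
  out <- lapply(colnames(p), function(cc) {
    rownames(p)[order(-p[, cc], seq_len(nrow(p)))[seq_len(k)]]
  })
  names(out) <- colnames(p)
  out
}

#' Cross-validate the fusion classifier
#'
#' Transductive protocol: networks and embeddings come from the prepared
#' feature bundle (built once on all miRNAs, without labels); per fold
#' only the supervised fusion classifier is retrained on the training
#' rows and scored on the held-out rows.  Per-class metrics are averaged
#' over folds; the macro average is the unweighted mean of the 7
#' per-class fold-means.  Degenerate (fold, class) cells (single-class
#' test split) are `NaN` and excluded from the means.
#'
#' @param features a `gtmaloc_features` bundle (or a named list of feature
#'   tables, in which case `labels` must be given).
#' @param k number of folds.
#' @param seed integer seed for the fold split and per-fold training.
#' @param config a [gtmaloc_config()] (defaults to the bundle's).
#' @param labels label matrix override.
#' @param sources subset of sources to use (ablation support).
#' @param use_raw use the unrefined node2vec tables (graph-transformer
#'   ablation).
#' @return object of class `gtmaloc_cv` with per-fold matrices `auc`,
#'   `aupr` (`k x 7`), per-class means, and `macro_auc` / `macro_aupr`.
#' @export
cross_validate <- function(features, k = 5L, seed = NULL, config = NULL,
                           labels = NULL, sources = NULL, use_raw = FALSE) {
  if (inherits(features, "gtmaloc_features")) {
    tabs <- if (use_raw) features$tokens_raw else features$tokens
    if (is.null(labels)) labels <- features$labels
    if (is.null(config)) config <- features$config
  } else {
    tabs <- features
    if (is.null(labels)) stop("labels required for plain feature lists")
    if (is.null(config)) config <- gtmaloc_config()
  }
  if (is.null(seed)) seed <- config$seed
  if (!is.null(sources)) {
    missing_s <- setdiff(sources, names(tabs))
    if (length(missing_s) > 0L) {
      stop("unknown source(s): ", paste(missing_s, collapse = ", "))
    }
    tabs <- tabs[sources]
  }
  n <- nrow(labels)
  split <- kfold_split(n, k, seed)
  n_cls <- ncol(labels)
  auc <- aupr <- matrix(NaN, k, n_cls,
                        dimnames = list(NULL, colnames(labels)))
  train_rows <- vector("list", k)
  for (i in seq_len(k)) {
    test_idx <- split$folds[[i]]
    train_idx <- setdiff(seq_len(n), test_idx)
    train_rows[[i]] <- train_idx
    fit <- gtmaloc(tabs, labels, train_index = train_idx, config = config,
                   seed = seed + i)
    pred <- predict(fit, tabs, rows = test_idx)
    for (cc in seq_len(n_cls)) {
      y <- labels[test_idx, cc]
      auc[i, cc] <- roc_auc(pred$probabilities[, cc], y)
      aupr[i, cc] <- pr_auc(pred$probabilities[, cc], y)
    }
    dropped <- sum(is.nan(auc[i, ]))
    if (dropped > 0L) {
      gt_verbose("fold %d: %d degenerate class cell(s) excluded", i, dropped)
    }
  }
  class_auc <- colMeans(auc, na.rm = TRUE)
  class_aupr <- colMeans(aupr, na.rm = TRUE)
  structure(list(k = k, seed = seed, folds = split$folds,
                 train_rows = train_rows,
                 auc = auc, aupr = aupr,
                 class_auc = class_auc, class_aupr = class_aupr,
                 macro_auc = mean(class_auc, na.rm = TRUE),
                 macro_aupr = mean(class_aupr, na.rm = TRUE),
                 sources = names(tabs),
                 config = config),
            class = "gtmaloc_cv")
}

#' @export
print.gtmaloc_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s)\n", x$k,
              paste(x$sources, collapse = "+")))
  tab <- rbind(AUC = x$class_auc, AUPR = x$class_aupr)
  print(round(tab, 4))
  cat(sprintf("macro AUC %.4f | macro AUPR %.4f\n",
              x$macro_auc, x$macro_aupr))
  invisible(x)
}

#' Ablation runner
#'
#' Re-evaluates the pipeline with one component removed: dropping an
#' association network removes its source token (3 tokens remain),
#' `graph_transformer` feeds the node2vec tables directly to the fusion
#' stage, and `mha` replaces the attention block with per-token
#' concatenation + FFN.  Everything else (fold split, seeds, other
#' components) is unchanged.
#'
#' @param features a `gtmaloc_features` bundle.
#' @param component one of `disease_net`, `drug_net`, `mrna_net`,
#'   `graph_transformer`, `mha`, or `none` (the unablated reference).
#' @inheritParams cross_validate
#' @return a `gtmaloc_cv` report.
#' @export
run_ablation <- function(features, component, k = 5L, seed = NULL) {
  all_src <- names(features$tokens)
  switch(component,
    none = cross_validate(features, k = k, seed = seed),
    disease_net = cross_validate(features, k = k, seed = seed,
                                 sources = setdiff(all_src, "disease")),
    drug_net = cross_validate(features, k = k, seed = seed,
                              sources = setdiff(all_src, "drug")),
    mrna_net = cross_validate(features, k = k, seed = seed,
                              sources = setdiff(all_src, "mrna")),
    graph_transformer = cross_validate(features, k = k, seed = seed,
                                       use_raw = TRUE),
    mha = {
      cfg <- features$config
      cfg$fusion$use_mha <- FALSE
      cross_validate(features, k = k, seed = seed, config = cfg)
    },
    stop("unknown ablation component: ", component)
  )
}

#' Attention-head study
#'
#' One cross-validation per head count with shared fold split and seeds;
#' every head count must divide the fusion width.
#'
#' @param features a `gtmaloc_features` bundle.
#' @param head_list integer head counts, e.g. `c(2, 4, 8)`.
#' @inheritParams cross_validate
#' @return named numeric vector mapping head count to macro AUC, with the
#'   full reports in attribute `reports`.
#' @export
head_count_study <- function(features, head_list = c(2L, 4L, 8L),
                             k = 5L, seed = NULL) {
  width <- features$config$fusion$width
  bad <- head_list[width %% head_list != 0L]
  if (length(bad) > 0L) {
    stop("head count(s) not dividing the fusion width (", width, "): ",
         paste(bad, collapse = ", "))
  }
  reports <- lapply(head_list, function(h) {
    cfg <- features$config
    cfg$fusion$heads <- as.integer(h)
    cross_validate(features, k = k, seed = seed, config = cfg)
  })
  out <- vapply(reports, function(r) r$macro_auc, 0)
  names(out) <- head_list
  attr(out, "reports") <- reports
  out
}

# serializable metric report for JSON output
cv_report_list <- function(cv) {
  list(k = cv$k, seed = cv$seed, sources = cv$sources,
       per_fold_auc = apply(cv$auc, 1L, as.list),
       per_fold_aupr = apply(cv$aupr, 1L, as.list),
       class_auc = as.list(cv$class_auc),
       class_aupr = as.list(cv$class_aupr),
       macro_auc = cv$macro_auc, macro_aupr = cv$macro_aupr)
}

#' Write a cross-validation report as JSON
#'
#' @param cv a `gtmaloc_cv`.
#' @param path output file.
#' @export
write_metrics <- function(cv, path) {
  jsonlite::write_json(cv_report_list(cv), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
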