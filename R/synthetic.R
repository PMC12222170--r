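# Planted-group synthetic data: G miRNA groups leave a consistent trace in
# every network (shared sequence motifs, block-structured associations,
# group-specific disease subtrees) and determine the localization labels,
# so the full pipeline has a recoverable signal with no external database.

RNA_BASES <- c("A", "C", "G", "U")

#' Specify a planted-group synthetic model
#'
#' miRNAs fall into `n_groups` groups.  Each group has a sequence motif
#' (mutated per miRNA), a block of each entity panel it preferentially
#' associates with (`p_in` within the block, `p_out` outside), a marked
#' subtree of the disease DAG its disease associations are drawn from,
#' and a label-probability vector over the 7 compartments.
#'
#' The default label profile is group-deterministic (probabilities 0/1)
#' with prevalences ranked like the curated localization data this
#' emulates: exosome and microvesicle most frequent, nucleolus rarest.
#'
#' @param n_mirna,n_disease,n_drug,n_mrna panel sizes.
#' @param n_groups number of planted groups (>= 2).
#' @param p_in,p_out association probabilities inside/outside the group
#'   block (`p_in > p_out`).
#' @param mutation_rate per-base substitution rate applied to the group
#'   motif.
#' @param motif_length motif length in nt (>= 15; sequences are trimmed or
#'   padded to 18-25 nt).
#' @param label_probs optional `[n_groups x 7]` probability matrix.
#' @param seed integer seed.
#' @return object of class `planted_model`.
#' @export
planted_model <- function(n_mirna = 300L, n_disease = 60L, n_drug = 40L,
                          n_mrna = 120L, n_groups = 4L, p_in = 0.3,
                          p_out = 0.02, mutation_rate = 0.1,
                          motif_length = 22L, label_probs = NULL,
                          seed = 42L) {
  stopifnot(n_groups >= 2L, p_in > p_out, p_in <= 1, p_out >= 0,
            mutation_rate >= 0, mutation_rate <= 1, motif_length >= 15L,
            n_disease >= n_groups)
  if (is.null(label_probs)) {
    label_probs <- default_label_profile(n_groups)
  }
  stopifnot(nrow(label_probs) == n_groups,
            ncol(label_probs) == length(COMPARTMENTS),
            all(label_probs >= 0), all(label_probs <= 1))
  groups <- rep(seq_len(n_groups), length.out = n_mirna)
  structure(list(n_mirna = as.integer(n_mirna),
                 n_disease = as.integer(n_disease),
                 n_drug = as.integer(n_drug), n_mrna = as.integer(n_mrna),
                 n_groups = as.integer(n_groups), groups = groups,
                 p_in = p_in, p_out = p_out,
                 mutation_rate = mutation_rate,
                 motif_length = as.integer(motif_length),
                 label_probs = label_probs, seed = as.integer(seed),
                 mirna_ids = sprintf("miR-%04d", seq_len(n_mirna))),
            class = "planted_model")
}

# Group-deterministic 0/1 label profile whose prevalences mimic the
# empirical compartment ranking (exosome > microvesicle > nucleus >
# cytoplasm > mitochondrion > extracellular vesicle > nucleolus).
# Column order follows COMPARTMENTS.
default_label_profile <- function(G) {
  rank_prev <- c(cytoplasm = 0.45, nucleus = 0.5, nucleolus = 0.1,
                 mitochondrion = 0.3, exosome = 0.8, microvesicle = 0.75,
                 extracellular_vesicle = 0.15)[COMPARTMENTS]
  probs <- matrix(0, G, length(COMPARTMENTS),
                  dimnames = list(NULL, COMPARTMENTS))
  for (cc in seq_along(COMPARTMENTS)) {
    g_on <- max(1L, min(G - 1L, round(rank_prev[cc] * G)))
    on <- ((cc + seq_len(g_on) - 1L) %% G) + 1L
    probs[on, cc] <- 1
  }
  probs
}

#' Generate miRNA sequences from the planted model
#'
#' Each miRNA is its group motif with i.i.d. per-base substitutions at the
#' configured rate, then trimmed/padded to a uniform 18-25 nt length.
#'
#' @param model a [planted_model()].
#' @return a `sequence_set` (named RNA strings).
#' @export
generate_sequences <- function(model) {
  set.seed(model$seed + 1L)
  motifs <- replicate(model$n_groups, paste(
    sample(RNA_BASES, model$motif_length, replace = TRUE), collapse = ""))
  seqs <- character(model$n_mirna)
  for (i in seq_len(model$n_mirna)) {
    b <- strsplit(motifs[model$groups[i]], "")[[1L]]
    mut <- runif(length(b)) < model$mutation_rate
    if (any(mut)) {
      b[mut] <- vapply(b[mut], function(x)
        sample(setdiff(RNA_BASES, x), 1L), "")
    }
    len <- sample(18:25, 1L)
    if (len <= length(b)) {
      b <- b[seq_len(len)]
    } else {
      b <- c(b, sample(RNA_BASES, len - length(b), replace = TRUE))
    }
    seqs[i] <- paste(b, collapse = "")
  }
  names(seqs) <- model$mirna_ids
  structure(seqs, registry = mirna_registry(model$mirna_ids),
            class = "sequence_set")
}

#' Generate the disease DAG of the planted model
#'
#' A rooted tree grown by seeded preferential attachment, with one marked
#' subtree per group: nodes 2..G+1 are the subtree anchors (children of
#' the root) and later diseases attach inside their group's subtree, so
#' group disease sets are DAG-coherent and carry semantic signal.
#'
#' @param model a [planted_model()].
#' @return list with `dag` (a [disease_dag()]), `edges` (child -> parent
#'   data frame) and `disease_group` (0 for the root).
#' @export
generate_disease_dag <- function(model) {
  set.seed(model$seed + 2L)
  n <- model$n_disease
  G <- model$n_groups
  ids <- sprintf("D%03d", seq_len(n))
  parent <- integer(n)  # parent[1] undefined (root)
  dgrp <- integer(n)
  dgrp[1L] <- 0L
  deg <- rep(1, n)
  for (i in 2:n) {
    if (i <= G + 1L) {
      parent[i] <- 1L        # group anchors hang off the root
      dgrp[i] <- i - 1L
    } else {
      g <- ((i - G - 2L) %% G) + 1L
      dgrp[i] <- g
      cand <- which(dgrp[seq_len(i - 1L)] == g)
      w <- deg[cand]
      parent[i] <- cand[sample_cum(w)]
    }
    deg[parent[i]] <- deg[parent[i]] + 1
  }
  edges <- data.frame(child = ids[2:n], parent = ids[parent[2:n]])
  list(dag = disease_dag(edges, nodes = ids), edges = edges,
       disease_group = setNames(dgrp, ids))
}

# weighted sample of one index, using R's RNG stream
sample_cum <- function(w) {
  u <- runif(1L) * sum(w)
  which(cumsum(w) >= u)[1L]
}

#' Generate a bipartite association network of the planted model
#'
#' For mRNA and drug panels, entities are partitioned into G contiguous
#' blocks and edges drawn with `p_in` inside the miRNA's group block and
#' `p_out` outside.  Disease associations are drawn from the group's
#' marked DAG subtree (`p_in`) versus the rest of the DAG (`p_out`).
#'
#' @param model a [planted_model()].
#' @param entity_kind `"mrna"`, `"drug"` or `"disease"`.
#' @return binary `bipartite_association` matrix.
#' @export
generate_associations <- function(model,
                                  entity_kind = c("mrna", "drug", "disease")) {
  entity_kind <- match.arg(entity_kind)
  set.seed(model$seed + 3L + match(entity_kind, c("mrna", "drug", "disease")))
  if (entity_kind == "disease") {
    dd <- generate_disease_dag(model)
    entity_ids <- names(dd$disease_group)
    egrp <- unname(dd$disease_group)
  } else {
    n_ent <- if (entity_kind == "mrna") model$n_mrna else model$n_drug
    prefix <- if (entity_kind == "mrna") "G" else "DR"
    entity_ids <- sprintf("%s%03d", prefix, seq_len(n_ent))
    egrp <- rep(seq_len(model$n_groups), length.out = n_ent)
  }
  same <- outer(model$groups, egrp, "==")
  pmat <- ifelse(same, model$p_in, model$p_out)
  mat <- matrix((runif(length(pmat)) < pmat) * 1L, nrow(pmat),
                dimnames = list(model$mirna_ids, entity_ids))
  structure(mat, entity_kind = entity_kind, skipped = 0L,
            class = c("bipartite_association", class(mat)))
}

#' Generate the localization label matrix of the planted model
#'
#' Each label is drawn independently per miRNA from its group's
#' probability vector (conditionally independent given the group).
#'
#' @param model a [planted_model()].
#' @return binary label matrix `[n_mirna x 7]`.
#' @export
generate_labels <- function(model) {
  set.seed(model$seed + 7L)
  p <- model$label_probs[model$groups, , drop = FALSE]
  expected <- colSums(p)
  if (any(expected == 0)) {
    warning("compartment(s) with zero expected positives: ",
            paste(COMPARTMENTS[expected == 0], collapse = ", "),
            call. = FALSE)
  }
  mat <- matrix((runif(length(p)) < p) * 1L, nrow(p),
                dimnames = list(model$mirna_ids, COMPARTMENTS))
  mat
}

#' Generate a complete synthetic dataset bundle
#'
#' Draws sequences, the disease DAG, the three association networks and
#' the labels from one [planted_model()].  With `out_dir` the bundle is
#' also written in the standard formats (FASTA, TSV edge lists, child ->
#' parent DAG TSV, labels CSV, model config YAML) and loads back through
#' [load_dataset()].
#'
#' @param model a [planted_model()].
#' @param out_dir optional output directory.
#' @return object of class `mirna_dataset`: `registry`, `sequences`,
#'   `assoc` (list of three bipartite matrices), `dag`, `labels`.
#' @export
generate_dataset <- function(model, out_dir = NULL) {
  seqs <- generate_sequences(model)
  dd <- generate_disease_dag(model)
  assoc <- list(mrna = generate_associations(model, "mrna"),
                drug = generate_associations(model, "drug"),
                disease = generate_associations(model, "disease"))
  labels <- generate_labels(model)
  ds <- structure(list(registry = attr(seqs, "registry"),
                       sequences = seqs, assoc = assoc, dag = dd$dag,
                       dag_edges = dd$edges, labels = labels,
                       groups = model$groups),
                  class = "mirna_dataset")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) &&
        !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
      stop("cannot create output directory: ", out_dir)
    }
    write_fasta(seqs, file.path(out_dir, "mirnas.fasta"))
    for (k in names(assoc)) {
      write_edgelist(assoc[[k]], file.path(out_dir, paste0(k, ".tsv")))
    }
    utils::write.table(dd$edges, file.path(out_dir, "disease_dag.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_labels(labels, file.path(out_dir, "labels.csv"))
    yaml::write_yaml(model[c("n_mirna", "n_disease", "n_drug", "n_mrna",
                             "n_groups", "p_in", "p_out", "mutation_rate",
                             "motif_length", "seed")],
                     file.path(out_dir, "model.yaml"))
  }
  ds
}

#' Load a dataset bundle from a directory
#'
#' Expects the files written by [generate_dataset()] (or real data in the
#' same formats): `mirnas.fasta`, `mrna.tsv`, `drug.tsv`, `disease.tsv`,
#' `disease_dag.tsv`, `labels.csv`.  The FASTA order defines the registry.
#'
#' @param dir directory path.
#' @return a `mirna_dataset`.
#' @export
load_dataset <- function(dir) {
  seqs <- read_fasta(file.path(dir, "mirnas.fasta"))
  registry <- attr(seqs, "registry")
  assoc <- list(
    mrna = read_edgelist(file.path(dir, "mrna.tsv"), registry, "mrna"),
    drug = read_edgelist(file.path(dir, "drug.tsv"), registry, "drug"),
    disease = read_edgelist(file.path(dir, "disease.tsv"), registry,
                            "disease"))
  dag_edges <- utils::read.delim(file.path(dir, "disease_dag.tsv"))
  # make sure every disease column of the association matrix is a DAG node
  dag <- disease_dag(dag_edges, nodes = colnames(assoc$disease))
  labels <- read_labels(file.path(dir, "labels.csv"), registry)
  structure(list(registry = registry, sequences = seqs, assoc = assoc,
                 dag = dag, dag_edges = dag_edges, labels = labels),
            class = "mirna_dataset")
}

#' @export
print.mirna_dataset <- function(x, ...) {
  cat("miRNA dataset:", length(x$registry$ids), "miRNAs |",
      ncol(x$assoc$mrna), "mRNAs |", ncol(x$assoc$drug), "drugs |",
      ncol(x$assoc$disease), "diseases\n")
  cat("label prevalence:\n")
  print(colMeans(x$labels))
  invisible(x)
}
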