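# Identifier registry, file readers/writers shared by all pipeline stages.
# The registry order is the single source of truth: every matrix produced
# downstream keeps one row per registry miRNA, in registry order.

#' Create a miRNA identifier registry
#'
#' @param ids character vector of unique miRNA identifiers; their order is
#'   the canonical row order of every downstream matrix.
#' @return An object of class `mirna_registry`.
#' @export
mirna_registry <- function(ids) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("duplicate miRNA identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (length(ids) == 0L) stop("registry must contain at least one miRNA")
  structure(list(ids = ids), class = "mirna_registry")
}

#' @export
length.mirna_registry <- function(x) length(x$ids)

#' @export
print.mirna_registry <- function(x, ...) {
  cat("miRNA registry with", length(x$ids), "identifiers\n")
  invisible(x)
}

# exact, case-sensitive lookup; NA for unregistered ids
registry_index <- function(registry, ids) match(ids, registry$ids)

#' Read miRNA sequences from a FASTA file
#'
#' Identifiers are the header token before the first whitespace; `T` is
#' converted to `U` on read.  Order of first appearance defines the
#' registry order when no registry is supplied.
#'
#' @param path FASTA file.
#' @return A named character vector of RNA sequences (class `sequence_set`)
#'   with the implied `mirna_registry` in attribute `registry`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) {
    stop("empty FASTA record(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  seqs <- gsub("T", "U", seqs, fixed = TRUE)
  names(seqs) <- ids
  structure(seqs, registry = mirna_registry(ids), class = "sequence_set")
}

#' Write miRNA sequences to FASTA
#'
#' @param sequences named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::BStringSet(setNames(as.character(sequences),
                                       names(sequences)))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a bipartite association edge list
#'
#' TSV with a header and two columns (`mirna_id`, entity id); an optional
#' third weight column is ignored (the networks are binary).  Duplicate
#' pairs collapse to a single 1; rows naming unregistered miRNAs are
#' skipped with a logged count.
#'
#' @param path TSV file.
#' @param registry a `mirna_registry`.
#' @param entity_kind one of `"mrna"`, `"drug"`, `"disease"`.
#' @return Binary matrix `[n_mirna x n_entity]` with `dimnames`, class
#'   `bipartite_association`; attributes `entity_kind` and `skipped`.
#' @export
read_edgelist <- function(path, registry, entity_kind = c("mrna", "drug", "disease")) {
  entity_kind <- match.arg(entity_kind)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty file (no header): ", path)
  body <- lines[-1L][nzchar(lines[-1L])]
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed row at line %d of %s", bad[1L] + 1L, path))
  }
  mir <- vapply(fields, `[[`, "", 1L)
  ent <- vapply(fields, `[[`, "", 2L)
  idx <- registry_index(registry, mir)
  n_skip <- sum(is.na(idx))
  if (n_skip > 0L) {
    gt_log("%s: skipped %d row(s) naming unregistered miRNAs", path, n_skip)
  }
  keep <- !is.na(idx)
  entity_ids <- unique(ent[keep])
  mat <- matrix(0L, length(registry$ids), length(entity_ids),
                dimnames = list(registry$ids, entity_ids))
  if (any(keep)) {
    mat[cbind(idx[keep], match(ent[keep], entity_ids))] <- 1L
  } else {
    gt_log("%s: no usable rows; association matrix is empty", path)
  }
  structure(mat, entity_kind = entity_kind, skipped = n_skip,
            class = c("bipartite_association", class(mat)))
}

#' Write a bipartite association matrix as a TSV edge list
#'
#' @param assoc binary association matrix with dimnames.
#' @param path output file.
#' @export
write_edgelist <- function(assoc, path) {
  idx <- which(assoc == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  df <- data.frame(mirna_id = rownames(assoc)[idx[, 1L]],
                   entity_id = colnames(assoc)[idx[, 2L]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a localization label matrix
#'
#' CSV with an id column plus the 7 binary compartment columns in the fixed
#' order of [COMPARTMENTS].  Registry miRNAs missing from the file get an
#' all-zero row with a warning; all-zero rows (unannotated miRNAs) are
#' flagged in attribute `unannotated`.
#'
#' @param path CSV file.
#' @param registry a `mirna_registry`.
#' @return Binary matrix `[n_mirna x 7]`, rows in registry order.
#' @export
read_labels <- function(path, registry) {
  df <- utils::read.csv(path, check.names = FALSE)
  expected <- c("mirna_id", COMPARTMENTS)
  if (!identical(names(df), expected)) {
    stop("label file columns must be exactly: ",
         paste(expected, collapse = ", "))
  }
  vals <- as.matrix(df[, COMPARTMENTS])
  if (!all(vals %in% c(0L, 1L))) {
    stop("label values must be 0 or 1")
  }
  mat <- matrix(0L, length(registry$ids), length(COMPARTMENTS),
                dimnames = list(registry$ids, COMPARTMENTS))
  idx <- registry_index(registry, df$mirna_id)
  mat[idx[!is.na(idx)], ] <- vals[!is.na(idx), ]
  n_missing <- sum(!registry$ids %in% df$mirna_id)
  if (n_missing > 0L) {
    warning(n_missing, " registry miRNA(s) missing from label file; ",
            "rows set to all-zero", call. = FALSE)
  }
  unannot <- rownames(mat)[rowSums(mat) == 0L]
  if (length(unannot) > 0L) {
    gt_log("%d miRNA(s) have no localization annotation", length(unannot))
  }
  structure(mat, unannotated = unannot)
}

#' Write a label matrix as CSV
#'
#' @param labels binary label matrix with rownames.
#' @param path output file.
#' @export
write_labels <- function(labels, path) {
  df <- data.frame(mirna_id = rownames(labels), labels,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a symmetric similarity matrix as TSV
#'
#' The file carries an id header row and an id first column.
#' @param path TSV file.
#' @export
read_similarity <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  as.matrix(df)
}

#' @rdname read_similarity
#' @param mat numeric matrix with dimnames.
#' @export
write_similarity <- function(mat, path) {
  write_float_table(mat, "mirna_id", rownames(mat), colnames(mat), path)
}

# %.17g guarantees doubles survive the text round trip bit-exactly
write_float_table <- function(mat, id_col, ids, cols, path) {
  chr <- vapply(seq_len(ncol(mat)),
                function(j) sprintf("%.17g", mat[, j]),
                character(nrow(mat)))
  if (nrow(mat) == 1L) chr <- matrix(chr, nrow = 1L)
  lines <- c(paste(c(id_col, cols), collapse = "\t"),
             paste(ids, apply(chr, 1L, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write an embedding table as TSV (`mirna_id` + d float columns)
#'
#' @param path TSV file.
#' @export
read_embeddings <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  as.matrix(df)
}

#' @rdname read_embeddings
#' @param emb numeric matrix, one row per miRNA, with rownames.
#' @export
write_embeddings <- function(emb, path) {
  write_float_table(emb, "mirna_id", rownames(emb),
                    paste0("e", seq_len(ncol(emb))), path)
}
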