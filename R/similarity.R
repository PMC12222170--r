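# Sequence similarity network (local alignment) and the GIP-fused,
# thresholded functional similarity network.

#' Alignment scoring scheme
#'
#' Per-base rewards/penalties of the local-alignment scorer.  The default
#' (+1 match, -1 mismatch, -1 per-base linear gap) keeps the score bounded
#' by the sequence length, so the normalized similarity lands in `[0, 1]`.
#'
#' @param match positive match reward.
#' @param mismatch mismatch penalty (<= 0).
#' @param gap linear gap penalty per base (<= 0).
#' @return list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1, mismatch = -1, gap = -1) {
  stopifnot(match > 0, mismatch <= 0, gap <= 0)
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "scoring_scheme")
}

check_rna <- function(...) {
  for (s in list(...)) {
    if (nchar(s) == 0L) stop("empty sequence")
    if (grepl("[^ACGU]", s)) {
      stop("sequence contains characters outside {A,C,G,U}: ", s)
    }
  }
}

#' Smith-Waterman local alignment score
#'
#' Maximum cell of the local-alignment dynamic-programming matrix with
#' linear gap penalties; always >= 0 and symmetric in its arguments.
#'
#' @param seq_a,seq_b RNA strings over `{A,C,G,U}`.
#' @param scheme a [scoring_scheme()].
#' @return non-negative alignment score.
#' @export
smith_waterman_score <- function(seq_a, seq_b, scheme = scoring_scheme()) {
  check_rna(seq_a, seq_b)
  .sw_score_cpp(seq_a, seq_b, scheme$match, scheme$mismatch, scheme$gap)
}

#' Normalized sequence similarity
#'
#' `sp(a, b) / sqrt(sp(a, a) * sp(b, b))`, the self-normalized local
#' alignment score: 1 for identical sequences, in `[0, 1]` under the
#' default scheme.
#'
#' @inheritParams smith_waterman_score
#' @return similarity in `[0, 1]`.
#' @export
normalized_sequence_similarity <- function(seq_a, seq_b,
                                           scheme = scoring_scheme()) {
  saa <- smith_waterman_score(seq_a, seq_a, scheme)
  sbb <- smith_waterman_score(seq_b, seq_b, scheme)
  if (saa <= 0 || sbb <= 0) stop("zero self-alignment score")
  sab <- smith_waterman_score(seq_a, seq_b, scheme)
  min(1, sab / sqrt(saa * sbb))
}

#' Build the weighted miRNA sequence similarity network
#'
#' All-pairs normalized local-alignment similarity; the matrix keeps real
#' edge weights (it is not binarized) and has a unit diagonal.
#'
#' @param sequences a `sequence_set` (named RNA strings).
#' @param scheme a [scoring_scheme()].
#' @return symmetric similarity matrix with `kind = "sequence"` attribute.
#' @export
build_sequence_network <- function(sequences, scheme = scoring_scheme()) {
  do.call(check_rna, as.list(unclass(sequences)))
  raw <- .sw_pairwise_cpp(as.character(sequences),
                          scheme$match, scheme$mismatch, scheme$gap)
  self <- diag(raw)
  if (any(self <= 0)) stop("zero self-alignment score")
  sim <- raw / sqrt(outer(self, self))
  sim <- pmin(sim, 1)
  diag(sim) <- 1
  dimnames(sim) <- list(names(sequences), names(sequences))
  structure(sim, kind = "sequence")
}

#' Gaussian interaction profile (GIP) kernel similarity
#'
#' `GIP(i, j) = exp(-gamma * ||IP_i - IP_j||^2)` over binary association
#' profiles, with bandwidth `gamma = gamma_prime / mean_i(||IP_i||^2)` and
#' `gamma_prime = 1`.
#'
#' @param profiles binary matrix, one association profile per miRNA row.
#' @param gamma_prime bandwidth normalizer (default 1).
#' @return symmetric similarity matrix with unit diagonal.
#' @export
gip_kernel <- function(profiles, gamma_prime = 1) {
  norms2 <- rowSums(profiles^2)
  if (mean(norms2) == 0) {
    stop("all association profiles are all-zero; GIP kernel width undefined")
  }
  gamma <- gamma_prime / mean(norms2)
  d2 <- outer(norms2, norms2, "+") - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0
  k <- exp(-gamma * d2)
  diag(k) <- 1
  dimnames(k) <- list(rownames(profiles), rownames(profiles))
  structure(k, kind = "gip")
}

#' Fuse functional and GIP similarity
#'
#' Elementwise `lambda * FS + (1 - lambda) * GIP`.
#'
#' @param fs,gip similarity matrices of identical shape.
#' @param lambda_ fusion weight in `[0, 1]`.
#' @return fused similarity matrix (`kind = "functional_fused"`).
#' @export
fuse_similarity <- function(fs, gip, lambda_ = 0.5) {
  stopifnot(lambda_ >= 0, lambda_ <= 1)
  if (!all(dim(fs) == dim(gip))) stop("shape mismatch between FS and GIP")
  structure(lambda_ * fs + (1 - lambda_) * gip, kind = "functional_fused")
}

#' Binarize a similarity matrix into an adjacency matrix
#'
#' Strict threshold (`> T`); the diagonal is forced to 0 (no self-loops).
#'
#' @param matrix similarity matrix.
#' @param T threshold in `[0, 1]`.
#' @return binary adjacency matrix; attribute `threshold_used`.
#' @export
binarize <- function(matrix, T = 0.6) {
  stopifnot(T >= 0, T <= 1)
  adj <- (matrix > T) * 1L
  diag(adj) <- 0L
  structure(adj, threshold_used = T, kind = NULL)
}
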