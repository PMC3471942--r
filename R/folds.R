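#' Pairwise global sequence identity
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap opening 10, gap extension
#' 0.5 — the documented scoring) with identity defined as the number of
#' identical aligned positions divided by the alignment length including
#' gaps.
#'
#' @param seq1,seq2 Amino-acid strings.
#' @return Identity fraction in `[0, 1]`.
#' @export
sequence_identity <- function(seq1, seq2) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq1), Biostrings::AAString(seq2),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  Biostrings::pid(aln, type = "PID1") / 100
}

#' Identity-clustered cross-validation folds
#'
#' Clusters the proteins by single-linkage at pairwise global sequence
#' identity above `identity_threshold` (default 30%), then assigns whole
#' clusters to `k` folds greedily — largest mutation count first, into the
#' currently lightest fold — so folds carry similar numbers of mutations and
#' no two proteins above the identity threshold ever sit in different folds.
#' Forward and reverse records share a protein id, hence always a fold. The
#' assignment is fully deterministic (ties broken by cluster order).
#'
#' @param mutations Mutation table (after augmentation, typically).
#' @param proteins Protein table covering every `protein_id`.
#' @param k Number of folds.
#' @param identity_threshold Single-linkage joining threshold.
#' @return Tibble with columns `protein_id`, `cluster`, `fold`; the pairwise
#'   identity matrix is attached as attribute `"identity"`.
#' @export
assign_folds <- function(mutations, proteins, k = 5,
                         identity_threshold = 0.30) {
  ids <- sort(unique(mutations$protein_id))
  n <- length(ids)
  seqs <- vapply(ids, function(i) protein_row(proteins, i)$sequence, "")
  idm <- diag(1, n)
  dimnames(idm) <- list(ids, ids)
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        idm[i, j] <- idm[j, i] <- sequence_identity(seqs[i], seqs[j])
      }
    }
  }
  # single-linkage union-find over pairs above the threshold
  parent <- seq_len(n)
  find2 <- function(p, x) { while (p[x] != x) x <- p[x]; x }
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (idm[i, j] > identity_threshold) {
          ri <- find2(parent, i); rj <- find2(parent, j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  cluster <- vapply(seq_len(n), function(x) find2(parent, x), integer(1))
  cluster <- match(cluster, sort(unique(cluster)))
  n_clusters <- length(unique(cluster))
  if (n_clusters < k) {
    stop(sprintf(
      "only %d identity clusters for %d folds; use k <= %d",
      n_clusters, k, n_clusters), call. = FALSE)
  }
  counts <- table(factor(mutations$protein_id, levels = ids))
  cl_count <- vapply(seq_len(n_clusters), function(c) sum(counts[cluster == c]),
                     numeric(1))
  ord <- order(-cl_count, seq_len(n_clusters))
  load <- numeric(k)
  cl_fold <- integer(n_clusters)
  for (c in ord) {
    f <- which.min(load)
    cl_fold[c] <- f
    load[f] <- load[f] + cl_count[c]
  }
  out <- tibble::tibble(protein_id = ids, cluster = cluster,
                        fold = cl_fold[cluster])
  attr(out, "identity") <- idm
  out
}
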