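#' Evolutionary-information features from a sequence profile
#'
#' Ten features per mutation record, extracted from the wild-type protein's
#' position-specific scoring matrix:
#'
#' * `Wtlo`, `Wtwt`: log-odds and weighted observed percentage of the
#'   wild-type residue at the mutated position;
#' * `Mulo`, `Muwt`: the same for the mutant residue;
#' * `wtlo5/9/15`, `wtwt5/9/15`: conservation of the neighbourhood — the mean
#'   over a window of 5, 9 or 15 positions centred on the site (truncated at
#'   the termini) of the per-position total log-odds (resp. weighted) score,
#'   where the per-position total is the sum of the 20 matrix entries.
#'
#' For multi-point records each slot is the arithmetic mean of the per-site
#' values. Raw matrix units are kept throughout. Because the window features
#' do not involve the mutant residue, swapping wild type and mutant (profile
#' reuse for hypothetical reverse mutations) exchanges `Wtlo`/`Wtwt` with
#' `Mulo`/`Muwt` and leaves the window slots unchanged.
#'
#' @param pssm A `pssm` object.
#' @param subs Substitution tibble (`wt`, `pos`, `mut`).
#' @return Named numeric vector of the 10 evolutionary features.
#' @export
evo_features <- function(pssm, subs) {
  n <- nrow(pssm$log_odds)
  if (any(subs$pos < 1 | subs$pos > n)) {
    stop("substitution position outside profile", call. = FALSE)
  }
  pts <- vapply(seq_len(nrow(subs)), function(k) {
    point_scores(pssm, subs$pos[k], subs$wt[k], subs$mut[k])
  }, numeric(4))
  wins <- vapply(c(5, 9, 15), function(w) {
    rowMeans(vapply(subs$pos, function(p) window_scores(pssm, p, w), numeric(2)))
  }, numeric(2))
  out <- c(rowMeans(pts),
           wins[1, 1], wins[2, 1], wins[1, 2], wins[2, 2], wins[1, 3], wins[2, 3])
  names(out) <- EVO_FEATURES
  out
}

#' @rdname evo_features
#' @param position 1-based residue position.
#' @param wt_aa,mut_aa Wild-type and mutant residue letters.
#' @export
point_scores <- function(pssm, position, wt_aa, mut_aa) {
  if (position < 1 || position > nrow(pssm$log_odds)) {
    stop("position outside profile", call. = FALSE)
  }
  c(Wtlo = unname(pssm$log_odds[position, wt_aa]),
    Wtwt = unname(pssm$weighted[position, wt_aa]),
    Mulo = unname(pssm$log_odds[position, mut_aa]),
    Muwt = unname(pssm$weighted[position, mut_aa]))
}

#' @rdname evo_features
#' @param w Window width (5, 9 or 15 positions).
#' @export
window_scores <- function(pssm, position, w) {
  n <- nrow(pssm$log_odds)
  half <- (w - 1) %/% 2
  idx <- max(1, position - half):min(n, position + half)
  c(avg_log_odds = mean(rowSums(pssm$log_odds[idx, , drop = FALSE])),
    avg_weighted = mean(rowSums(pssm$weighted[idx, , drop = FALSE])))
}
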