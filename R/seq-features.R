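#' Secondary-structure and solvent-accessibility features of the mutated sites
#'
#' Five features describing where the mutation sits in the wild-type
#' conformation (the mutant is assumed to keep it): indicator fractions of the
#' mutated sites in helix / sheet / coil and in exposed / buried state at the
#' 25% relative-accessibility threshold. A single-point record yields one-hot
#' indicators; a multi-point record the fraction of its sites in each state.
#' `Helix + Sheet + Coil = 1` and `Exposed + Buried = 1` always hold.
#'
#' @param states Per-residue state tibble (`pos`, `ss3`, `exposure2`) for the
#'   wild-type protein.
#' @param subs Substitution tibble (`wt`, `pos`, `mut`).
#' @return Named numeric vector of the 5 features.
#' @export
sssa_features <- function(states, subs) {
  i <- match(subs$pos, states$pos)
  if (anyNA(i)) {
    stop(sprintf("missing annotation at position(s) %s",
                 paste(subs$pos[is.na(i)], collapse = ", ")), call. = FALSE)
  }
  ss <- states$ss3[i]
  ex <- states$exposure2[i]
  c(Helix = mean(ss == "H"), Sheet = mean(ss == "E"), Coil = mean(ss == "C"),
    Exposed = mean(ex == "exposed"), Buried = mean(ex == "buried"))
}

#' Fraction of a sequence in a residue set
#'
#' @param sequence Amino-acid string.
#' @param residue_set Character vector of one-letter codes.
#' @return Count of residues in the set divided by sequence length.
#' @export
composition_fraction <- function(sequence, residue_set) {
  chars <- strsplit(sequence, "")[[1]]
  mean(chars %in% residue_set)
}

#' Relative-difference features between wild-type and mutant sequences
#'
#' Six whole-sequence differences, each computed as mutant value minus
#' wild-type value so that swapping the two sequences negates every slot
#' exactly:
#'
#' * `POSI`: composition of positively charged residues (R, K, H);
#' * `CHAR`: composition of charged residues (R, K, H, D, E);
#' * `SMAL`: composition of the small-residue set (T, D), implemented
#'   verbatim as published for this feature family (`small_set` overrides);
#' * `TINY`: composition of tiny residues (A, G, P, S);
#' * `dASA`: mean per-residue maximum accessible surface area (`AA_MAX_ASA`);
#' * `pIa`: mean per-residue isoelectric point (`AA_PI`).
#'
#' Only mutated positions contribute to the differences, so each equals the
#' per-site property change summed over substitutions and divided by the
#' sequence length.
#'
#' @param wt_seq,mut_seq Equal-length amino-acid strings.
#' @param small_set,asa_scale,pi_table Replaceable constant tables.
#' @return Named numeric vector of the 6 features.
#' @export
reldiff_features <- function(wt_seq, mut_seq,
                             small_set = AA_SET_SMAL,
                             asa_scale = AA_MAX_ASA,
                             pi_table = AA_PI) {
  if (nchar(wt_seq) != nchar(mut_seq)) {
    stop("wild-type and mutant sequences differ in length", call. = FALSE)
  }
  wt <- strsplit(wt_seq, "")[[1]]
  mu <- strsplit(mut_seq, "")[[1]]
  n <- length(wt)
  d <- which(wt != mu)
  comp_delta <- function(set) {
    (sum(mu[d] %in% set) - sum(wt[d] %in% set)) / n
  }
  c(POSI = comp_delta(AA_SET_POSI),
    CHAR = comp_delta(AA_SET_CHAR),
    SMAL = comp_delta(small_set),
    TINY = comp_delta(AA_SET_TINY),
    dASA = (sum(asa_scale[mu[d]]) - sum(asa_scale[wt[d]])) / n,
    pIa = (sum(pi_table[mu[d]]) - sum(pi_table[wt[d]])) / n)
}
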