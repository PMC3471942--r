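#' Amino-acid constant tables
#'
#' Named per-residue constants used by the feature pipeline. All tables are
#' keyed by one-letter code over the standard 20-residue alphabet and every
#' function that consumes one accepts a replacement via its `scale =` /
#' `table =` argument, so an alternative published scale can be dropped in
#' without touching the pipeline.
#'
#' * `AA_ALPHABET`: the 20 one-letter codes in the column order used by
#'   profile-search ASCII matrices (A R N D C Q E G H I L K M F P S T W Y V).
#' * `AA_MAX_ASA`: theoretical maximum accessible surface area per residue
#'   (Angstrom^2), Tien et al. (2013) theoretical scale; denominator for
#'   relative solvent accessibility.
#' * `AA_PI`: isoelectric point of the free amino acid.
#' * `AA_FREQ`: background residue frequencies (UniProt-like composition),
#'   used by the synthetic sequence generator; sums to 1.
#'
#' @format Named numeric (or character) vectors of length 20.
#' @name aa_tables
NULL

#' @rdname aa_tables
#' @export
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' @rdname aa_tables
#' @export
AA_MAX_ASA <- c(
  A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
  Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
  L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
  S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0
)

#' @rdname aa_tables
#' @export
AA_PI <- c(
  A = 6.01, R = 10.76, N = 5.41, D = 2.77, C = 5.07,
  Q = 5.65, E = 3.22, G = 5.97, H = 7.59, I = 6.02,
  L = 5.98, K = 9.74, M = 5.74, F = 5.48, P = 6.30,
  S = 5.68, T = 5.60, W = 5.89, Y = 5.66, V = 5.96
)

#' @rdname aa_tables
#' @export
AA_FREQ <- c(
  A = 0.0825, R = 0.0553, N = 0.0406, D = 0.0545, C = 0.0137,
  Q = 0.0393, E = 0.0675, G = 0.0707, H = 0.0227, I = 0.0596,
  L = 0.0966, K = 0.0584, M = 0.0242, F = 0.0386, P = 0.0470,
  S = 0.0656, T = 0.0534, W = 0.0108, Y = 0.0292, V = 0.0687
)

# residue-set definitions behind the six relative-difference features;
# SMAL is deliberately {T, D} as published for this feature set
AA_SET_POSI <- c("R", "K", "H")
AA_SET_CHAR <- c("R", "K", "H", "D", "E")
AA_SET_SMAL <- c("T", "D")
AA_SET_TINY <- c("A", "G", "P", "S")

#' Canonical feature-name sets
#'
#' Slot names of the feature vector, grouped as in the model: 10 evolutionary
#' features, 5 secondary-structure/solvent-accessibility features, 6 relative
#' difference features, 13 sequential fragment-potential features and 7
#' Delaunay (structure-only) fragment features. `feature_names("structure")`
#' returns all 41, `feature_names("sequence")` the 34 sequence-derivable ones.
#'
#' @param mode `"structure"` (41 features) or `"sequence"` (34 features).
#' @return Character vector of feature names.
#' @export
feature_names <- function(mode = c("structure", "sequence")) {
  mode <- match.arg(mode)
  nm <- c(EVO_FEATURES, SSSA_FEATURES, RELDIFF_FEATURES, SEQFRAG_FEATURES)
  if (mode == "structure") nm <- c(nm, DT_FEATURES)
  nm
}

EVO_FEATURES <- c("Wtlo", "Wtwt", "Mulo", "Muwt",
                  "wtlo5", "wtwt5", "wtlo9", "wtwt9", "wtlo15", "wtwt15")
SSSA_FEATURES <- c("Helix", "Sheet", "Coil", "Exposed", "Buried")
RELDIFF_FEATURES <- c("POSI", "CHAR", "SMAL", "TINY", "dASA", "pIa")
SEQFRAG_FEATURES <- c("FBocc", "FBhel", "FBshe", "FBcoi", "FBexp", "FBbur",
                      "FBint", "FDhel", "FDshe", "FDcoi", "FDexp", "FDbur",
                      "FDint")
DT_FEATURES <- c("FBDTocc", "FBDTD43", "FBDTD2", "FBDTD1",
                 "FBDTDD43", "FBDTDD2", "FBDTDD1")

# difference-type slots: exactly anti-symmetric under wild-type/mutant swap
DIFF_FEATURES <- c(RELDIFF_FEATURES, SEQFRAG_FEATURES, DT_FEATURES)

check_aa <- function(aa, what = "residue") {
  bad <- setdiff(unique(aa), AA_ALPHABET)
  if (length(bad) > 0) {
    stop(sprintf("unknown %s letter(s): %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(aa)
}
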