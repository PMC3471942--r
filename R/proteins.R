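#' Build a protein table
#'
#' The protein table is the package's central container: one row per wild-type
#' protein, with the sequence as a character column and every optional
#' per-residue layer (C-alpha coordinates, three-state secondary structure,
#' relative solvent accessibility, sequence profile) held in a list-column.
#' Layers are length-checked against the sequence when attached.
#'
#' @param id Character vector of protein identifiers (unique).
#' @param sequence Character vector of amino-acid sequences over the standard
#'   20-letter alphabet.
#' @return A tibble with columns `id`, `sequence` and empty list-columns
#'   `ca`, `ss3`, `rsa`, `pssm`.
#' @export
protein_table <- function(id, sequence) {
  stopifnot(length(id) == length(sequence))
  if (anyDuplicated(id)) stop("duplicate protein ids", call. = FALSE)
  sequence <- toupper(sequence)
  if (any(!nzchar(sequence))) stop("empty sequence", call. = FALSE)
  check_aa(unlist(strsplit(sequence, "")), "sequence")
  tibble::tibble(
    id = as.character(id),
    sequence = sequence,
    ca = vector("list", length(id)),
    ss3 = vector("list", length(id)),
    rsa = vector("list", length(id)),
    pssm = vector("list", length(id))
  )
}

protein_row <- function(proteins, protein_id) {
  i <- match(protein_id, proteins$id)
  if (is.na(i)) stop(sprintf("unknown protein id '%s'", protein_id), call. = FALSE)
  proteins[i, ]
}

check_layer_length <- function(proteins, protein_id, layer, n) {
  len <- nchar(protein_row(proteins, protein_id)$sequence)
  if (n != len) {
    stop(sprintf("layer '%s' for protein '%s' has length %d but sequence has %d residues",
                 layer, protein_id, n, len), call. = FALSE)
  }
}

#' Attach per-residue layers to a protein table
#'
#' `add_structure()` attaches C-alpha coordinates (and, when given, the
#' DSSP-derived secondary structure and accessible surface area converted to
#' relative solvent accessibility). `add_annotation()` attaches
#' sequence-mode predicted secondary structure / RSA. `add_profile()` attaches
#' a position-specific scoring matrix. All validate layer length against the
#' sequence and return the modified table.
#'
#' @param proteins A protein table (see [protein_table()]).
#' @param protein_id Id of the row to modify.
#' @param ca Numeric matrix, one row per residue, columns x/y/z in Angstrom.
#'   Rows with any `NA` mark residues without observed coordinates.
#' @param ss3 Character vector of per-residue states in `{"H","E","C"}`.
#' @param rsa Numeric vector of relative solvent accessibility, `>= 0`.
#' @param pssm A `pssm` object from [read_pssm()] or [sim_pssm()].
#' @return The protein table with the layer filled in.
#' @export
add_structure <- function(proteins, protein_id, ca, ss3 = NULL, rsa = NULL) {
  ca <- as.matrix(ca)
  if (ncol(ca) != 3) stop("ca must have 3 columns (x, y, z)", call. = FALSE)
  check_layer_length(proteins, protein_id, "ca", nrow(ca))
  i <- match(protein_id, proteins$id)
  proteins$ca[[i]] <- unname(ca)
  if (!is.null(ss3)) proteins <- add_annotation(proteins, protein_id, ss3 = ss3)
  if (!is.null(rsa)) proteins <- add_annotation(proteins, protein_id, rsa = rsa)
  proteins
}

#' @rdname add_structure
#' @export
add_annotation <- function(proteins, protein_id, ss3 = NULL, rsa = NULL) {
  i <- match(protein_id, proteins$id)
  if (is.na(i)) stop(sprintf("unknown protein id '%s'", protein_id), call. = FALSE)
  if (!is.null(ss3)) {
    check_layer_length(proteins, protein_id, "ss3", length(ss3))
    bad <- setdiff(unique(ss3), c("H", "E", "C"))
    if (length(bad) > 0) stop("ss3 states must be H, E or C", call. = FALSE)
    proteins$ss3[[i]] <- as.character(ss3)
  }
  if (!is.null(rsa)) {
    check_layer_length(proteins, protein_id, "rsa", length(rsa))
    if (any(rsa < 0, na.rm = TRUE)) stop("rsa values must be >= 0", call. = FALSE)
    proteins$rsa[[i]] <- as.numeric(rsa)
  }
  proteins
}

#' @rdname add_structure
#' @export
add_profile <- function(proteins, protein_id, pssm) {
  stopifnot(inherits(pssm, "pssm"))
  check_layer_length(proteins, protein_id, "pssm", nrow(pssm$log_odds))
  seq_chars <- strsplit(protein_row(proteins, protein_id)$sequence, "")[[1]]
  if (!is.null(pssm$residues) && !all(pssm$residues == seq_chars)) {
    stop(sprintf("profile residue column disagrees with sequence of '%s'", protein_id),
         call. = FALSE)
  }
  i <- match(protein_id, proteins$id)
  proteins$pssm[[i]] <- pssm
  proteins
}

new_pssm <- function(log_odds, weighted, residues = NULL) {
  log_odds <- as.matrix(log_odds)
  weighted <- as.matrix(weighted)
  stopifnot(ncol(log_odds) == 20, ncol(weighted) == 20,
            nrow(log_odds) == nrow(weighted))
  colnames(log_odds) <- AA_ALPHABET
  colnames(weighted) <- AA_ALPHABET
  structure(list(log_odds = log_odds, weighted = weighted, residues = residues),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("<pssm> %d positions x 20 residues (log-odds + weighted %%)\n",
              nrow(x$log_odds)))
  invisible(x)
}

#' Apply substitutions to a sequence
#'
#' Replaces the residue at each substitution position, after checking that the
#' current residue matches the recorded wild-type letter.
#'
#' @param sequence Amino-acid string.
#' @param subs Tibble with columns `wt`, `pos`, `mut` (see [parse_subs()]).
#' @return The mutated sequence string.
#' @export
apply_subs <- function(sequence, subs) {
  chars <- strsplit(sequence, "")[[1]]
  if (any(subs$pos < 1 | subs$pos > length(chars))) {
    stop("substitution position out of range", call. = FALSE)
  }
  mismatch <- chars[subs$pos] != subs$wt
  if (any(mismatch)) {
    k <- which(mismatch)[1]
    stop(sprintf("substitution %s%d%s: sequence has %s at position %d",
                 subs$wt[k], subs$pos[k], subs$mut[k], chars[subs$pos[k]],
                 subs$pos[k]), call. = FALSE)
  }
  chars[subs$pos] <- subs$mut
  paste(chars, collapse = "")
}

#' Parse substitution strings
#'
#' Parses compact substitution notation (`"V66A"`, multi-point
#' `"V66A,G88V"`) into a tibble of one row per site.
#'
#' @param x A single substitution string; sites separated by commas.
#' @return Tibble with columns `wt` (wild-type letter), `pos` (1-based
#'   position) and `mut` (mutant letter).
#' @export
parse_subs <- function(x) {
  parts <- strsplit(trimws(x), ",")[[1]]
  parts <- trimws(parts)
  m <- regmatches(parts, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", parts))
  bad <- lengths(m) != 4
  if (length(parts) == 0 || any(bad)) {
    stop(sprintf("unparsable substitution string '%s'", x), call. = FALSE)
  }
  subs <- tibble::tibble(
    wt = toupper(vapply(m, `[`, "", 2)),
    pos = as.integer(vapply(m, `[`, "", 3)),
    mut = toupper(vapply(m, `[`, "", 4))
  )
  check_aa(c(subs$wt, subs$mut), "substitution")
  if (any(subs$wt == subs$mut)) {
    stop(sprintf("substitution '%s' does not change the residue", x), call. = FALSE)
  }
  if (anyDuplicated(subs$pos)) {
    stop(sprintf("duplicate substitution position in '%s'", x), call. = FALSE)
  }
  subs
}

format_subs <- function(subs) {
  paste(sprintf("%s%d%s", subs$wt, subs$pos, subs$mut), collapse = ",")
}
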