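#' Read wild-type proteins from FASTA
#'
#' Wraps `Biostrings::readAAStringSet()` and validates every sequence against
#' the standard 20-letter alphabet (ambiguity codes such as `B` or `X` are
#' rejected; the record id is named in the error). The first whitespace-
#' delimited token of each header is used as the protein id.
#'
#' @param path Path to a FASTA file.
#' @return A protein table (see [protein_table()]), entries in file order.
#' @export
read_fasta <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0) stop(sprintf("no FASTA records in '%s'", path), call. = FALSE)
  ids <- sub("\\s.*$", "", names(aas))
  seqs <- unname(as.character(aas))
  for (k in seq_along(seqs)) {
    if (!nzchar(seqs[k])) {
      stop(sprintf("empty sequence for record '%s' in '%s'", ids[k], path),
           call. = FALSE)
    }
    bad <- setdiff(unique(strsplit(seqs[k], "")[[1]]), AA_ALPHABET)
    if (length(bad) > 0) {
      stop(sprintf("record '%s' in '%s' contains non-standard letter(s): %s",
                   ids[k], path, paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  protein_table(ids, seqs)
}

#' Read a profile-search ASCII position-specific scoring matrix
#'
#' Parses the standard ASCII PSSM layout produced by iterative profile search:
#' one row per position carrying the residue letter, 20 integer log-odds
#' columns and 20 weighted observed-percentage columns (trailing per-position
#' information columns are ignored). Column order is the fixed documented
#' order `AA_ALPHABET`.
#'
#' @param path Path to the ASCII PSSM file.
#' @return A `pssm` object: list with `log_odds` and `weighted` matrices
#'   (positions x 20) and the `residues` column for validation against a
#'   sequence.
#' @export
read_pssm <- function(path) {
  lines <- readLines(path)
  toks <- strsplit(trimws(lines), "\\s+")
  is_data <- vapply(toks, function(t) {
    length(t) >= 2 && grepl("^[0-9]+$", t[1]) && grepl("^[A-Za-z]$", t[2])
  }, logical(1))
  if (!any(is_data)) stop(sprintf("no PSSM rows found in '%s'", path), call. = FALSE)
  rows <- toks[is_data]
  lineno <- which(is_data)
  n <- length(rows)
  log_odds <- matrix(NA_real_, n, 20)
  weighted <- matrix(NA_real_, n, 20)
  residues <- character(n)
  for (k in seq_len(n)) {
    t <- rows[[k]]
    if (length(t) < 42) {
      stop(sprintf("PSSM row at line %d of '%s' has %d fields, expected >= 42",
                   lineno[k], path, length(t)), call. = FALSE)
    }
    pos <- as.integer(t[1])
    if (pos != k) {
      stop(sprintf("PSSM positions not contiguous at line %d of '%s'",
                   lineno[k], path), call. = FALSE)
    }
    residues[k] <- toupper(t[2])
    vals <- suppressWarnings(as.numeric(t[3:42]))
    if (anyNA(vals)) {
      stop(sprintf("non-numeric PSSM value at line %d of '%s'", lineno[k], path),
           call. = FALSE)
    }
    log_odds[k, ] <- vals[1:20]
    weighted[k, ] <- vals[21:40]
  }
  new_pssm(log_odds, weighted, residues)
}

#' Extract C-alpha coordinates from a PDB file
#'
#' Reads `ATOM` records via `bio3d::read.pdb()` and keeps C-alpha atoms of one
#' chain from the first model. Alternate locations other than blank or `A`
#' are dropped; records with insertion codes are rejected so residue numbering
#' stays unambiguous.
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier; default takes the first chain present.
#' @return Numeric matrix (residues x 3) of coordinates in file order.
#' @export
read_pdb_ca <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  atoms <- pdb$atom
  atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) chain <- atoms$chain[1]
  atoms <- atoms[atoms$chain %in% chain, , drop = FALSE]
  ins <- atoms$insert
  if (any(!is.na(ins) & nzchar(trimws(ins)))) {
    stop(sprintf("'%s' contains insertion codes; renumber the structure first", path),
         call. = FALSE)
  }
  alt <- atoms$alt
  keep_alt <- is.na(alt) | alt %in% c("", "A")
  cas <- atoms[keep_alt & atoms$elety == "CA", , drop = FALSE]
  if (nrow(cas) == 0) {
    stop(sprintf("no C-alpha atoms in chain '%s' of '%s'", chain, path),
         call. = FALSE)
  }
  unname(as.matrix(cas[, c("x", "y", "z")]))
}

#' Read a DSSP output file
#'
#' Parses the classic fixed-width DSSP layout: residues after the
#' `#  RESIDUE` header line, one-letter amino acid at column 14, 8-state
#' secondary structure at column 17, accessible surface area (ACC, Angstrom^2)
#' at columns 35-38. Chain-break rows (`!`) are skipped and reported as gaps.
#'
#' @param path Path to a DSSP file.
#' @return Tibble with `pos` (1-based running residue index), `aa`, `ss8`
#'   (`" "` for unassigned) and `acc`.
#' @export
read_dssp <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^\\s*#\\s+RESIDUE", lines)
  if (length(hdr) == 0) stop(sprintf("'%s' is not a DSSP file", path), call. = FALSE)
  body <- lines[(hdr[1] + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  aa <- substr(body, 14, 14)
  gap <- aa == "!"
  body <- body[!gap]
  aa <- aa[!gap]
  ss8 <- substr(body, 17, 17)
  acc <- suppressWarnings(as.numeric(substr(body, 35, 38)))
  if (anyNA(acc)) stop(sprintf("unreadable ACC field in '%s'", path), call. = FALSE)
  tibble::tibble(pos = seq_along(aa), aa = toupper(aa), ss8 = ss8, acc = acc)
}

#' Read predicted per-residue annotation
#'
#' Sequence-mode secondary structure and relative solvent accessibility are
#' consumed from a 3-column TSV (`pos`, `ss3`, `rsa`) written by an external
#' predictor or by [sim_bundle()].
#'
#' @param path Path to the annotation TSV.
#' @return Tibble with columns `pos`, `ss3`, `rsa`, sorted by position.
#' @export
read_annotation_tsv <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    pos = readr::col_integer(),
    ss3 = readr::col_character(),
    rsa = readr::col_double()
  ))
  if (!all(c("pos", "ss3", "rsa") %in% names(x))) {
    stop(sprintf("'%s' must have columns pos, ss3, rsa", path), call. = FALSE)
  }
  dplyr::arrange(x, .data$pos)
}

#' Read and write mutation tables
#'
#' The mutation table is a TSV with header columns `protein_id`, `mutations`
#' (comma-joined substitution strings such as `V66A` or `V66A,G88V`) and
#' `ddg` (kcal/mol). The package-wide sign convention is positive =
#' stabilizing; sources using the opposite convention are negated at load time
#' via `negate_ddg = TRUE` — this is the only place the convention is applied.
#' Every substitution is validated against the protein sequence. Optional
#' `direction` and `pair_id` columns (as written by [write_mutations()] after
#' [augment_reverse()]) are honoured on re-read.
#'
#' @param path Path to the TSV file.
#' @param proteins Protein table resolving every `protein_id`.
#' @param negate_ddg Negate the ddg column on load (source uses
#'   positive = destabilizing).
#' @return A mutation table: tibble with columns `protein_id`, `mutations`,
#'   `subs` (list-column of per-site tibbles), `ddg`, `direction`, `pair_id`.
#' @export
read_mutations <- function(path, proteins, negate_ddg = FALSE) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(),
    mutations = readr::col_character(),
    ddg = readr::col_double(),
    .default = readr::col_character()
  ))
  if (!all(c("protein_id", "mutations", "ddg") %in% names(x))) {
    stop(sprintf("'%s' must have columns protein_id, mutations, ddg", path),
         call. = FALSE)
  }
  subs <- lapply(x$mutations, parse_subs)
  direction <- if ("direction" %in% names(x)) x$direction else rep("forward", nrow(x))
  pair_id <- if ("pair_id" %in% names(x)) x$pair_id else sprintf("m%05d", seq_len(nrow(x)))
  out <- tibble::tibble(
    protein_id = x$protein_id,
    mutations = vapply(subs, format_subs, ""),
    subs = subs,
    ddg = if (negate_ddg) -x$ddg else x$ddg,
    direction = direction,
    pair_id = pair_id
  )
  validate_mutations(out, proteins)
  out
}

#' @rdname read_mutations
#' @param mutations A mutation table.
#' @export
write_mutations <- function(mutations, path) {
  out <- mutations[, c("protein_id", "mutations", "ddg", "direction", "pair_id")]
  readr::write_tsv(out, path)
  invisible(path)
}

# check every record's substitutions against the record's source sequence
# (wild-type sequence for forward records, mutant sequence for reverse ones)
validate_mutations <- function(mutations, proteins) {
  for (k in seq_len(nrow(mutations))) {
    seqs <- record_sequences(mutations[k, ], proteins)
    if (is.null(seqs)) {
      stop(sprintf("record %d (%s %s): substitution does not match sequence",
                   k, mutations$protein_id[k], mutations$mutations[k]),
           call. = FALSE)
    }
  }
  invisible(mutations)
}

# source ("wild-type side") and target ("mutant side") sequences of a record.
# For a forward record the source is the wild-type protein sequence; for a
# hypothetical reverse record the source is the mutant sequence (wild type
# with the forward substitutions applied) and the target restores the wild
# type. Returns NULL if the substitutions are inconsistent with the sequence.
record_sequences <- function(record, proteins) {
  base <- protein_row(proteins, record$protein_id)$sequence
  subs <- record$subs[[1]]
  res <- tryCatch({
    if (identical(record$direction, "reverse")) {
      fwd <- tibble::tibble(wt = subs$mut, pos = subs$pos, mut = subs$wt)
      src <- apply_subs(base, fwd)
      list(from = src, to = apply_subs(src, subs))
    } else {
      list(from = base, to = apply_subs(base, subs))
    }
  }, error = function(e) NULL)
  res
}
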