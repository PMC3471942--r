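#' Fragment potential tables
#'
#' A potential table maps a fragment key (a contiguous tetra-peptide for
#' sequential tables, a sorted 4-residue composition for Delaunay tables) to a
#' real-valued potential contrasting two reference corpora, typically a
#' thermophile-like set A against a mesophile-like set B. Two functional
#' forms are used:
#'
#' * occurrence (`kind = "occurrence"`): smoothed log-ratio of fragment
#'   frequencies,
#'   `ln((nA(f)+k)/(NA+kK)) - ln((nB(f)+k)/(NB+kK))`, with pseudocount
#'   `k > 0` and key-space size `K`;
#' * propensity (`kind = "propensity"`): state-conditioned enrichment,
#'   `ln(P(f|state)/P(f))` computed per corpus with the same smoothing and
#'   differenced A minus B.
#'
#' State-conditioned tables exist for the three secondary-structure states
#' and the three exposure states (sequential tables) or the three sequence-
#' continuity classes (Delaunay tables). Identical corpora give all-zero
#' tables; fragments unseen in both corpora score a table-wide constant
#' stored as the table default.
#'
#' @name potential_tables
NULL

new_potential_table <- function(kind, state, values, default, pseudocount,
                                key_space, corpus_meta = character()) {
  structure(list(kind = kind, state = state,
                 values = values, default = default,
                 pseudocount = pseudocount, key_space = key_space,
                 corpus_meta = corpus_meta),
            class = "potential_table")
}

#' @export
print.potential_table <- function(x, ...) {
  cat(sprintf("<potential_table> kind=%s state=%s keys=%d default=%.4g\n",
              x$kind, x$state, length(x$values), x$default))
  invisible(x)
}

lookup_potential <- function(table, keys) {
  v <- unname(table$values[keys])
  v[is.na(v)] <- table$default
  v
}

# all contiguous tetra-peptides of a sequence (empty if shorter than 4)
fragments4 <- function(sequence) {
  n <- nchar(sequence)
  if (n < 4) return(character(0))
  substring(sequence, 1:(n - 3), 4:n)
}

#' Assign one state to a 4-residue fragment
#'
#' The state of a fragment whose residues carry per-residue states is the
#' majority state of the four positions; a 2-2 tie is broken by the state of
#' the third residue, and (as a final guard) by a fixed state order.
#'
#' @param states Character vector of length 4 (the per-residue states of the
#'   fragment positions, in sequence order).
#' @param order Fixed tie-break order of states.
#' @return A single state.
#' @export
fragment_state <- function(states, order = c("H", "E", "C", "buried",
                                             "intermediate", "exposed")) {
  stopifnot(length(states) == 4)
  counts <- table(states)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1) return(top)
  if (states[3] %in% top) return(states[3])
  top[order(match(top, order))][1]
}

# vectorised fragment states for all windows of one annotated sequence;
# states: per-residue character vector, windows start at 1..(n-3)
window_states <- function(states) {
  n <- length(states)
  if (n < 4) return(character(0))
  vapply(seq_len(n - 3), function(i) fragment_state(states[i:(i + 3)]),
         character(1))
}

smoothed_log_freq <- function(counts, keys, total, pseudocount, key_space) {
  n <- unname(counts[keys])
  n[is.na(n)] <- 0
  log((n + pseudocount) / (total + pseudocount * key_space))
}

# occurrence table from two named count vectors over the same key space
occurrence_table <- function(countsA, countsB, pseudocount, key_space,
                             state = "none", corpus_meta = character()) {
  keys <- sort(unique(c(names(countsA), names(countsB))))
  NA_ <- sum(countsA)
  NB_ <- sum(countsB)
  vals <- stats::setNames(
    as.numeric(smoothed_log_freq(countsA, keys, NA_, pseudocount, key_space) -
                 smoothed_log_freq(countsB, keys, NB_, pseudocount,
                                   key_space)),
    keys)
  default <- log(pseudocount / (NA_ + pseudocount * key_space)) -
    log(pseudocount / (NB_ + pseudocount * key_space))
  new_potential_table("occurrence", state, vals, default, pseudocount,
                      key_space, corpus_meta)
}

# propensity table: per-corpus ln(P(f|state)/P(f)), differenced A - B
propensity_table <- function(countsA_state, countsA_all,
                             countsB_state, countsB_all,
                             pseudocount, key_space, state,
                             corpus_meta = character()) {
  keys <- sort(unique(c(names(countsA_state), names(countsA_all),
                        names(countsB_state), names(countsB_all))))
  lp <- function(cs, ca) {
    smoothed_log_freq(cs, keys, sum(cs), pseudocount, key_space) -
      smoothed_log_freq(ca, keys, sum(ca), pseudocount, key_space)
  }
  vals <- stats::setNames(
    as.numeric(lp(countsA_state, countsA_all) - lp(countsB_state,
                                                   countsB_all)),
    keys)
  d0 <- function(cs, ca) {
    log(pseudocount / (sum(cs) + pseudocount * key_space)) -
      log(pseudocount / (sum(ca) + pseudocount * key_space))
  }
  default <- d0(countsA_state, countsA_all) - d0(countsB_state, countsB_all)
  new_potential_table("propensity", state, vals, default, pseudocount,
                      key_space, corpus_meta)
}

count_by_state <- function(frags, states, state) {
  sel <- frags[states == state]
  if (length(sel) == 0) return(integer(0))
  table(sel)
}

corpus_fragments <- function(corpus, need_states = TRUE) {
  frags <- character(0)
  ss <- character(0)
  ex <- character(0)
  for (k in seq_len(nrow(corpus))) {
    f <- fragments4(corpus$sequence[k])
    if (length(f) == 0) next
    frags <- c(frags, f)
    if (need_states) {
      ss3 <- corpus$ss3[[k]]
      rsa <- corpus$rsa[[k]]
      if (is.null(ss3) || is.null(rsa)) {
        stop(sprintf("corpus protein '%s' lacks ss3/rsa annotation",
                     corpus$id[k]), call. = FALSE)
      }
      e3 <- exposure_states(rsa)$exposure3
      ss <- c(ss, window_states(ss3))
      ex <- c(ex, window_states(e3))
    }
  }
  list(frags = frags, ss = ss, ex = ex)
}

#' Build the sequential fragment-potential set
#'
#' Builds the 13 tables behind the sequential fragment features from two
#' annotated reference corpora: one unconditioned occurrence table (`FBocc`),
#' six state-conditioned occurrence tables (`FBhel` ... `FBint`) and six
#' state-conditioned propensity tables (`FDhel` ... `FDint`). States are the
#' three secondary-structure states and the three exposure classes of
#' [exposure_states()]; a fragment's state is the majority state of its four
#' residues ([fragment_state()]). Building is deterministic: same corpora and
#' parameters give byte-identical serialized tables.
#'
#' @param corpusA,corpusB Annotated protein tables (ss3 and rsa layers set);
#'   nonempty, every sequence at least 4 residues contributes.
#' @param pseudocount Additive smoothing constant, `> 0`.
#' @return A `potential_set` object (named list of `potential_table`s, one
#'   per feature slot).
#' @export
build_potentials <- function(corpusA, corpusB, pseudocount = 1) {
  if (nrow(corpusA) == 0 || nrow(corpusB) == 0) {
    stop("reference corpora must be nonempty", call. = FALSE)
  }
  stopifnot(pseudocount > 0)
  key_space <- 20^4
  a <- corpus_fragments(corpusA)
  b <- corpus_fragments(corpusB)
  if (length(a$frags) == 0 || length(b$frags) == 0) {
    stop("reference corpora contain no tetra-peptide fragments", call. = FALSE)
  }
  meta <- c(sprintf("corpusA_fragments=%d", length(a$frags)),
            sprintf("corpusB_fragments=%d", length(b$frags)))
  cntA <- table(a$frags)
  cntB <- table(b$frags)
  tabs <- list(FBocc = occurrence_table(cntA, cntB, pseudocount, key_space,
                                        "none", meta))
  ss_states <- c(FBhel = "H", FBshe = "E", FBcoi = "C")
  ex_states <- c(FBexp = "exposed", FBbur = "buried", FBint = "intermediate")
  for (nm in names(ss_states)) {
    s <- ss_states[[nm]]
    ca <- count_by_state(a$frags, a$ss, s)
    cb <- count_by_state(b$frags, b$ss, s)
    if (length(ca) == 0 || length(cb) == 0) {
      warning(sprintf("state '%s' has no fragments in a corpus; table is flat", s))
    }
    tabs[[nm]] <- occurrence_table(ca, cb, pseudocount, key_space, s, meta)
  }
  for (nm in names(ex_states)) {
    s <- ex_states[[nm]]
    ca <- count_by_state(a$frags, a$ex, s)
    cb <- count_by_state(b$frags, b$ex, s)
    if (length(ca) == 0 || length(cb) == 0) {
      warning(sprintf("state '%s' has no fragments in a corpus; table is flat", s))
    }
    tabs[[nm]] <- occurrence_table(ca, cb, pseudocount, key_space, s, meta)
  }
  fd <- c(FDhel = "H", FDshe = "E", FDcoi = "C",
          FDexp = "exposed", FDbur = "buried", FDint = "intermediate")
  for (nm in names(fd)) {
    s <- fd[[nm]]
    which_states <- if (s %in% c("H", "E", "C")) "ss" else "ex"
    tabs[[nm]] <- propensity_table(
      count_by_state(a$frags, a[[which_states]], s), cntA,
      count_by_state(b$frags, b[[which_states]], s), cntB,
      pseudocount, key_space, s, meta)
  }
  structure(list(tables = tabs, pseudocount = pseudocount,
                 key_space = key_space),
            class = "potential_set")
}

#' @export
print.potential_set <- function(x, ...) {
  cat(sprintf("<potential_set> %d tables, pseudocount=%g, key space=%d\n",
              length(x$tables), x$pseudocount, x$key_space))
  invisible(x)
}

# state track ("ss" or "ex") a sequential table is conditioned on
table_track <- function(state) {
  if (state %in% c("H", "E", "C")) "ss"
  else if (state %in% c("buried", "intermediate", "exposed")) "ex"
  else "none"
}

# score of a full sequence under one table (sum over all windows, state-
# filtered); used by tests as the brute-force reference and by the public
# scorer
score_sequence <- function(sequence, table, ss3 = NULL, rsa = NULL) {
  frags <- fragments4(sequence)
  if (length(frags) == 0) return(0)
  track <- table_track(table$state)
  if (track == "none") return(sum(lookup_potential(table, frags)))
  st <- if (track == "ss") window_states(ss3)
        else window_states(exposure_states(rsa)$exposure3)
  sel <- st == table$state
  if (!any(sel)) return(0)
  sum(lookup_potential(table, frags[sel]))
}

#' Sequential fragment-potential features
#'
#' The 13 feature values for one mutation record: for each table of the set,
#' the score of the mutant sequence minus the score of the wild-type
#' sequence, where a sequence's score is the sum of table values over its
#' contiguous tetra-peptides (restricted to windows of the table's state).
#' Window states come from the wild-type annotation and are held fixed under
#' mutation, so only the at most `4 * n_subs` windows overlapping a
#' substituted position can differ — the implementation rescores only those —
#' and swapping the two sequences negates every slot exactly.
#'
#' @param wt_seq,mut_seq Equal-length sequences differing at the substituted
#'   positions.
#' @param ss3,rsa Wild-type per-residue annotation layers.
#' @param potentials A `potential_set` from [build_potentials()].
#' @return Named numeric vector of the 13 features.
#' @export
seq_frag_features <- function(wt_seq, mut_seq, ss3, rsa, potentials) {
  stopifnot(inherits(potentials, "potential_set"))
  if (nchar(wt_seq) != nchar(mut_seq)) {
    stop("sequences differ in length", call. = FALSE)
  }
  n <- nchar(wt_seq)
  out <- stats::setNames(numeric(length(SEQFRAG_FEATURES)), SEQFRAG_FEATURES)
  if (n < 4) return(out)
  wt <- strsplit(wt_seq, "")[[1]]
  mu <- strsplit(mut_seq, "")[[1]]
  dpos <- which(wt != mu)
  if (length(dpos) == 0) return(out)
  starts <- sort(unique(unlist(lapply(dpos, function(p) {
    max(1, p - 3):min(n - 3, p)
  }))))
  starts <- starts[starts >= 1 & starts <= n - 3]
  wt_frag <- substring(wt_seq, starts, starts + 3)
  mu_frag <- substring(mut_seq, starts, starts + 3)
  ss_state <- vapply(starts, function(i) fragment_state(ss3[i:(i + 3)]),
                     character(1))
  e3 <- exposure_states(rsa)$exposure3
  ex_state <- vapply(starts, function(i) fragment_state(e3[i:(i + 3)]),
                     character(1))
  for (nm in SEQFRAG_FEATURES) {
    tab <- potentials$tables[[nm]]
    if (is.null(tab)) stop(sprintf("missing potential table '%s'", nm), call. = FALSE)
    track <- table_track(tab$state)
    sel <- switch(track,
                  none = rep(TRUE, length(starts)),
                  ss = ss_state == tab$state,
                  ex = ex_state == tab$state)
    if (!any(sel)) next
    out[nm] <- sum(lookup_potential(tab, mu_frag[sel])) -
      sum(lookup_potential(tab, wt_frag[sel]))
  }
  out
}

#' Serialize and read potential sets
#'
#' Potential sets are written to a single TSV with a `#`-prefixed metadata
#' header (pseudocount, key-space size, per-table kind/state/default) and
#' columns `table`, `fragment`, `value`, keys sorted, so a rebuild from the
#' same corpora is byte-identical.
#'
#' @param potentials A `potential_set`.
#' @param path Output / input path.
#' @return `read_potentials()` returns the reconstructed `potential_set`.
#' @export
write_potentials <- function(potentials, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pseudocount=%.17g", potentials$pseudocount), con)
  writeLines(sprintf("# key_space=%d", potentials$key_space), con)
  for (nm in names(potentials$tables)) {
    t <- potentials$tables[[nm]]
    writeLines(sprintf("# table=%s kind=%s state=%s default=%.17g",
                       nm, t$kind, t$state, t$default), con)
  }
  writeLines("table\tfragment\tvalue", con)
  for (nm in names(potentials$tables)) {
    t <- potentials$tables[[nm]]
    keys <- sort(names(t$values))
    if (length(keys) > 0) {
      writeLines(sprintf("%s\t%s\t%.17g", nm, keys, t$values[keys]), con)
    }
  }
  invisible(path)
}

#' @rdname write_potentials
#' @export
read_potentials <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get1 <- function(key) {
    m <- regmatches(hdr, regexec(paste0("\\b", key, "=([^ ]+)"), hdr))
    vals <- vapply(m[lengths(m) == 2], `[`, "", 2)
    vals
  }
  pseudocount <- as.numeric(get1("pseudocount")[1])
  key_space <- as.numeric(get1("key_space")[1])
  tab_lines <- hdr[grepl("# table=", hdr, fixed = TRUE)]
  meta <- lapply(tab_lines, function(l) {
    m <- regmatches(l, regexec(
      "# table=(\\S+) kind=(\\S+) state=(\\S+) default=(\\S+)", l))[[1]]
    list(name = m[2], kind = m[3], state = m[4], default = as.numeric(m[5]))
  })
  df <- utils::read.table(text = paste(body, collapse = "\n"), sep = "\t",
                          header = TRUE, colClasses = c("character", "character",
                                                        "numeric"))
  tabs <- list()
  for (m in meta) {
    rows <- df[df$table == m$name, , drop = FALSE]
    vals <- stats::setNames(rows$value, rows$fragment)
    tabs[[m$name]] <- new_potential_table(m$kind, m$state, vals, m$default,
                                          pseudocount, key_space)
  }
  structure(list(tables = tabs, pseudocount = pseudocount,
                 key_space = key_space),
            class = "potential_set")
}
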