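#' Add hypothetical reverse mutations
#'
#' For every forward record a hypothetical reverse mutation is created by
#' swapping the wild-type protein and its mutant: the substitution letters
#' are exchanged (`V66A` becomes `A66V`), the ddG is negated (free energy is
#' a state function) and the new record shares the forward record's
#' `pair_id`. The augmented table is perfectly balanced: with no zero-ddG
#' records, stabilizing and destabilizing counts are equal by construction.
#' Calling it on an already-augmented table is an error.
#'
#' @param mutations A forward-only mutation table.
#' @param proteins Protein table (used to re-validate the reverse records).
#' @return Mutation table of twice the size: the forward block followed by
#'   the reverse block in the same order.
#' @export
augment_reverse <- function(mutations, proteins) {
  if (any(mutations$direction == "reverse")) {
    stop("mutation table already contains reverse records", call. = FALSE)
  }
  if (anyDuplicated(mutations$pair_id)) {
    stop("duplicate pair_id in forward records", call. = FALSE)
  }
  rev_subs <- lapply(mutations$subs, function(s) {
    tibble::tibble(wt = s$mut, pos = s$pos, mut = s$wt)
  })
  rev_ddg <- -mutations$ddg
  rev_pair <- mutations$pair_id
  rev <- tibble::tibble(
    protein_id = mutations$protein_id,
    mutations = vapply(rev_subs, format_subs, ""),
    subs = rev_subs,
    ddg = rev_ddg,
    direction = "reverse",
    pair_id = rev_pair
  )
  out <- dplyr::bind_rows(mutations, rev)
  validate_mutations(out, proteins)
  out
}

#' Compute the feature matrix for a mutation table
#'
#' Runs the full feature pipeline on every record and returns one row per
#' record: the record's metadata columns followed by the named feature
#' columns — 41 in structure mode, 34 in sequence mode (the 7 Delaunay
#' features need coordinates). For a hypothetical reverse record the source
#' sequence is the mutant and the target the wild type; the wild-type
#' protein's profile, annotation, and (in structure mode) tessellation are
#' reused under the fixed-conformation assumption, which makes all
#' difference-type features exactly anti-symmetric within a pair and swaps
#' the wild-type/mutant point scores of the evolutionary features.
#'
#' @param mutations A mutation table.
#' @param proteins Protein table with the layers the mode needs: `pssm` and
#'   `ss3`/`rsa` always; `ca` in structure mode.
#' @param potentials Sequential `potential_set` ([build_potentials()]).
#' @param mode `"structure"` or `"sequence"`.
#' @param dt_potentials Delaunay `potential_set` ([build_dt_potentials()]);
#'   required in structure mode.
#' @param edge_cutoff Edge cutoff for the per-protein tessellations.
#' @return Tibble with columns `protein_id`, `mutations`, `ddg`, `direction`,
#'   `pair_id` and the feature columns of [feature_names()].
#' @export
featurize <- function(mutations, proteins, potentials,
                      mode = c("structure", "sequence"),
                      dt_potentials = NULL, edge_cutoff = 10) {
  mode <- match.arg(mode)
  stopifnot(inherits(potentials, "potential_set"))
  if (mode == "structure" && is.null(dt_potentials)) {
    stop("structure mode needs dt_potentials", call. = FALSE)
  }
  ids <- unique(mutations$protein_id)
  tess <- list()
  if (mode == "structure") {
    for (id in ids) {
      ca <- protein_row(proteins, id)$ca[[1]]
      if (is.null(ca)) {
        stop(sprintf("structure mode: protein '%s' has no coordinates", id),
             call. = FALSE)
      }
      tess[[id]] <- delaunay_tessellate(ca, edge_cutoff)
    }
  }
  nms <- feature_names(mode)
  feat <- matrix(NA_real_, nrow(mutations), length(nms),
                 dimnames = list(NULL, nms))
  for (k in seq_len(nrow(mutations))) {
    rec <- mutations[k, ]
    row <- protein_row(proteins, rec$protein_id)
    pssm <- row$pssm[[1]]
    ss3 <- row$ss3[[1]]
    rsa <- row$rsa[[1]]
    if (is.null(pssm)) {
      stop(sprintf("protein '%s' has no profile", rec$protein_id), call. = FALSE)
    }
    if (is.null(ss3) || is.null(rsa)) {
      stop(sprintf("protein '%s' has no ss3/rsa annotation", rec$protein_id),
           call. = FALSE)
    }
    seqs <- record_sequences(rec, proteins)
    if (is.null(seqs)) {
      stop(sprintf("record %d: substitutions inconsistent with sequence", k),
           call. = FALSE)
    }
    subs <- rec$subs[[1]]
    states <- tibble::tibble(pos = seq_along(ss3), ss3 = ss3,
                             exposure2 = exposure_states(rsa)$exposure2)
    v <- c(evo_features(pssm, subs),
           sssa_features(states, subs),
           reldiff_features(seqs$from, seqs$to),
           seq_frag_features(seqs$from, seqs$to, ss3, rsa, potentials))
    if (mode == "structure") {
      v <- c(v, dt_features(seqs$from, seqs$to, tess[[rec$protein_id]],
                            dt_potentials))
    }
    feat[k, ] <- v[nms]
  }
  dplyr::bind_cols(
    mutations[, c("protein_id", "mutations", "ddg", "direction", "pair_id")],
    tibble::as_tibble(feat)
  )
}
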