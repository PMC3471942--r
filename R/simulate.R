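#' Synthetic fixture generators
#'
#' These generators emulate every input the pipeline consumes — sequences,
#' idealised C-alpha traces, sequence profiles, per-residue annotation and
#' mutation tables with a planted, exactly anti-symmetric ddG signal — so the
#' full workflow runs and is testable with no external data. All draws flow
#' from an explicit integer seed; the caller's random state is restored on
#' exit, and the same seed always reproduces the same fixture.
#'
#' @name simulate
NULL

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' @rdname simulate
#' @param length Sequence length, `>= 10`.
#' @param seed Integer seed.
#' @param freq Named residue-frequency table for sampling.
#' @return `sim_protein()`: an amino-acid string.
#' @export
sim_protein <- function(length, seed, freq = AA_FREQ) {
  if (length < 10) stop("length must be >= 10", call. = FALSE)
  with_seed(seed, paste(sample(names(freq), length, replace = TRUE,
                               prob = freq), collapse = ""))
}

#' @rdname simulate
#' @param n Number of proteins.
#' @param lengths Sequence length(s), recycled over proteins.
#' @return `sim_proteins()`: a protein table with ids `sp001`, `sp002`, ...
#' @export
sim_proteins <- function(n, lengths = 100, seed = 1) {
  lengths <- rep_len(lengths, n)
  seqs <- vapply(seq_len(n), function(k) sim_protein(lengths[k], seed + k), "")
  protein_table(sprintf("sp%03d", seq_len(n)), seqs)
}

#' @rdname simulate
#' @param sequence Amino-acid string the trace is generated for.
#' @param motif `"helix"` for an ideal alpha-helical C-alpha trace (rise
#'   1.5 Angstrom per residue, radius 2.3 Angstrom, 100 degrees per residue,
#'   all residues labelled `H`, plus a 0.01-Angstrom general-position
#'   jitter) or `"walk"` for a self-avoiding 3.8-Angstrom-step chain
#'   labelled `C`.
#' @return `sim_structure()`: list with `ca` (n x 3 matrix), `ss3` and `rsa`
#'   (uniform in `[0, 1]`).
#' @export
sim_structure <- function(sequence, motif = c("helix", "walk"), seed = 1) {
  motif <- match.arg(motif)
  n <- nchar(sequence)
  with_seed(seed, {
    if (motif == "helix") {
      th <- (seq_len(n) - 1) * 100 * pi / 180
      ca <- cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * (seq_len(n) - 1))
      ca <- ca + matrix(stats::rnorm(3 * n, sd = 0.01), ncol = 3)
      ss3 <- rep("H", n)
    } else {
      ca <- matrix(0, n, 3)
      for (i in 2:n) {
        repeat {
          d <- stats::rnorm(3)
          step <- 3.8 * d / sqrt(sum(d^2))
          cand <- ca[i - 1, ] + step
          dmin <- if (i > 2) {
            min(sqrt(rowSums(sweep(ca[1:(i - 2), , drop = FALSE], 2,
                                   cand)^2)))
          } else Inf
          if (dmin > 3.0) break
        }
        ca[i, ] <- cand
      }
      ss3 <- rep("C", n)
    }
    list(ca = ca, ss3 = ss3, rsa = stats::runif(n))
  })
}

#' @rdname simulate
#' @param concentration Strength of the native-residue signal in the
#'   profile; the native residue's sampling weight is `exp(concentration)`
#'   against 1 for the others.
#' @return `sim_pssm()`: a `pssm` object; weighted rows are multinomial
#'   percentage counts (sum 100) and log-odds are integers
#'   `round(2 * log2(((count + 1) / 104) / background))`.
#' @export
sim_pssm <- function(sequence, concentration = 3, seed = 1) {
  if (concentration <= 0) stop("concentration must be > 0", call. = FALSE)
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  with_seed(seed, {
    weighted <- matrix(0, n, 20, dimnames = list(NULL, AA_ALPHABET))
    for (i in seq_len(n)) {
      w <- rep(1, 20)
      w[match(chars[i], AA_ALPHABET)] <- exp(concentration)
      weighted[i, ] <- as.vector(stats::rmultinom(1, 100, w / sum(w)))
    }
    log_odds <- round(2 * log2(((weighted + 1) / 104) /
                                 matrix(AA_FREQ[AA_ALPHABET], n, 20,
                                        byrow = TRUE)))
    new_pssm(log_odds, weighted, residues = chars)
  })
}

#' Decorate a protein table with simulated layers
#'
#' Adds a simulated structure (or walk), annotation and profile to every
#' protein in the table; per-protein seeds are derived from `seed`.
#'
#' @inheritParams simulate
#' @param proteins A protein table.
#' @param motif Trace motif per [sim_structure()].
#' @return The protein table with `ca`, `ss3`, `rsa` and `pssm` filled.
#' @export
sim_layers <- function(proteins, motif = "helix", concentration = 3,
                       seed = 1) {
  for (k in seq_len(nrow(proteins))) {
    st <- sim_structure(proteins$sequence[k], motif, seed = seed + 7919 * k)
    proteins <- add_structure(proteins, proteins$id[k], st$ca,
                              ss3 = st$ss3, rsa = st$rsa)
    proteins <- add_profile(proteins, proteins$id[k],
                            sim_pssm(proteins$sequence[k], concentration,
                                     seed = seed + 104729 * k))
  }
  proteins
}

#' Simulate reference corpora for potential building
#'
#' Two corpora with tilted residue compositions stand in for the
#' thermophile/mesophile contrast the potentials are learned from: `tilt`
#' up-weights charged residues (R, K, H, D, E), as thermophilic proteomes
#' are enriched in them; `tilt = 0` reproduces the background composition.
#'
#' @inheritParams simulate
#' @param n Number of corpus sequences.
#' @param lengths Sequence length(s).
#' @param tilt Log-weight added to charged residues.
#' @param motif Trace motif for the corpus structures.
#' @return An annotated protein table usable as a corpus.
#' @export
sim_corpus <- function(n, lengths = 80, tilt = 0, motif = "helix", seed = 1) {
  freq <- AA_FREQ
  freq[AA_SET_CHAR] <- freq[AA_SET_CHAR] * exp(tilt)
  freq <- freq / sum(freq)
  lengths <- rep_len(lengths, n)
  seqs <- vapply(seq_len(n), function(k) {
    sim_protein(lengths[k], seed + 31 * k, freq = freq)
  }, "")
  corpus <- protein_table(sprintf("c%s%03d", if (tilt >= 0) "A" else "B",
                                  seq_len(n)), seqs)
  # varied annotation so all six states occur
  for (k in seq_len(nrow(corpus))) {
    st <- sim_structure(corpus$sequence[k], motif, seed = seed + 53 * k)
    ss3 <- with_seed(seed + 97 * k, sample(c("H", "E", "C"), lengths[k],
                                           replace = TRUE,
                                           prob = c(0.4, 0.25, 0.35)))
    corpus <- add_structure(corpus, corpus$id[k], st$ca, ss3 = ss3,
                            rsa = st$rsa)
  }
  corpus
}

#' Simulate a mutation table with a planted anti-symmetric ddG signal
#'
#' Draws forward mutation records (protein chosen uniformly, distinct
#' positions, mutant letter by background frequency) and assigns each a ddG
#' from a planted linear model over difference-type features:
#' `ddg = sum(weights * features) + Normal(0, noise_sd)`. Because every
#' weighted feature is exactly anti-symmetric under wild-type/mutant swap,
#' the planted ground truth obeys the thermodynamic reverse-mutation
#' identity. When `noise_sd` is `NULL` it is set to
#' `sd(signal) / snr`, fixing the signal-to-noise ratio.
#'
#' @inheritParams simulate
#' @param proteins Annotated protein table ([sim_layers()]).
#' @param n_records Number of forward records.
#' @param potentials,dt_potentials Potential sets used to compute the
#'   planted features (DT set only needed if a weight names a DT feature).
#' @param weights Named numeric vector over difference-type feature names.
#' @param noise_sd Noise standard deviation (kcal/mol); `NULL` = from `snr`.
#' @param snr Signal-to-noise ratio used when `noise_sd` is `NULL`.
#' @param multiplicity 1, 2 or `"mixed"` substitution sites per record.
#' @return List: `mutations` (forward mutation table), `truth` (weights,
#'   `noise_sd`, per-record `signal`).
#' @export
sim_mutations <- function(proteins, n_records, potentials,
                          weights = c(FBocc = 1, SMAL = 30, TINY = -20,
                                      dASA = 0.15, pIa = -3),
                          dt_potentials = NULL, noise_sd = NULL, snr = 2,
                          multiplicity = 1, seed = 1) {
  stopifnot(all(names(weights) %in% DIFF_FEATURES))
  needs_dt <- any(names(weights) %in% DT_FEATURES)
  mode <- if (needs_dt) "structure" else "sequence"
  recs <- with_seed(seed, {
    lapply(seq_len(n_records), function(k) {
      i <- sample.int(nrow(proteins), 1)
      seqc <- strsplit(proteins$sequence[i], "")[[1]]
      m <- if (identical(multiplicity, "mixed")) sample(1:2, 1) else multiplicity
      if (m > length(seqc)) stop("substitution count exceeds sequence length",
                                 call. = FALSE)
      pos <- sort(sample.int(length(seqc), m))
      mut <- vapply(pos, function(p) {
        sample(setdiff(AA_ALPHABET, seqc[p]), 1,
               prob = AA_FREQ[setdiff(AA_ALPHABET, seqc[p])])
      }, "")
      tibble::tibble(protein_id = proteins$id[i],
                     subs = list(tibble::tibble(wt = seqc[pos], pos = pos,
                                                mut = mut)))
    })
  })
  recs <- dplyr::bind_rows(recs)
  mut <- tibble::tibble(
    protein_id = recs$protein_id,
    mutations = vapply(recs$subs, format_subs, ""),
    subs = recs$subs,
    ddg = 0,
    direction = "forward",
    pair_id = sprintf("m%05d", seq_len(n_records))
  )
  feats <- featurize(mut, proteins, potentials, mode,
                     dt_potentials = dt_potentials)
  x <- as.matrix(feats[, names(weights)])
  signal <- as.vector(x %*% weights)
  if (is.null(noise_sd)) noise_sd <- stats::sd(signal) / snr
  mut$ddg <- signal + with_seed(seed + 1L,
                                stats::rnorm(n_records, sd = noise_sd))
  list(mutations = mut,
       truth = list(weights = weights, noise_sd = noise_sd, signal = signal,
                    seed = seed))
}

#' Write a complete synthetic fixture bundle
#'
#' Generates proteins, layers, corpora-derived potential sets and a planted
#' mutation table, and writes every external format the pipeline reads into
#' `dir`: `proteins.fasta`, per-protein `*.pssm` (ASCII profile layout),
#' `*.pdb` (C-alpha ATOM records), `*.ann.tsv` (predicted-annotation TSV),
#' `mutations.tsv`, `potentials.tsv`, `dt_potentials.tsv` and
#' `truth.json`.
#'
#' @inheritParams sim_mutations
#' @param dir Output directory.
#' @param n_proteins,lengths,n_records,multiplicity Fixture dimensions.
#' @return Invisibly, a list with the in-memory `proteins`, `mutations`,
#'   `potentials`, `dt_potentials` and `truth`.
#' @export
sim_bundle <- function(dir, n_proteins = 8, lengths = 80, n_records = 100,
                       multiplicity = 1, snr = 2, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  proteins <- sim_proteins(n_proteins, lengths, seed = seed)
  proteins <- sim_layers(proteins, motif = "helix", seed = seed + 1000L)
  corpusA <- sim_corpus(12, 80, tilt = 0.4, seed = seed + 2000L)
  corpusB <- sim_corpus(12, 80, tilt = -0.4, seed = seed + 3000L)
  potentials <- build_potentials(corpusA, corpusB)
  dt_potentials <- build_dt_potentials(corpusA, corpusB)
  sim <- sim_mutations(proteins, n_records, potentials,
                       dt_potentials = dt_potentials,
                       multiplicity = multiplicity, snr = snr,
                       seed = seed + 4000L)
  write_fasta(proteins, file.path(dir, "proteins.fasta"))
  for (k in seq_len(nrow(proteins))) {
    id <- proteins$id[k]
    write_pssm(proteins$pssm[[k]], file.path(dir, paste0(id, ".pssm")))
    write_pdb_ca(proteins$ca[[k]], proteins$sequence[k],
                 file.path(dir, paste0(id, ".pdb")))
    write_annotation_tsv(proteins$ss3[[k]], proteins$rsa[[k]],
                         file.path(dir, paste0(id, ".ann.tsv")))
  }
  write_mutations(sim$mutations, file.path(dir, "mutations.tsv"))
  write_potentials(potentials, file.path(dir, "potentials.tsv"))
  write_potentials(dt_potentials, file.path(dir, "dt_potentials.tsv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(weights = as.list(sim$truth$weights),
           noise_sd = sim$truth$noise_sd, seed = seed),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(list(proteins = proteins, mutations = sim$mutations,
                 potentials = potentials, dt_potentials = dt_potentials,
                 truth = sim$truth))
}

#' Writers for the external fixture formats
#'
#' Counterparts of the readers: FASTA, ASCII profile matrix, C-alpha-only
#' PDB `ATOM` records and the 3-column predicted-annotation TSV.
#'
#' @param proteins Protein table (`write_fasta`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(stats::setNames(proteins$sequence,
                                                 proteins$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname write_fasta
#' @param pssm A `pssm` object.
#' @export
write_pssm <- function(pssm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", "Last position-specific scoring matrix computed",
               paste0("            ", paste(sprintf("%3s", AA_ALPHABET),
                                            collapse = " "), "  ",
                      paste(sprintf("%3s", AA_ALPHABET), collapse = " "))),
             con)
  res <- pssm$residues
  if (is.null(res)) res <- rep("X", nrow(pssm$log_odds))
  for (i in seq_len(nrow(pssm$log_odds))) {
    writeLines(paste0(
      sprintf("%5d %s  ", i, res[i]),
      paste(sprintf("%3d", as.integer(pssm$log_odds[i, ])), collapse = " "),
      "  ",
      paste(sprintf("%3d", as.integer(pssm$weighted[i, ])), collapse = " "),
      sprintf("  %5.2f %9.2f", 0, 0)
    ), con)
  }
  invisible(path)
}

#' @rdname write_fasta
#' @param ca Coordinate matrix (n x 3).
#' @param sequence Amino-acid string matching `ca` rows.
#' @export
write_pdb_ca <- function(ca, sequence, path) {
  three <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
  chars <- strsplit(sequence, "")[[1]]
  stopifnot(length(chars) == nrow(ca))
  lines <- sprintf(
    "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(ca)), three[chars], seq_len(nrow(ca)),
    ca[, 1], ca[, 2], ca[, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' @rdname write_fasta
#' @param ss3,rsa Per-residue annotation vectors.
#' @export
write_annotation_tsv <- function(ss3, rsa, path) {
  readr::write_tsv(tibble::tibble(pos = seq_along(ss3), ss3 = ss3,
                                  rsa = rsa), path)
  invisible(path)
}
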