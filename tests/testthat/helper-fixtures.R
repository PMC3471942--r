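# Shared fixtures (built once per test run) and independent oracles.

test_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      prot <- sim_proteins(8, 70, seed = 201)
      prot <- sim_layers(prot, motif = "helix", seed = 202)
      cA <- sim_corpus(10, 60, tilt = 0.4, seed = 203)
      cB <- sim_corpus(10, 60, tilt = -0.4, seed = 204)
      pot <- build_potentials(cA, cB)
      dtp <- build_dt_potentials(cA, cB)
      cache <<- list(proteins = prot, corpusA = cA, corpusB = cB,
                     potentials = pot, dt_potentials = dtp)
    }
    cache
  }
})

# --- independent oracles ----------------------------------------------------

# AUC as the fraction of concordant (positive, negative) pairs, ties half
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# two-sample KS statistic as the exhaustive sup of |F1 - F2| over all pooled
# points
oracle_ks_D <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  max(abs(vapply(grid, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# whole-sequence rescoring of the 13 sequential fragment features
oracle_seq_frag_full <- function(wt_seq, mut_seq, ss3, rsa, potentials) {
  vapply(ddgforest:::SEQFRAG_FEATURES, function(nm) {
    tab <- potentials$tables[[nm]]
    ddgforest:::score_sequence(mut_seq, tab, ss3 = ss3, rsa = rsa) -
      ddgforest:::score_sequence(wt_seq, tab, ss3 = ss3, rsa = rsa)
  }, numeric(1))
}

# whole-structure rescoring of the 7 Delaunay features
oracle_dt_full <- function(wt_seq, mut_seq, tess, dtp) {
  score <- function(seq) {
    chars <- strsplit(seq, "")[[1]]
    vapply(names(dtp$tables), function(nm) {
      tab <- dtp$tables[[nm]]
      cls <- c(FBDTocc = "none", FBDTD43 = "D43", FBDTD2 = "D2",
               FBDTD1 = "D1", FBDTDD43 = "D43", FBDTDD2 = "D2",
               FBDTDD1 = "D1")[nm]
      sel <- if (cls == "none") rep(TRUE, nrow(tess)) else tess$class == cls
      if (!any(sel)) return(0)
      keys <- apply(cbind(tess$v1, tess$v2, tess$v3, tess$v4)[sel, ,
                                                              drop = FALSE],
                    1, function(v) paste(sort(chars[v]), collapse = ""))
      sum(ddgforest:::lookup_potential(tab, keys))
    }, numeric(1))
  }
  score(mut_seq) - score(wt_seq)
}

# brute-force Delaunay: all 4-subsets with an empty circumsphere
oracle_delaunay <- function(pts) {
  n <- nrow(pts)
  combs <- utils::combn(n, 4)
  keep <- list()
  for (k in seq_len(ncol(combs))) {
    idx <- combs[, k]
    a <- pts[idx[1], ]
    m <- rbind(pts[idx[2], ] - a, pts[idx[3], ] - a, pts[idx[4], ] - a)
    if (abs(det(m)) < 1e-9) next
    ctr <- a + solve(m, 0.5 * rowSums(m^2))
    r2 <- sum((ctr - a)^2)
    d2 <- rowSums(sweep(pts, 2, ctr)^2)
    if (all(d2[-idx] > r2 * (1 - 1e-12))) keep[[length(keep) + 1]] <- idx
  }
  do.call(rbind, keep)
}

# continuity class straight from its definition, by enumeration of runs
oracle_continuity <- function(pos) {
  pos <- sort(pos)
  has_run3 <- any(vapply(seq_len(2), function(i) {
    all(diff(pos[i:(i + 2)]) == 1)
  }, logical(1)))
  if (has_run3) return("D43")
  if (any(diff(pos) == 1)) return("D2")
  "D1"
}

# random substitution set on a protein row
random_subs <- function(sequence, n_sites) {
  chars <- strsplit(sequence, "")[[1]]
  pos <- sort(sample.int(length(chars), n_sites))
  tibble::tibble(
    wt = chars[pos], pos = pos,
    mut = vapply(pos, function(p) sample(setdiff(AA_ALPHABET, chars[p]), 1),
                 "")
  )
}
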