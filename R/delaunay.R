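#' Delaunay tessellation of a C-alpha trace
#'
#' Computes the 3-D Delaunay tetrahedralization of the residue C-alpha
#' coordinates by incremental insertion (Bowyer-Watson): points are inserted
#' one at a time into an enclosing super-tetrahedron, every tetrahedron whose
#' circumsphere contains the new point is removed and the cavity is re-filled
#' with tetrahedra on the new point. Cells touching the super-tetrahedron are
#' discarded at the end, as are cells with any edge longer than `edge_cutoff`
#' (sliver cells spanning the convex hull carry no packing information; the
#' default 10 Angstrom keeps physically contacting residue quadruples).
#' Residues without coordinates (`NA` rows) are skipped; returned indices
#' refer to the original residue numbering. The result depends only on the
#' point geometry, so it is invariant under rigid-body motion of the
#' structure.
#'
#' @param ca Numeric matrix (residues x 3) of coordinates in Angstrom.
#' @param edge_cutoff Maximum allowed edge length (Angstrom); `Inf` keeps all
#'   cells.
#' @return A tibble with columns `v1 < v2 < v3 < v4` (1-based residue
#'   indices) and `class` (see [continuity_class()]), sorted lexicographically.
#' @export
delaunay_tessellate <- function(ca, edge_cutoff = 10) {
  ca <- as.matrix(ca)
  stopifnot(ncol(ca) == 3)
  keep <- which(stats::complete.cases(ca))
  pts <- ca[keep, , drop = FALSE]
  n <- nrow(pts)
  if (n < 4) stop("need at least 4 residues with coordinates", call. = FALSE)
  if (anyDuplicated(round(pts, 9)) > 0) {
    stop("duplicate C-alpha coordinates", call. = FALSE)
  }
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))$d
  if (sv[3] < 1e-8 * max(sv[1], 1)) {
    stop("coordinates are (nearly) coplanar; tessellation is degenerate",
         call. = FALSE)
  }
  cells <- bowyer_watson(pts)
  # map back to original residue indices, drop long-edged cells
  if (is.finite(edge_cutoff)) {
    ok <- vapply(seq_len(nrow(cells)), function(t) {
      v <- cells[t, ]
      e <- utils::combn(4, 2)
      all(sqrt(colSums((t(pts[v[e[1, ]], ]) - t(pts[v[e[2, ]], ]))^2)) <=
            edge_cutoff)
    }, logical(1))
    cells <- cells[ok, , drop = FALSE]
  }
  if (nrow(cells) == 0) {
    return(tibble::tibble(v1 = integer(), v2 = integer(), v3 = integer(),
                          v4 = integer(), class = character()))
  }
  cells <- matrix(keep[cells], ncol = 4)
  cells <- t(apply(cells, 1, sort))
  cells <- cells[order(cells[, 1], cells[, 2], cells[, 3], cells[, 4]), ,
                 drop = FALSE]
  tibble::tibble(
    v1 = as.integer(cells[, 1]), v2 = as.integer(cells[, 2]),
    v3 = as.integer(cells[, 3]), v4 = as.integer(cells[, 4]),
    class = apply(cells, 1, continuity_class)
  )
}

# determinant insphere test: negative when p lies strictly inside the
# circumsphere of (positively oriented) tetrahedron tet. Centered at p, so
# it stays well-conditioned for sliver cells whose circumradius is huge.
insphere_det <- function(tet, p) {
  m <- sweep(tet, 2, p)
  m4 <- cbind(m, rowSums(m^2))
  d <- det(m4)
  orient <- det(rbind(tet[2, ] - tet[1, ], tet[3, ] - tet[1, ],
                      tet[4, ] - tet[1, ]))
  if (orient < 0) d <- -d
  d
}

# circumsphere (center, squared radius) of a tetrahedron; flat cells get an
# infinite sphere so they are always broken up by the next insertion
circumsphere <- function(p) {
  a <- p[1, ]
  m <- rbind(p[2, ] - a, p[3, ] - a, p[4, ] - a)
  rhs <- 0.5 * rowSums(m^2)
  det_m <- det(m)
  if (!is.finite(det_m) || abs(det_m) < 1e-12) {
    return(list(c = a, r2 = Inf))
  }
  x <- solve(m, rhs)
  list(c = a + x, r2 = sum(x^2))
}

bowyer_watson <- function(pts) {
  n <- nrow(pts)
  lo <- apply(pts, 2, min)
  hi <- apply(pts, 2, max)
  ctr <- (lo + hi) / 2
  # far enough that no empty circumsphere of a real cell (even a hull
  # sliver with a huge circumradius) can reach a super-vertex
  R <- max(hi - lo, 1) * 1e6
  super <- rbind(ctr + c(0, 0, 3) * R,
                 ctr + c(-2.4, -1.4, -1) * R,
                 ctr + c(2.4, -1.4, -1) * R,
                 ctr + c(0, 2.8, -1) * R)
  allp <- rbind(pts, super)
  tets <- matrix(n + 1:4, nrow = 1)
  cs <- circumsphere(allp[tets[1, ], ])
  centers <- matrix(cs$c, nrow = 1)
  r2 <- cs$r2
  for (i in seq_len(n)) {
    p <- allp[i, ]
    d2 <- (centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2 +
      (centers[, 3] - p[3])^2
    # fast sphere prefilter; borderline or flat cells go to the determinant
    inside <- d2 < r2 * (1 - 1e-9)
    unsure <- which(!inside & (!is.finite(r2) | d2 < r2 * (1 + 1e-9)))
    for (u in unsure) {
      inside[u] <- insphere_det(allp[tets[u, ], , drop = FALSE], p) < 0
    }
    bad <- which(inside)
    if (length(bad) == 0) stop("tessellation failed: point outside all circumspheres",
                               call. = FALSE)
    # boundary of the cavity: faces appearing in exactly one bad tetrahedron
    faces <- matrix(0L, 4 * length(bad), 3)
    pick <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
    for (b in seq_along(bad)) {
      v <- sort(tets[bad[b], ])
      faces[4 * (b - 1) + 1:4, ] <- matrix(v[pick], ncol = 3)
    }
    key <- paste(faces[, 1], faces[, 2], faces[, 3])
    keep_face <- faces[!(key %in% key[duplicated(key)]), , drop = FALSE]
    tets <- tets[-bad, , drop = FALSE]
    centers <- centers[-bad, , drop = FALSE]
    r2 <- r2[-bad]
    for (f in seq_len(nrow(keep_face))) {
      newt <- c(keep_face[f, ], i)
      cs <- circumsphere(allp[newt, ])
      tets <- rbind(tets, newt)
      centers <- rbind(centers, cs$c)
      r2 <- c(r2, cs$r2)
    }
  }
  real <- tets[apply(tets <= n, 1, all), , drop = FALSE]
  if (nrow(real) == 0) stop("tessellation produced no cells", call. = FALSE)
  unname(real)
}

#' Sequence-continuity class of a four-residue tetrahedron
#'
#' Classifies a sorted 4-tuple of residue indices by how sequence-local it
#' is: `D43` if it contains a run of at least 3 consecutive indices, `D2` if
#' it contains at least one adjacent pair but no such run, `D1` if no two
#' indices are sequence-adjacent.
#'
#' @param positions Sorted distinct 1-based residue indices (length 4).
#' @return `"D43"`, `"D2"` or `"D1"`.
#' @export
continuity_class <- function(positions) {
  stopifnot(length(positions) == 4, !is.unsorted(positions, strictly = TRUE))
  adj <- diff(positions) == 1
  if ((adj[1] && adj[2]) || (adj[2] && adj[3])) return("D43")
  if (any(adj)) return("D2")
  "D1"
}

dt_key <- function(letters4) {
  paste(sort(letters4), collapse = "")
}

corpus_dt_fragments <- function(corpus, edge_cutoff) {
  keys <- character(0)
  cls <- character(0)
  for (k in seq_len(nrow(corpus))) {
    ca <- corpus$ca[[k]]
    if (is.null(ca)) {
      stop(sprintf("corpus protein '%s' lacks coordinates", corpus$id[k]),
           call. = FALSE)
    }
    tess <- delaunay_tessellate(ca, edge_cutoff)
    if (nrow(tess) == 0) next
    chars <- strsplit(corpus$sequence[k], "")[[1]]
    kk <- vapply(seq_len(nrow(tess)), function(t) {
      dt_key(chars[c(tess$v1[t], tess$v2[t], tess$v3[t], tess$v4[t])])
    }, character(1))
    keys <- c(keys, kk)
    cls <- c(cls, tess$class)
  }
  list(keys = keys, cls = cls)
}

#' Build the Delaunay fragment-potential set
#'
#' Builds the 7 tables behind the spatial fragment features from two
#' reference corpora carrying C-alpha coordinates: one unconditioned
#' occurrence table (`FBDTocc`), three occurrence tables conditioned on the
#' continuity class (`FBDTD43`, `FBDTD2`, `FBDTD1`) and three class-
#' conditioned propensity tables (`FBDTDD43`, `FBDTDD2`, `FBDTDD1`). The
#' fragment key is the unordered composition of the four residues (sorted
#' letters; 8855 possible keys) since spatial neighbours carry no canonical
#' order. The occurrence form is the same smoothed log-ratio as the
#' sequential tables.
#'
#' @param corpusA,corpusB Protein tables with `ca` layers set.
#' @param pseudocount Additive smoothing constant, `> 0`.
#' @param edge_cutoff Edge-length cutoff passed to [delaunay_tessellate()].
#' @return A `potential_set` with 7 tables.
#' @export
build_dt_potentials <- function(corpusA, corpusB, pseudocount = 1,
                                edge_cutoff = 10) {
  if (nrow(corpusA) == 0 || nrow(corpusB) == 0) {
    stop("reference corpora must be nonempty", call. = FALSE)
  }
  key_space <- choose(23, 4)  # multisets of size 4 from 20 letters: 8855
  a <- corpus_dt_fragments(corpusA, edge_cutoff)
  b <- corpus_dt_fragments(corpusB, edge_cutoff)
  meta <- c(sprintf("corpusA_cells=%d", length(a$keys)),
            sprintf("corpusB_cells=%d", length(b$keys)))
  cntA <- table(a$keys)
  cntB <- table(b$keys)
  tabs <- list(FBDTocc = occurrence_table(cntA, cntB, pseudocount, key_space,
                                          "none", meta))
  for (cl in c("D43", "D2", "D1")) {
    ca <- count_by_state(a$keys, a$cls, cl)
    cb <- count_by_state(b$keys, b$cls, cl)
    tabs[[paste0("FBDT", cl)]] <-
      occurrence_table(ca, cb, pseudocount, key_space, cl, meta)
    tabs[[paste0("FBDTD", cl)]] <-
      propensity_table(ca, cntA, cb, cntB, pseudocount, key_space, cl, meta)
  }
  structure(list(tables = tabs, pseudocount = pseudocount,
                 key_space = key_space),
            class = "potential_set")
}

#' Delaunay fragment features for one mutation record
#'
#' The 7 spatial feature values: for each Delaunay table, the score of the
#' mutant minus the score of the wild type, where a sequence's score under a
#' table is the sum of table values over the tetrahedra of the tessellation
#' (restricted to the table's continuity class). Coordinates — hence the
#' tessellation and every cell's class — are held fixed under mutation, so
#' only cells containing a substituted residue contribute and the features
#' are exactly anti-symmetric under sequence swap.
#'
#' @param wt_seq,mut_seq Equal-length sequences.
#' @param tessellation Result of [delaunay_tessellate()] on the wild-type
#'   structure.
#' @param dt_potentials A `potential_set` from [build_dt_potentials()].
#' @return Named numeric vector of the 7 features.
#' @export
dt_features <- function(wt_seq, mut_seq, tessellation, dt_potentials) {
  stopifnot(inherits(dt_potentials, "potential_set"))
  out <- stats::setNames(numeric(length(DT_FEATURES)), DT_FEATURES)
  wt <- strsplit(wt_seq, "")[[1]]
  mu <- strsplit(mut_seq, "")[[1]]
  dpos <- which(wt != mu)
  if (length(dpos) == 0 || nrow(tessellation) == 0) return(out)
  vm <- cbind(tessellation$v1, tessellation$v2, tessellation$v3,
              tessellation$v4)
  hit <- apply(matrix(vm %in% dpos, ncol = 4), 1, any)
  if (!any(hit)) return(out)
  vm <- vm[hit, , drop = FALSE]
  cls <- tessellation$class[hit]
  wt_key <- apply(vm, 1, function(v) dt_key(wt[v]))
  mu_key <- apply(vm, 1, function(v) dt_key(mu[v]))
  spec <- list(FBDTocc = "none", FBDTD43 = "D43", FBDTD2 = "D2",
               FBDTD1 = "D1", FBDTDD43 = "D43", FBDTDD2 = "D2",
               FBDTDD1 = "D1")
  for (nm in names(spec)) {
    tab <- dt_potentials$tables[[nm]]
    if (is.null(tab)) stop(sprintf("missing potential table '%s'", nm), call. = FALSE)
    sel <- if (spec[[nm]] == "none") rep(TRUE, length(cls)) else cls == spec[[nm]]
    if (!any(sel)) next
    out[nm] <- sum(lookup_potential(tab, mu_key[sel])) -
      sum(lookup_potential(tab, wt_key[sel]))
  }
  out
}
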