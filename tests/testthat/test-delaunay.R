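test_that("tessellation handles minimal and degenerate inputs", {
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  out <- delaunay_tessellate(tet, edge_cutoff = Inf)
  expect_equal(nrow(out), 1)
  expect_equal(unlist(out[1, 1:4], use.names = FALSE), 1:4)

  set.seed(70)
  coplanar <- cbind(matrix(runif(8), 4, 2), 0)
  expect_error(delaunay_tessellate(coplanar), "coplanar")
  expect_error(delaunay_tessellate(tet[c(1, 1, 2, 3), ]), "duplicate")
  expect_error(delaunay_tessellate(tet[1:3, ]), "at least 4")
})

test_that("tessellation equals the empty-circumsphere enumeration oracle", {
  set.seed(71)
  for (rep in 1:6) {
    n <- sample(5:10, 1)
    pts <- matrix(runif(3 * n, 0, 10), ncol = 3)
    got <- delaunay_tessellate(pts, edge_cutoff = Inf)
    ref <- oracle_delaunay(pts)
    key <- function(m) sort(apply(m, 1, paste, collapse = "-"))
    expect_equal(key(as.matrix(got[, 1:4])), key(ref))
  }
})

test_that("tessellation is invariant under rigid-body motion", {
  set.seed(72)
  pts <- matrix(runif(3 * 25, 0, 15), ncol = 3)
  base <- delaunay_tessellate(pts, edge_cutoff = Inf)
  for (rep in 1:5) {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    moved <- pts %*% q + matrix(rnorm(3, sd = 20), nrow(pts), 3, byrow = TRUE)
    got <- delaunay_tessellate(moved, edge_cutoff = Inf)
    expect_equal(got[, 1:4], base[, 1:4])
  }
})

test_that("every tetrahedron gets exactly one continuity class", {
  expect_equal(continuity_class(c(5, 6, 7, 20)), "D43")
  expect_equal(continuity_class(c(5, 6, 20, 30)), "D2")
  expect_equal(continuity_class(c(5, 10, 20, 30)), "D1")
  expect_equal(continuity_class(c(1, 2, 3, 4)), "D43")
  expect_equal(continuity_class(c(5, 6, 8, 9)), "D2")

  # definition-enumeration oracle over all 4-subsets of 1..12
  combs <- utils::combn(12, 4)
  for (k in seq_len(ncol(combs))) {
    expect_equal(continuity_class(combs[, k]), oracle_continuity(combs[, k]))
  }

  # partition over random point clouds
  set.seed(73)
  for (n in c(20, 60, 100)) {
    pts <- matrix(runif(3 * n, 0, 20), ncol = 3)
    tess <- delaunay_tessellate(pts, edge_cutoff = Inf)
    expect_true(all(tess$class %in% c("D43", "D2", "D1")))
    expect_equal(sum(table(tess$class)), nrow(tess))
  }
})

test_that("edge cutoff removes hull slivers but keeps local cells", {
  w <- test_world()
  ca <- w$proteins$ca[[1]]
  full <- delaunay_tessellate(ca, edge_cutoff = Inf)
  cut <- delaunay_tessellate(ca, edge_cutoff = 10)
  expect_lte(nrow(cut), nrow(full))
  expect_gt(nrow(cut), 0)
  key <- function(t) paste(t$v1, t$v2, t$v3, t$v4)
  expect_true(all(key(cut) %in% key(full)))
})

test_that("Delaunay features match whole-structure rescoring and are anti-symmetric", {
  w <- test_world()
  set.seed(74)
  prot <- w$proteins
  for (rep in 1:20) {
    i <- sample(nrow(prot), 1)
    tess <- delaunay_tessellate(prot$ca[[i]])
    wt <- prot$sequence[i]
    subs <- random_subs(wt, sample(1:2, 1))
    mu <- apply_subs(wt, subs)
    fast <- dt_features(wt, mu, tess, w$dt_potentials)
    full <- oracle_dt_full(wt, mu, tess, w$dt_potentials)
    expect_equal(fast, full[names(fast)])
    expect_identical(fast, -dt_features(mu, wt, tess, w$dt_potentials))
  }

  # identity and isolated-site locality
  wt <- prot$sequence[1]
  tess <- delaunay_tessellate(prot$ca[[1]])
  expect_equal(unname(dt_features(wt, wt, tess, w$dt_potentials)), rep(0, 7))
  lonely <- setdiff(seq_len(nchar(wt)),
                    c(tess$v1, tess$v2, tess$v3, tess$v4))
  if (length(lonely) > 0) {
    subs <- tibble::tibble(wt = substr(wt, lonely[1], lonely[1]),
                           pos = lonely[1], mut = "W")
    if (subs$wt != "W") {
      mu <- apply_subs(wt, subs)
      expect_equal(unname(dt_features(wt, mu, tess, w$dt_potentials)),
                   rep(0, 7))
    }
  }
})
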