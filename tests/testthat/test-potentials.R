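annotate_all <- function(proteins, ss3_fun, rsa_fun) {
  for (k in seq_len(nrow(proteins))) {
    n <- nchar(proteins$sequence[k])
    proteins <- add_annotation(proteins, proteins$id[k],
                               ss3 = ss3_fun(n), rsa = rsa_fun(n))
  }
  proteins
}

tiny_corpus <- function(seqs, ids, ss3 = NULL, rsa = NULL) {
  p <- protein_table(ids, seqs)
  annotate_all(p,
               function(n) if (is.null(ss3)) rep("H", n) else rep_len(ss3, n),
               function(n) if (is.null(rsa)) rep(0.1, n) else rep_len(rsa, n))
}

test_that("identical corpora give all-zero potential tables", {
  cc <- tiny_corpus(c("MKVLYWAD", "ACDEFGHI"), c("a1", "a2"),
                    ss3 = c("H", "E", "C"), rsa = c(0.1, 0.3, 0.7))
  pot <- build_potentials(cc, cc)
  for (tab in pot$tables) {
    expect_true(all(tab$values == 0))
    expect_equal(tab$default, 0)
  }
})

test_that("unseen fragments score the closed-form pseudocount value", {
  a <- tiny_corpus("MKVLYWAD", "a1")
  b <- tiny_corpus("ACDEFGHIKLMNP", "b1")
  pot <- suppressWarnings(build_potentials(a, b, pseudocount = 1))
  K <- 20^4
  NA_ <- 8 - 3   # fragments in corpus A
  NB_ <- 13 - 3
  tab <- pot$tables$FBocc
  expect_equal(tab$default,
               log(1 / (NA_ + K)) - log(1 / (NB_ + K)))
  expect_equal(ddgforest:::lookup_potential(tab, "WWWW"), tab$default)
})

test_that("occurrence values match a brute-force recount on tiny corpora", {
  a <- tiny_corpus(c("MKVLMKVL", "AKVLY", "MKVA"), c("a1", "a2", "a3"))
  b <- tiny_corpus(c("MKVLYW", "CCDEF", "GHIKL"), c("b1", "b2", "b3"))
  pot <- suppressWarnings(build_potentials(a, b, pseudocount = 1))
  tab <- pot$tables$FBocc

  frags_of <- function(seqs) {
    unlist(lapply(seqs, function(s) {
      n <- nchar(s)
      substring(s, 1:(n - 3), 4:n)
    }))
  }
  fa <- frags_of(c("MKVLMKVL", "AKVLY", "MKVA"))
  fb <- frags_of(c("MKVLYW", "CCDEF", "GHIKL"))
  K <- 20^4
  for (f in unique(c(fa, fb))) {
    expected <- log((sum(fa == f) + 1) / (length(fa) + K)) -
      log((sum(fb == f) + 1) / (length(fb) + K))
    expect_equal(ddgforest:::lookup_potential(tab, f), expected,
                 info = f)
  }
})

test_that("state-conditional tables match hand-computed frequencies", {
  # all-helix corpora: helix table equals the unconditioned one
  a <- tiny_corpus(c("MKVLMKVL", "AKVLY"), c("a1", "a2"))
  b <- tiny_corpus(c("MKVLYW", "GHIKL"), c("b1", "b2"))
  pot <- suppressWarnings(build_potentials(a, b))
  expect_equal(pot$tables$FBhel$values, pot$tables$FBocc$values)
  # sheet/coil never occur: flat at the pseudocount default, no keys
  expect_length(pot$tables$FBshe$values, 0)

  # two-state annotation on two sequences, checked by hand enumeration
  a2 <- tiny_corpus("MKVLYWAD", "a1", ss3 = c("H", "H", "H", "H", "E"))
  b2 <- tiny_corpus("ACDEFGHI", "b1", ss3 = c("H", "H", "H", "H", "E"))
  pot2 <- suppressWarnings(build_potentials(a2, b2))
  # window states for an 8-residue sequence with period-5 HHHHE annotation:
  # windows 1..5 over states (H,H,H,H),(H,H,H,E),(H,H,E,H),(H,E,H,H),(E,H,H,H)
  # -> majority H everywhere
  expect_equal(length(pot2$tables$FBhel$values), 10)   # 5 + 5 distinct keys
  k1 <- substr("MKVLYWAD", 1, 4)
  K <- 20^4
  expect_equal(ddgforest:::lookup_potential(pot2$tables$FBhel, k1),
               log(2 / (5 + K)) - log(1 / (5 + K)))
})

test_that("fragment state is majority with third-residue tie-break", {
  expect_equal(fragment_state(c("H", "H", "H", "C")), "H")
  expect_equal(fragment_state(c("H", "H", "E", "E")), "E")  # residue 3
  expect_equal(fragment_state(c("E", "E", "H", "H")), "H")  # residue 3
  expect_equal(fragment_state(c("C", "C", "C", "C")), "C")
  expect_equal(fragment_state(c("H", "E", "C", "C")), "C")
})

test_that("windowed rescoring equals whole-sequence rescoring", {
  w <- test_world()
  set.seed(55)
  prot <- w$proteins
  for (rep in 1:40) {
    i <- sample(nrow(prot), 1)
    wt <- prot$sequence[i]
    subs <- random_subs(wt, sample(1:2, 1))
    mu <- apply_subs(wt, subs)
    fast <- seq_frag_features(wt, mu, prot$ss3[[i]], prot$rsa[[i]],
                              w$potentials)
    full <- oracle_seq_frag_full(wt, mu, prot$ss3[[i]], prot$rsa[[i]],
                                 w$potentials)
    expect_equal(fast, full, tolerance = 1e-12)
    # exact anti-symmetry under sequence swap
    expect_identical(fast, -seq_frag_features(mu, wt, prot$ss3[[i]],
                                              prot$rsa[[i]], w$potentials))
  }
})

test_that("potential serialization round-trips and rebuilds byte-identically", {
  w <- test_world()
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_potentials(w$potentials, f1)
  back <- read_potentials(f1)
  for (nm in names(w$potentials$tables)) {
    expect_equal(back$tables[[nm]]$values, w$potentials$tables[[nm]]$values)
    expect_equal(back$tables[[nm]]$default, w$potentials$tables[[nm]]$default)
  }
  # deterministic rebuild from the same corpora
  pot2 <- build_potentials(w$corpusA, w$corpusB)
  write_potentials(pot2, f2)
  expect_identical(readLines(f1), readLines(f2))
})
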