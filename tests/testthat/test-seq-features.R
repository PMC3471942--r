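test_that("structure/accessibility indicators are one-hot or fractions", {
  states <- tibble::tibble(pos = 1:4,
                           ss3 = c("H", "E", "C", "C"),
                           exposure2 = c("exposed", "buried", "buried",
                                         "exposed"))
  one <- sssa_features(states, tibble::tibble(wt = "A", pos = 1, mut = "G"))
  expect_equal(unname(one), c(1, 0, 0, 1, 0))

  two <- sssa_features(states, tibble::tibble(wt = c("A", "C"), pos = c(1, 2),
                                              mut = c("G", "S")))
  expect_equal(unname(two), c(0.5, 0.5, 0, 0.5, 0.5))
  expect_equal(sum(two[1:3]), 1)
  expect_equal(sum(two[4:5]), 1)

  coils <- sssa_features(states, tibble::tibble(wt = c("A", "C"),
                                                pos = c(3, 4),
                                                mut = c("G", "S")))
  expect_equal(unname(coils[1:3]), c(0, 0, 1))
  expect_error(sssa_features(states, tibble::tibble(wt = "A", pos = 9,
                                                    mut = "G")),
               "missing annotation")
})

test_that("composition fractions count set membership", {
  expect_equal(composition_fraction("RKHDE", c("R", "K", "H")), 0.6)
  expect_equal(composition_fraction("AAAA", c("W")), 0)
  expect_equal(composition_fraction("MKV", AA_ALPHABET), 1)
})

test_that("relative differences match hand arithmetic with the shipped tables", {
  # K -> R: both positive-charged, so POSI and CHAR cancel
  f <- reldiff_features("MKV", "MRV")
  expect_equal(unname(f["POSI"]), 0)
  expect_equal(unname(f["CHAR"]), 0)
  expect_equal(unname(f["pIa"]), (AA_PI[["R"]] - AA_PI[["K"]]) / 3)
  expect_equal(unname(f["dASA"]), (AA_MAX_ASA[["R"]] - AA_MAX_ASA[["K"]]) / 3)

  expect_equal(unname(reldiff_features("MKVA", "MKVA")), rep(0, 6))

  # T belongs to the published small-residue set, G to tiny
  g <- reldiff_features("ATG", "AVG")
  expect_equal(unname(g["SMAL"]), -1 / 3)
  h <- reldiff_features("ATG", "ATA")
  expect_equal(unname(h["TINY"]), 0)  # G and A both tiny
  expect_error(reldiff_features("MK", "MKV"), "length")
})

test_that("relative differences are exactly anti-symmetric and site-local", {
  set.seed(91)
  for (rep in 1:50) {
    n <- sample(10:60, 1)
    wt <- sim_protein(n, seed = rep)
    subs <- random_subs(wt, sample(1:3, 1))
    mu <- apply_subs(wt, subs)
    f <- reldiff_features(wt, mu)
    expect_identical(f, -reldiff_features(mu, wt))

    # whole-sequence composition difference equals the site-restricted form
    full <- vapply(list(c("R", "K", "H"), c("R", "K", "H", "D", "E"),
                        c("T", "D"), c("A", "G", "P", "S")),
                   function(s) composition_fraction(mu, s) -
                     composition_fraction(wt, s), numeric(1))
    expect_equal(unname(f[c("POSI", "CHAR", "SMAL", "TINY")]), full)
    wtc <- strsplit(wt, "")[[1]]
    muc <- strsplit(mu, "")[[1]]
    expect_equal(unname(f["pIa"]),
                 mean(AA_PI[muc]) - mean(AA_PI[wtc]))
  }
})
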