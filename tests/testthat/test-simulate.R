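test_that("sequence generation is seeded and length-correct", {
  expect_identical(sim_protein(50, seed = 11), sim_protein(50, seed = 11))
  expect_equal(nchar(sim_protein(50, seed = 11)), 50)
  expect_error(sim_protein(5, seed = 1), ">= 10")

  diffs <- vapply(1:100, function(s) {
    a <- strsplit(sim_protein(30, seed = s), "")[[1]]
    b <- strsplit(sim_protein(30, seed = s + 5000), "")[[1]]
    sum(a != b)
  }, numeric(1))
  expect_true(all(diffs > 0))

  # the caller's RNG state is untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(sim_protein(20, seed = 9)); after <- runif(1)
  expect_identical(before, after)
})

test_that("helix traces have C-alpha geometry and walk traces self-avoid", {
  seq <- sim_protein(40, seed = 21)
  hx <- sim_structure(seq, "helix", seed = 22)
  d <- sqrt(rowSums((hx$ca[-1, ] - hx$ca[-40, ])^2))
  expect_true(all(abs(d - 3.8) < 0.1))
  expect_true(all(hx$ss3 == "H"))
  expect_true(all(hx$rsa >= 0 & hx$rsa <= 1))

  wk <- sim_structure(sim_protein(200, seed = 23), "walk", seed = 24)
  dw <- sqrt(rowSums((wk$ca[-1, ] - wk$ca[-200, ])^2))
  expect_true(all(abs(dw - 3.8) < 1e-9))
  expect_true(all(wk$ss3 == "C"))
  # non-coplanar: the tessellation precondition holds
  expect_gt(nrow(delaunay_tessellate(wk$ca, edge_cutoff = Inf)), 0)
})

test_that("simulated profiles favour the native residue and sum to 100", {
  seq <- sim_protein(120, seed = 31)
  pssm <- sim_pssm(seq, concentration = 3, seed = 32)
  expect_true(all(rowSums(pssm$weighted) == 100))
  native <- match(strsplit(seq, "")[[1]], AA_ALPHABET)
  argmax <- apply(pssm$log_odds, 1, which.max)
  expect_gte(mean(argmax == native), 0.95)
  expect_identical(sim_pssm(seq, 3, seed = 32)$log_odds, pssm$log_odds)
})

test_that("zero-noise planted ddg is exactly recoverable from the pipeline", {
  w <- test_world()
  sm <- sim_mutations(w$proteins, 25, w$potentials, noise_sd = 0, seed = 41)
  f <- featurize(sm$mutations, w$proteins, w$potentials, mode = "sequence")
  recomputed <- as.matrix(f[, names(sm$truth$weights)]) %*% sm$truth$weights
  expect_equal(unname(as.vector(recomputed)), sm$mutations$ddg)

  two <- sim_mutations(w$proteins, 10, w$potentials, multiplicity = 2,
                       seed = 42)
  expect_true(all(vapply(two$mutations$subs, nrow, numeric(1)) == 2))
  expect_true(all(vapply(two$mutations$subs,
                         function(s) length(unique(s$pos)), numeric(1)) == 2))
})

test_that("a written bundle reloads into the identical analysis inputs", {
  dir <- withr::local_tempdir()
  bundle <- sim_bundle(dir, n_proteins = 4, lengths = 50, n_records = 12,
                       seed = 51)
  expect_true(file.exists(file.path(dir, "proteins.fasta")))
  b <- load_bundle(dir)
  expect_equal(b$proteins$sequence, bundle$proteins$sequence)
  expect_equal(b$mutations$ddg, bundle$mutations$ddg)
  for (k in seq_len(nrow(b$proteins))) {
    expect_equal(b$proteins$pssm[[k]]$log_odds,
                 bundle$proteins$pssm[[k]]$log_odds)
    expect_equal(b$proteins$ca[[k]], bundle$proteins$ca[[k]],
                 tolerance = 1e-3)  # PDB coordinates carry 3 decimals
    expect_equal(b$proteins$rsa[[k]], bundle$proteins$rsa[[k]])
  }
  # features computed from files match features computed in memory
  f_disk <- featurize(b$mutations, b$proteins, b$potentials,
                      mode = "sequence")
  f_mem <- featurize(bundle$mutations, bundle$proteins, bundle$potentials,
                     mode = "sequence")
  expect_equal(f_disk, f_mem)
})
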