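test_that("identity clustering never splits homologous proteins across folds", {
  set.seed(401)
  # 5 mutually unrelated proteins plus a planted 3-member >90% clique
  base <- sim_proteins(5, 60, seed = 402)
  clique_seq <- sim_protein(60, seed = 403)
  variants <- vapply(1:3, function(k) {
    subs <- random_subs(clique_seq, 2)  # 2/60 changes: >93% pairwise identity
    apply_subs(clique_seq, subs)
  }, "")
  prot <- protein_table(c(base$id, paste0("cl", 1:3)),
                        c(base$sequence, variants))
  prot <- sim_layers(prot, seed = 404)
  w <- test_world()
  sm <- sim_mutations(prot, 48, w$potentials, seed = 405)
  mut <- augment_reverse(sm$mutations, prot)

  fa <- assign_folds(mut, prot, k = 5, identity_threshold = 0.30)
  idm <- attr(fa, "identity")

  # clique members share one fold
  clique_folds <- fa$fold[fa$protein_id %in% paste0("cl", 1:3)]
  expect_length(unique(clique_folds), 1)
  expect_true(all(idm[paste0("cl", 1:3), paste0("cl", 1:3)] > 0.9))

  # no cross-fold pair above the threshold, asserted by recomputation
  for (i in seq_len(nrow(fa))) {
    for (j in seq_len(nrow(fa))) {
      if (fa$fold[i] != fa$fold[j]) {
        ident <- sequence_identity(
          prot$sequence[match(fa$protein_id[i], prot$id)],
          prot$sequence[match(fa$protein_id[j], prot$id)])
        expect_lte(ident, 0.30)
      }
    }
  }

  # every forward/reverse pair maps into one fold
  fold_of <- fa$fold[match(mut$protein_id, fa$protein_id)]
  by_pair <- tapply(fold_of, mut$pair_id, function(x) length(unique(x)))
  expect_true(all(by_pair == 1))
})

test_that("identical sequences always share a cluster and fold", {
  prot <- protein_table(c("t1", "t2", "u1", "u2", "u3", "u4"),
                        c(sim_protein(50, 1), sim_protein(50, 1),
                          sim_protein(50, 2), sim_protein(50, 3),
                          sim_protein(50, 4), sim_protein(50, 5)))
  mut <- tibble::tibble(
    protein_id = prot$id,
    mutations = "X",
    subs = list(NULL), ddg = 1, direction = "forward",
    pair_id = paste0("m", 1:6)
  )
  fa <- assign_folds(mut, prot, k = 5)
  expect_equal(fa$cluster[fa$protein_id == "t1"],
               fa$cluster[fa$protein_id == "t2"])
  expect_equal(fa$fold[fa$protein_id == "t1"],
               fa$fold[fa$protein_id == "t2"])
})

test_that("balanced greedy assignment and the too-few-clusters error", {
  prot <- sim_proteins(10, 60, seed = 406)
  mut <- tibble::tibble(
    protein_id = rep(prot$id, each = 4),
    mutations = "X", subs = list(NULL), ddg = 1, direction = "forward",
    pair_id = sprintf("m%02d", 1:40)
  )
  fa <- assign_folds(mut, prot, k = 5)
  load <- table(fa$fold[match(mut$protein_id, fa$protein_id)])
  expect_equal(unname(as.vector(load)), rep(8, 5))

  expect_error(assign_folds(mut, prot, k = 50), "clusters")
})
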