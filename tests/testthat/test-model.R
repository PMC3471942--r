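test_that("reverse augmentation doubles, balances and refuses to repeat", {
  w <- test_world()
  sm <- sim_mutations(w$proteins, 30, w$potentials, seed = 301)
  aug <- augment_reverse(sm$mutations, w$proteins)
  expect_equal(nrow(aug), 60)
  expect_equal(sum(aug$ddg > 0), sum(aug$ddg < 0))
  expect_error(augment_reverse(aug, w$proteins), "already")

  # the documented example: (p, V66A, -1.2) pairs with (A66V, +1.2)
  prot <- protein_table("p", paste(c(rep("G", 65), "V", rep("G", 14)),
                                   collapse = ""))
  fwd <- tibble::tibble(protein_id = "p", mutations = "V66A",
                        subs = list(tibble::tibble(wt = "V", pos = 66L,
                                                   mut = "A")),
                        ddg = -1.2, direction = "forward", pair_id = "m1")
  got <- augment_reverse(fwd, prot)
  expect_equal(got$mutations[2], "A66V")
  expect_equal(got$ddg[2], 1.2)
  expect_equal(got$pair_id[2], "m1")
})

test_that("classification uses zero as threshold with ties destabilizing", {
  expect_equal(classify_ddg(c(0.5, -0.5, 0)),
               c("stabilizing", "destabilizing", "destabilizing"))
  expect_error(classify_ddg(NaN), "non-finite")
})

test_that("midrank AUC equals the concordant-pair fraction", {
  expect_equal(auc_midrank(c(3, 2, 1, 0), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc_midrank(rep(1, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_true(is.na(auc_midrank(1:4, rep(TRUE, 4))))

  set.seed(302)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    scores <- sample(0:4, n, replace = TRUE) / 2  # plenty of ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c(TRUE, FALSE)
    expect_equal(auc_midrank(scores, labels), oracle_auc_pairs(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("evaluation reports per-direction ACC, AUC and Pearson R", {
  pred <- tibble::tibble(
    pred = c(1, -1, 2, -2, 0.5, -0.5, 1.5, -1),
    ddg = c(0.8, -0.7, 1.1, -2.0, -0.3, 0.4, 1.2, -0.9),
    direction = rep(c("forward", "reverse"), each = 4)
  )
  m <- evaluate_predictions(pred)
  expect_equal(nrow(m), 2)
  fwd <- pred[1:4, ]
  expect_equal(m$acc[m$direction == "forward"],
               mean((fwd$pred > 0) == (fwd$ddg > 0)))
  expect_equal(m$r[m$direction == "forward"], cor(fwd$pred, fwd$ddg))
  expect_equal(m$auc[m$direction == "forward"],
               oracle_auc_pairs(fwd$pred, fwd$ddg > 0))

  # ddg == 0 records are excluded from the classification metrics only
  withzero <- tibble::tibble(pred = c(1, -1, 0.2), ddg = c(0.5, -0.5, 0),
                             direction = "forward")
  mz <- evaluate_predictions(withzero)
  expect_equal(mz$acc, 1)
  expect_equal(mz$r, cor(withzero$pred, withzero$ddg))
})

test_that("random forest training is seeded, deterministic and degenerate-safe", {
  set.seed(303)
  x <- as.data.frame(matrix(rnorm(200 * 5), 200))
  y <- x[[1]] * 2 + rnorm(200, sd = 0.1)
  m1 <- rf_train(x, y, n_trees = 60, seed = 9)
  m2 <- rf_train(x, y, n_trees = 60, seed = 9)
  expect_identical(predict(m1, x), predict(m2, x))
  expect_error(rf_train(x, y, n_trees = 0), "n_trees")

  const <- suppressWarnings(rf_train(x, rep(1.5, 200), n_trees = 30,
                                     seed = 1))
  expect_equal(unname(predict(const, x[1:5, ])), rep(1.5, 5))
})

test_that("impurity importance separates planted signal from noise", {
  set.seed(304)
  n <- 250
  x <- as.data.frame(matrix(rnorm(n * 8), n))
  names(x) <- c(paste0("sig", 1:2), paste0("noise", 1:6))
  y <- 2 * x$sig1 - 1.5 * x$sig2 + rnorm(n, sd = 0.5)
  imp <- feature_importance(list(rf_train(x, y, n_trees = 150, seed = 5)))
  expect_true(all(is.na(imp$se)))  # single fold: no spread estimate
  ranks <- match(names(x), imp$feature)
  expect_true(max(ranks[1:2]) < min(ranks[3:8]))

  # an all-constant feature can never split
  x$flat <- 1
  imp2 <- feature_importance(list(rf_train(x, y, n_trees = 80, seed = 5)))
  expect_equal(imp2$importance[imp2$feature == "flat"], 0)
})

test_that("KS feature table matches the exhaustive ECDF oracle", {
  set.seed(305)
  for (rep in 1:30) {
    x <- round(rnorm(sample(4:15, 1)), 1)
    y <- round(rnorm(sample(4:15, 1), mean = 0.5), 1)
    df <- tibble::tibble(f = c(x, y))
    kt <- ks_feature_table(df, stabilizing = c(rep(TRUE, length(x)),
                                               rep(FALSE, length(y))))
    expect_equal(kt$statistic, oracle_ks_D(x, y), tolerance = 1e-12)
    expect_equal(kt$median_stab, median(x))
    expect_equal(kt$mean_destab, mean(y))
  }
  ident <- ks_feature_table(tibble::tibble(f = rep(1:5, 2)),
                            stabilizing = rep(c(TRUE, FALSE), each = 5))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  disj <- ks_feature_table(tibble::tibble(f = c(1:5, 11:15)),
                           stabilizing = rep(c(TRUE, FALSE), each = 5))
  expect_equal(disj$statistic, 1)
  expect_error(ks_feature_table(tibble::tibble(f = 1:4),
                                stabilizing = rep(TRUE, 4)), "nonempty")
})
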