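#' Clustered cross-validation of the ddG model
#'
#' Runs the full evaluation protocol as one verb: augment the forward
#' mutation table with hypothetical reverse mutations (if not already done),
#' compute the feature matrix, assign identity-clustered folds, train one
#' Random Forest per fold on the out-of-fold records and predict the held-out
#' fold, then pool all out-of-fold predictions and score them per direction.
#' Pooling across folds matches how the combined cross-validation results are
#' reported: one AUC/ACC/R per direction plus per-fold values and the
#' impurity-importance ranking.
#'
#' @param mutations Mutation table (forward-only or already augmented).
#' @param proteins Protein table with the layers the mode needs.
#' @param potentials Sequential `potential_set`.
#' @param mode `"structure"` (41 features) or `"sequence"` (34).
#' @param dt_potentials Delaunay `potential_set` (structure mode).
#' @param n_trees Trees per fold model.
#' @param folds Number of folds.
#' @param identity_threshold Clustering threshold for fold assignment.
#' @param seed Integer seed; the whole run is bit-reproducible given it.
#' @param edge_cutoff Tessellation edge cutoff (structure mode).
#' @return A `ddg_cv` object: list with `metrics` (per-direction pooled),
#'   `fold_metrics`, `predictions`, `importance`, `fold_assignment`,
#'   `models` and `config`. Has [tidy()], [glance()] and
#'   [ggplot2::autoplot()] methods.
#' @export
ddg_cv <- function(mutations, proteins, potentials,
                   mode = c("structure", "sequence"), dt_potentials = NULL,
                   n_trees = 2000, folds = 5, identity_threshold = 0.30,
                   seed = 1, edge_cutoff = 10) {
  mode <- match.arg(mode)
  if (!any(mutations$direction == "reverse")) {
    mutations <- augment_reverse(mutations, proteins)
  }
  feats <- featurize(mutations, proteins, potentials, mode,
                     dt_potentials = dt_potentials, edge_cutoff = edge_cutoff)
  fa <- assign_folds(mutations, proteins, k = folds,
                     identity_threshold = identity_threshold)
  fold_of <- fa$fold[match(feats$protein_id, fa$protein_id)]
  nms <- feature_names(mode)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fold_seeds <- sample.int(.Machine$integer.max - 1, folds)
  models <- vector("list", folds)
  pred <- rep(NA_real_, nrow(feats))
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    te <- !tr
    models[[f]] <- rf_train(feats[tr, nms], feats$ddg[tr],
                            n_trees = n_trees, seed = fold_seeds[f])
    pred[te] <- unname(stats::predict(models[[f]],
                                      as.data.frame(feats[te, nms])))
  }
  predictions <- dplyr::bind_cols(
    feats[, c("protein_id", "mutations", "ddg", "direction", "pair_id")],
    tibble::tibble(fold = fold_of, pred = pred)
  )
  metrics <- evaluate_predictions(predictions)
  fold_metrics <- predictions |>
    dplyr::group_by(.data$fold) |>
    dplyr::group_modify(~ evaluate_predictions(.x)) |>
    dplyr::ungroup()
  structure(list(
    metrics = metrics,
    fold_metrics = fold_metrics,
    predictions = predictions,
    importance = feature_importance(models),
    fold_assignment = fa,
    models = models,
    config = list(mode = mode, n_trees = n_trees, folds = folds,
                  identity_threshold = identity_threshold, seed = seed,
                  edge_cutoff = edge_cutoff,
                  n_records = nrow(feats), n_features = length(nms))
  ), class = "ddg_cv")
}

#' @export
print.ddg_cv <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<ddg_cv> %s mode, %d records, %d features, %d folds x %d trees (seed %d)\n",
              cfg$mode, cfg$n_records, cfg$n_features, cfg$folds, cfg$n_trees,
              cfg$seed))
  m <- x$metrics
  for (k in seq_len(nrow(m))) {
    cat(sprintf("  %-8s n=%5d  AUC=%.3f  ACC=%.3f  R=%.3f\n",
                m$direction[k], m$n[k], m$auc[k], m$acc[k], m$r[k]))
  }
  invisible(x)
}

#' Tidy methods for cross-validation results
#'
#' `tidy()` returns the pooled per-direction metrics (or per-fold metrics
#' with `per_fold = TRUE`, or the importance ranking with
#' `what = "importance"`); `glance()` a one-row summary with
#' direction-suffixed columns.
#'
#' @param x A `ddg_cv` object.
#' @param per_fold Return per-fold rather than pooled metrics.
#' @param what `"metrics"` or `"importance"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ddg_cv <- function(x, per_fold = FALSE, what = c("metrics", "importance"),
                        ...) {
  what <- match.arg(what)
  if (what == "importance") return(x$importance)
  if (per_fold) x$fold_metrics else x$metrics
}

#' @rdname tidy.ddg_cv
#' @export
glance.ddg_cv <- function(x, ...) {
  m <- x$metrics
  wide <- tidyr::pivot_wider(
    m, names_from = "direction",
    values_from = c("n", "auc", "acc", "r"))
  dplyr::bind_cols(
    tibble::tibble(mode = x$config$mode, folds = x$config$folds,
                   n_trees = x$config$n_trees, seed = x$config$seed),
    wide
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot cross-validation results
#'
#' `type = "importance"` draws the across-fold mean impurity importance of
#' every feature with standard-error bars; `type = "scatter"` the pooled
#' out-of-fold predicted vs experimental ddG, coloured by direction, with
#' the identity line.
#'
#' @param object A `ddg_cv` object.
#' @param type `"importance"` or `"scatter"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ddg_cv <- function(object, type = c("importance", "scatter"), ...) {
  type <- match.arg(type)
  if (type == "importance") {
    imp <- object$importance
    imp$feature <- factor(imp$feature, levels = rev(imp$feature))
    p <- ggplot2::ggplot(imp, ggplot2::aes(x = .data$importance,
                                           y = .data$feature)) +
      ggplot2::geom_col(fill = "grey35") +
      ggplot2::labs(x = "Impurity importance (mean across folds)",
                    y = NULL)
    if (!all(is.na(imp$se))) {
      p <- p + ggplot2::geom_errorbarh(
        ggplot2::aes(xmin = .data$importance - .data$se,
                     xmax = .data$importance + .data$se), height = 0.3)
    }
    return(p)
  }
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$ddg, y = .data$pred,
                               colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "Experimental ddG (kcal/mol)",
                  y = "Predicted ddG (kcal/mol)")
}

#' Write the evaluation report to disk
#'
#' Writes `metrics.tsv` (pooled per-direction), `fold_metrics.tsv`,
#' `importance.tsv`, `predictions.tsv` and a human-readable `report.txt`
#' into `dir`. Output is byte-deterministic for a given fitted object.
#'
#' @param cv A `ddg_cv` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cv_report <- function(cv, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(cv$metrics, file.path(dir, "metrics.tsv"))
  readr::write_tsv(cv$fold_metrics, file.path(dir, "fold_metrics.tsv"))
  readr::write_tsv(cv$importance, file.path(dir, "importance.tsv"))
  readr::write_tsv(cv$predictions, file.path(dir, "predictions.tsv"))
  txt <- c(
    sprintf("mode: %s", cv$config$mode),
    sprintf("records: %d  features: %d  folds: %d  trees: %d  seed: %d",
            cv$config$n_records, cv$config$n_features, cv$config$folds,
            cv$config$n_trees, cv$config$seed),
    sprintf("%-8s n=%5d AUC=%.4f ACC=%.4f R=%.4f",
            cv$metrics$direction, cv$metrics$n, cv$metrics$auc,
            cv$metrics$acc, cv$metrics$r)
  )
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
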