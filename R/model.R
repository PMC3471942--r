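#' Train the Random Forest regressor
#'
#' A thin seeded wrapper around `randomForest::randomForest()` in regression
#' mode: an ensemble of `n_trees` trees (default 2000), each grown on a
#' bootstrap sample with a random variable subset at each split; the
#' prediction is the mean of the tree outputs. Default tree parameters are
#' kept — the algorithm is near-optimal without tuning. Node-impurity
#' importance (total decrease in residual sum of squares attributed to each
#' feature) is retained on the fit.
#'
#' @param features Data frame / tibble of numeric feature columns only.
#' @param ddg Numeric response (ddG, kcal/mol).
#' @param n_trees Number of trees, `>= 1`.
#' @param seed Integer seed; the fit is bit-reproducible given it.
#' @return A `randomForest` fit.
#' @export
rf_train <- function(features, ddg, n_trees = 2000, seed = 1) {
  if (n_trees < 1) stop("n_trees must be >= 1", call. = FALSE)
  x <- as.data.frame(features)
  stopifnot(all(vapply(x, is.numeric, logical(1))))
  if (anyNA(x)) stop("missing feature values", call. = FALSE)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  randomForest::randomForest(x = x, y = ddg, ntree = n_trees)
}

#' Classify a predicted ddG
#'
#' Zero change is the classification threshold: a prediction strictly above
#' 0 is stabilizing, 0 or below (conservative tie-break) destabilizing.
#'
#' @param predicted_ddg Numeric vector of predictions (finite).
#' @return Character vector, `"stabilizing"` / `"destabilizing"`.
#' @export
classify_ddg <- function(predicted_ddg) {
  if (any(!is.finite(predicted_ddg))) {
    stop("non-finite predicted ddg", call. = FALSE)
  }
  ifelse(predicted_ddg > 0, "stabilizing", "destabilizing")
}

#' Area under the ROC curve by midranks
#'
#' Rank-statistic AUC: the probability that a randomly chosen positive
#' outscores a randomly chosen negative, with ties counted half (midranks) —
#' equivalent to sweeping all score cutoffs.
#'
#' @param scores Numeric scores (higher = more positive-like).
#' @param labels Logical, `TRUE` for the positive class.
#' @return AUC in `[0, 1]`, or `NA` if a class is empty.
#' @export
auc_midrank <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate predictions against experimental ddG
#'
#' Per mutation direction (WT->MT forward, MT->WT reverse): classification
#' accuracy at the zero threshold, midrank AUC of the predicted ddG against
#' the true stabilizing label, and the Pearson correlation of predicted vs
#' experimental ddG. Records with experimental ddG exactly 0 sit on the
#' class boundary and are excluded from ACC/AUC (kept for the correlation).
#'
#' @param predictions Tibble with columns `pred`, `ddg` and `direction`.
#' @return Tibble, one row per direction: `direction`, `n`, `auc`, `acc`,
#'   `r`.
#' @export
evaluate_predictions <- function(predictions) {
  stopifnot(all(c("pred", "ddg", "direction") %in% names(predictions)))
  dplyr::group_by(predictions, .data$direction) |>
    dplyr::summarise(
      n = dplyr::n(),
      auc = auc_midrank(.data$pred[.data$ddg != 0],
                        .data$ddg[.data$ddg != 0] > 0),
      acc = mean((classify_ddg(.data$pred) == "stabilizing")[.data$ddg != 0] ==
                   (.data$ddg[.data$ddg != 0] > 0)),
      r = stats::cor(.data$pred, .data$ddg),
      .groups = "drop"
    )
}

#' Impurity importance across cross-validation folds
#'
#' Per-feature total impurity decrease (IncNodePurity) from each fold's
#' forest, summarised as the across-fold mean and standard error and sorted
#' descending — the content of the importance ranking plot.
#'
#' @param models List of `randomForest` fits (one per fold).
#' @return Tibble with `feature`, `importance` (mean), `se` (`NA` for a
#'   single model), `rank`.
#' @export
feature_importance <- function(models) {
  stopifnot(length(models) >= 1)
  imp <- vapply(models, function(m) m$importance[, "IncNodePurity"],
                numeric(nrow(models[[1]]$importance)))
  imp <- matrix(imp, ncol = length(models),
                dimnames = list(rownames(models[[1]]$importance), NULL))
  m <- rowMeans(imp)
  se <- if (length(models) > 1) {
    apply(imp, 1, stats::sd) / sqrt(length(models))
  } else {
    rep(NA_real_, nrow(imp))
  }
  out <- tibble::tibble(feature = names(m), importance = unname(m),
                        se = unname(se))
  out <- dplyr::arrange(out, dplyr::desc(.data$importance))
  out$rank <- seq_len(nrow(out))
  out
}

#' Feature distributions in stabilizing vs destabilizing mutations
#'
#' For every feature column: the median and mean within the stabilizing and
#' destabilizing groups and the two-sample Kolmogorov-Smirnov test of the
#' two distributions (statistic `D = sup |F1 - F2|`, asymptotic p-value from
#' the Kolmogorov distribution).
#'
#' @param features Feature tibble as returned by [featurize()] (metadata
#'   columns are ignored) or any data frame of numeric columns.
#' @param stabilizing Logical vector: `TRUE` where the record is stabilizing
#'   (defaults to `features$ddg > 0` when a `ddg` column is present).
#' @return Tibble with one row per feature: group medians/means, `statistic`
#'   and `p_value`.
#' @export
ks_feature_table <- function(features, stabilizing = NULL) {
  if (is.null(stabilizing)) {
    if (!"ddg" %in% names(features)) {
      stop("supply `stabilizing` or include a ddg column", call. = FALSE)
    }
    stabilizing <- features$ddg > 0
  }
  num <- features[, setdiff(names(features)[vapply(features, is.numeric,
                                                   logical(1))], "ddg"),
                  drop = FALSE]
  if (sum(stabilizing) == 0 || sum(!stabilizing) == 0) {
    stop("both stabilizing and destabilizing groups must be nonempty",
         call. = FALSE)
  }
  purrr::map_dfr(names(num), function(nm) {
    x <- num[[nm]][stabilizing]
    y <- num[[nm]][!stabilizing]
    kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
    tibble::tibble(
      feature = nm,
      median_stab = stats::median(x), median_destab = stats::median(y),
      mean_stab = mean(x), mean_destab = mean(y),
      statistic = unname(kt$statistic), p_value = kt$p.value
    )
  })
}
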