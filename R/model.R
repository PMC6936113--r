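#' Build the feature matrix for the refinement classifier
#'
#' Joins scored variants to truth labels by `(chrom, pos, ref, alt)` and
#' extracts the metric columns in canonical order. Unlabeled variants are
#' dropped with a message.
#'
#' @param scored Tibble with variant identity columns plus the metric
#'   columns (from [score_variants()] or [compute_metric_vector()] bound to
#'   identities).
#' @param truth Tibble with `chrom`, `pos`, `ref`, `alt`, `label` (1 = true
#'   variant).
#' @param mode `"germline"` (16 features) or `"somatic"` (18 features).
#' @return A list of class `vartag_features`: `x` (numeric matrix), `y`
#'   (0/1 labels), `feature_names`, `variants` (identity tibble).
#' @export
build_feature_matrix <- function(scored, truth,
                                 mode = c("germline", "somatic")) {
  mode <- match.arg(mode)
  feats <- if (mode == "germline") .metrics_germline else .metrics_somatic
  missing_cols <- setdiff(feats, names(scored))
  if (length(missing_cols)) {
    stop("scored input lacks metric column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  joined <- dplyr::inner_join(
    scored, dplyr::select(truth, "chrom", "pos", "ref", "alt", "label"),
    by = c("chrom", "pos", "ref", "alt"))
  dropped <- nrow(scored) - nrow(joined)
  if (dropped > 0L) {
    message(dropped, " unlabeled variant(s) excluded from the feature matrix")
  }
  x <- as.matrix(joined[, feats])
  storage.mode(x) <- "double"
  structure(list(x = x, y = as.integer(joined$label),
                 feature_names = feats,
                 variants = dplyr::select(joined, "chrom", "pos", "ref", "alt")),
            class = "vartag_features")
}

#' Train the gradient-boosted refinement classifier
#'
#' Fits an XGBoost model with binary-logistic objective. Hyperparameters
#' are selected by grid search over learning rate, gamma and tree depth
#' (27 combinations by default) with k-fold cross-validation; the grid
#' point with the highest mean fold AUC wins and the model is refit on the
#' full data.
#'
#' @param features A `vartag_features` from [build_feature_matrix()].
#' @param learning_rates,gammas,max_depths Grid values.
#' @param folds Number of CV folds (default 10).
#' @param nrounds Boosting rounds (default 100).
#' @param seed Integer seed controlling fold assignment.
#' @return A `vartag_refiner`: the fitted booster, chosen hyperparameters,
#'   the full CV grid (see [tidy.vartag_refiner()]), feature names and
#'   seed.
#' @export
fit_refiner <- function(features,
                        learning_rates = c(0.01, 0.05, 0.1),
                        gammas = c(0.1, 1, 10),
                        max_depths = c(3, 6, 9),
                        folds = 10L, nrounds = 100L, seed = 1L) {
  stopifnot(inherits(features, "vartag_features"), folds >= 2L)
  y <- features$y
  if (length(unique(y)) < 2L) {
    stop("degenerate labels: ", sum(y == 1L), " positive / ",
         sum(y == 0L), " negative examples")
  }
  if (min(sum(y == 1L), sum(y == 0L)) < folds) {
    stop("need at least `folds` (", folds, ") examples of each class; got ",
         sum(y == 1L), " positive / ", sum(y == 0L), " negative")
  }
  grid <- expand.grid(eta = learning_rates, gamma = gammas,
                      max_depth = max_depths, KEEP.OUT.ATTRS = FALSE)
  n <- length(y)
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))
  dtrain_full <- xgboost::xgb.DMatrix(features$x, label = y)
  cv_auc <- purrr::map_dbl(seq_len(nrow(grid)), function(g) {
    aucs <- vapply(seq_len(folds), function(k) {
      tr <- fold_id != k
      if (length(unique(y[!tr])) < 2L) return(NA_real_)
      bst <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      eta = grid$eta[g], gamma = grid$gamma[g],
                      max_depth = grid$max_depth[g], nthread = 1),
        data = xgboost::xgb.DMatrix(features$x[tr, , drop = FALSE],
                                    label = y[tr]),
        nrounds = nrounds, verbose = 0)
      p <- predict(bst, xgboost::xgb.DMatrix(features$x[!tr, , drop = FALSE]))
      roc_auc(p, y[!tr])
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  })
  grid$cv_auc <- cv_auc
  best <- which.max(cv_auc)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  eta = grid$eta[best], gamma = grid$gamma[best],
                  max_depth = grid$max_depth[best], nthread = 1),
    data = dtrain_full, nrounds = nrounds, verbose = 0)
  structure(
    list(booster = booster,
         best_params = as.list(grid[best, c("eta", "gamma", "max_depth")]),
         cv_grid = tibble::as_tibble(grid),
         feature_names = features$feature_names,
         nrounds = nrounds, folds = folds, seed = seed,
         fold_id = fold_id),
    class = "vartag_refiner")
}

#' Predict true-variant probabilities
#'
#' @param object A `vartag_refiner`.
#' @param newdata A `vartag_features`, a numeric matrix, or a tibble
#'   carrying the model's metric columns. The column set must match the
#'   model's embedded feature order.
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]` that each variant
#'   is true.
#' @export
predict.vartag_refiner <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "vartag_features")) {
    if (!identical(newdata$feature_names, object$feature_names)) {
      stop("feature columns differ from the model's embedded order: model has [",
           paste(object$feature_names, collapse = ", "), "]")
    }
    newdata$x
  } else if (is.matrix(newdata)) {
    if (!is.null(colnames(newdata)) &&
        !identical(colnames(newdata), object$feature_names)) {
      stop("feature columns differ from the model's embedded order")
    }
    newdata
  } else {
    missing_cols <- setdiff(object$feature_names, names(newdata))
    if (length(missing_cols)) {
      stop("newdata lacks metric column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    m <- as.matrix(newdata[, object$feature_names])
    storage.mode(m) <- "double"
    m
  }
  stats::predict(object$booster, xgboost::xgb.DMatrix(x))
}

#' @rdname fit_refiner
#' @param x A `vartag_refiner`.
#' @param ... Unused.
#' @export
tidy.vartag_refiner <- function(x, ...) {
  dplyr::arrange(x$cv_grid, dplyr::desc(.data$cv_auc))
}

#' @rdname fit_refiner
#' @export
glance.vartag_refiner <- function(x, ...) {
  tibble::tibble(eta = x$best_params$eta, gamma = x$best_params$gamma,
                 max_depth = x$best_params$max_depth,
                 cv_auc = max(x$cv_grid$cv_auc), folds = x$folds,
                 nrounds = x$nrounds, seed = x$seed)
}

#' @export
print.vartag_refiner <- function(x, ...) {
  g <- glance.vartag_refiner(x)
  cat(sprintf(paste0("<vartag_refiner> eta=%.3g gamma=%.3g max_depth=%d ",
                     "(cv AUC %.3f over %d-fold CV, %d grid points)\n"),
              g$eta, g$gamma, g$max_depth, g$cv_auc, x$folds,
              nrow(x$cv_grid)))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation with midrank tie handling: the
#' probability that a randomly chosen positive outranks a randomly chosen
#' negative, counting ties as one half.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels 0/1 or logical labels.
#' @return AUC in `[0, 1]`; `NA` if either class is absent.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels 0/1 or logical labels.
#' @return Tibble of `fpr`, `tpr` ordered along the curve.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord]); fp <- cumsum(!labels[ord])
  tibble::tibble(fpr = c(0, fp / max(sum(!labels), 1L)),
                 tpr = c(0, tp / max(sum(labels), 1L)))
}

#' Plot ROC curves for one or more scoring schemes
#'
#' @param ... Named numeric score vectors (higher = more likely true).
#' @param labels Shared truth labels.
#' @return A ggplot of the ROC curves with AUC in the legend.
#' @export
plot_roc <- function(..., labels) {
  scores <- list(...)
  stopifnot(length(scores) >= 1L, !is.null(names(scores)))
  df <- purrr::imap(scores, function(s, nm) {
    dplyr::mutate(roc_points(s, labels),
                  scheme = sprintf("%s (AUC %.3f)", nm, roc_auc(s, labels)))
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$scheme)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
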