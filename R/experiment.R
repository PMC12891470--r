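# Repeated stratified train/test experiments. Per repeat: split, fit
# transforms on the training rows only, augment the training split only
# (augmentation is also refit fold-locally inside the grid-search CV so
# synthetic neighbours of validation rows never reach the fitting folds),
# grid-search by inner-CV score, refit, evaluate on the untouched test rows.

#' Plan for a repeated train/test experiment
#'
#' @param models Model kinds to run (defaults: the full six-member suite for
#'   the task).
#' @param augmenters List of augmentation settings, each a list
#'   `(method, target_size)`; default no augmentation plus SMOTE to a
#'   100-row minority class.
#' @param n_repeats Number of repeated splits (default 50, the study's
#'   repetition count; reduce for quick runs).
#' @param test_fraction Held-out fraction per repeat (default 0.2).
#' @param inner_folds Grid-search cross-validation folds (default 5).
#' @param grids Hyperparameter grids, as [default_grids()].
#' @param base_seed First split seed; repeat r uses `base_seed + r - 1`
#'   (default 42).
#' @param task `"classification"` or `"regression"`.
#' @return List of class `experiment_plan`.
#' @export
experiment_plan <- function(models = NULL, augmenters = NULL, n_repeats = 50L,
                            test_fraction = 0.2, inner_folds = 5L,
                            grids = NULL, base_seed = 42L,
                            task = c("classification", "regression")) {
  task <- match.arg(task)
  if (is.null(models)) models <- if (task == "classification") clf_kinds() else reg_kinds()
  if (is.null(augmenters))
    augmenters <- if (task == "classification")
      list(list(method = "none", target_size = "balance100"),
           list(method = "smote", target_size = "balance100"))
    else list(list(method = "none", target_size = "balance100"))
  if (is.null(grids)) grids <- default_grids(task)
  if (n_repeats < 1L) gs_param_error("n_repeats must be >= 1")
  if (any(vapply(grids[models], length, integer(1)) < 1L))
    gs_param_error("every model needs a non-empty grid")
  structure(list(models = models, augmenters = augmenters,
                 n_repeats = as.integer(n_repeats),
                 test_fraction = test_fraction,
                 inner_folds = as.integer(inner_folds), grids = grids,
                 base_seed = as.integer(base_seed), task = task),
            class = "experiment_plan")
}

# stratified train/test split on a factor label (classification) or plain
# random split (regression); returns row indices
split_indices <- function(n, strata, test_fraction, seed) {
  with_seed(seed, {
    test <- integer(0)
    if (is.null(strata)) {
      test <- sample.int(n, round(test_fraction * n))
    } else {
      for (lv in levels(strata)) {
        idx <- which(strata == lv)
        test <- c(test, sample(idx, max(1L, round(test_fraction * length(idx)))))
      }
    }
    list(train = setdiff(seq_len(n), test), test = sort(test))
  })
}

# stratified fold assignment for inner CV
fold_ids <- function(strata, k, seed) {
  n <- length(strata)
  with_seed(seed, {
    f <- integer(n)
    if (is.factor(strata)) {
      for (lv in levels(strata)) {
        idx <- sample(which(strata == lv))
        f[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      f[sample.int(n)] <- rep_len(seq_len(k), n)
    }
    f
  })
}

# grid search one model kind by inner-CV score over fold-local augmented sets
grid_search <- function(kind, grid, folds, task, label_col, target_col,
                        feature_cols, seed) {
  score_one <- function(params) {
    scores <- vapply(folds, function(fd) {
      fit <- fit_model(kind, fd$train[feature_cols],
                       if (task == "classification") fd$train[[label_col]]
                       else fd$train[[target_col]],
                       params, seed = seed)
      pr <- predict(fit, fd$valid[feature_cols])
      if (task == "classification") {
        if (nlevels(droplevels(fd$valid[[label_col]])) < 2L) return(NA_real_)
        roc_auc(pr, fd$valid[[label_col]])
      } else {
        -mean((fd$valid[[target_col]] - pr)^2)
      }
    }, numeric(1))
    mean(scores, na.rm = TRUE)
  }
  sc <- vapply(grid, score_one, numeric(1))
  list(params = grid[[which.max(sc)]], cv_score = max(sc))
}

run_experiment <- function(table, plan, label_col = "group", target_col = NULL,
                           feature_cols = NULL, preprocess = TRUE) {
  task <- plan$task
  if (is.null(feature_cols)) {
    feature_cols <- names(table)[vapply(table, is.numeric, logical(1))]
    feature_cols <- setdiff(feature_cols, target_col)
  }
  if (task == "classification") {
    if (!label_col %in% names(table) || nlevels(factor(table[[label_col]])) != 2L)
      gs_param_error("classification needs a binary label column")
    table[[label_col]] <- factor(table[[label_col]])
  }
  raw <- list()
  for (r in seq_len(plan$n_repeats)) {
    seed <- plan$base_seed + r - 1L
    strata <- if (task == "classification") table[[label_col]] else NULL
    # re-draw with the next seed if a split loses a class (guarded anyway by
    # the stratified draw)
    repeat {
      idx <- split_indices(nrow(table), strata, plan$test_fraction, seed)
      if (task != "classification" ||
          nlevels(droplevels(table[[label_col]][idx$test])) == 2L) break
      seed <- seed + 1000L
    }
    train <- table[idx$train, , drop = FALSE]
    test <- table[idx$test, , drop = FALSE]
    if (preprocess) {
      pp <- preprocess_fit(train, cols = feature_cols)
      train <- preprocess_apply(pp, train)
      test <- preprocess_apply(pp, test)
    }
    fid <- fold_ids(if (task == "classification") train[[label_col]]
                    else seq_len(nrow(train)), plan$inner_folds, seed + 1L)
    for (aug in plan$augmenters) {
      aug_name <- paste0(aug$method,
                         if (aug$method != "none") paste0("_", aug$target_size) else "")
      full <- augment_training_split(
        list(train = train, test = test), method = aug$method,
        target_size = aug$target_size, label_col = label_col,
        feature_cols = feature_cols, seed = seed + 2L)
      # fold-local augmentation: the augmenter never sees the validation fold
      folds <- lapply(seq_len(plan$inner_folds), function(f) {
        tr <- train[fid != f, , drop = FALSE]
        a <- augment_training_split(
          list(train = tr, test = NULL), method = aug$method,
          target_size = aug$target_size, label_col = label_col,
          feature_cols = feature_cols, seed = seed + 2L + f)
        list(train = a$train, valid = train[fid == f, , drop = FALSE])
      })
      for (kind in plan$models) {
        gs <- grid_search(kind, plan$grids[[kind]], folds, task, label_col,
                          target_col, feature_cols, seed)
        fit <- fit_model(kind, full$train[feature_cols],
                         if (task == "classification") full$train[[label_col]]
                         else full$train[[target_col]],
                         gs$params, seed = seed)
        pr <- predict(fit, test[feature_cols])
        met <- if (task == "classification")
          classification_metrics(pr, test[[label_col]])
        else regression_metrics(test[[target_col]], pr)
        raw[[length(raw) + 1L]] <- data.frame(
          model = kind, augmenter = aug_name, repeat_id = r, seed = seed,
          t(met), cv_score = gs$cv_score,
          params = jsonlite::toJSON(gs$params, auto_unbox = TRUE))
      }
    }
  }
  raw <- do.call(rbind, raw)
  metric_cols <- setdiff(names(raw), c("model", "augmenter", "repeat_id",
                                       "seed", "cv_score", "params"))
  summ <- do.call(rbind, lapply(split(raw, list(raw$model, raw$augmenter),
                                      drop = TRUE), function(d) {
    out <- data.frame(model = d$model[1L], augmenter = d$augmenter[1L],
                      n_repeats = nrow(d))
    for (m in metric_cols) {
      out[[paste0(m, "_mean")]] <- mean(d[[m]])
      out[[paste0(m, "_sd")]] <- stats::sd(d[[m]])
    }
    out
  }))
  rownames(summ) <- NULL
  rank_col <- if (task == "classification") "auc_mean" else "r2_mean"
  summ <- summ[order(-summ[[rank_col]]), ]
  structure(list(task = task, raw = raw, summary = summ,
                 best = summ[1L, c("model", "augmenter")],
                 label_col = label_col, target_col = target_col,
                 feature_cols = feature_cols, plan = plan),
            class = "experiment_report")
}

#' Run the stroke-vs-control classification experiment
#'
#' Repeated stratified 80/20 evaluation of the six-classifier suite with
#' leakage-guarded preprocessing and augmentation; models are tuned by inner
#' 5-fold cross-validated AUC and scored on the untouched test split with
#' AUC, sensitivity, specificity, F1 and Brier score.
#'
#' @param table Feature table with a binary `group` column.
#' @param plan An [experiment_plan()] with `task = "classification"`.
#' @param label_col Label column name (default `"group"`).
#' @param feature_cols Feature columns (default: all numeric).
#' @param preprocess Fit the IQR/power/z-score chain per split (default TRUE).
#' @return An `experiment_report`: `$raw` per-repeat metrics, `$summary`
#'   means/SDs per model x augmenter, `$best` the top combination.
#' @export
run_classification <- function(table, plan = experiment_plan(task = "classification"),
                               label_col = "group", feature_cols = NULL,
                               preprocess = TRUE) {
  stopifnot(plan$task == "classification")
  run_experiment(table, plan, label_col = label_col,
                 feature_cols = feature_cols, preprocess = preprocess)
}

#' Run an uneven-surface regression experiment
#'
#' Same harness as [run_classification()] with the regression suite and
#' R^2 / RMSE / MAE / MSE metrics.
#'
#' @param table Feature table.
#' @param target Name of the numeric target column.
#' @param plan An [experiment_plan()] with `task = "regression"`.
#' @param feature_cols Predictor columns (default: all numeric except target).
#' @param preprocess Fit the transform chain per split (default TRUE).
#' @return An `experiment_report`.
#' @export
run_regression <- function(table, target,
                           plan = experiment_plan(task = "regression"),
                           feature_cols = NULL, preprocess = TRUE) {
  stopifnot(plan$task == "regression")
  run_experiment(table, plan, target_col = target,
                 feature_cols = feature_cols, preprocess = preprocess)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %s, %d combinations x %d repeats\n",
              x$task, nrow(x$summary), max(x$raw$repeat_id)))
  cat(sprintf("best: %s (%s)\n", x$best$model, x$best$augmenter))
  print(utils::head(x$summary, 6))
  invisible(x)
}

#' Export an experiment report
#'
#' Writes the tidy per-repeat CSV (one row per model x augmenter x repeat)
#' and a JSON summary.
#'
#' @param report An `experiment_report`.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(report$raw, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(task = report$task, summary = report$summary,
                              best = report$best),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}
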