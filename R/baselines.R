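# Comparison arm: visit-aggregation featurization and the four classical
# regressors (linear regression, SVR, decision tree, random forest).

#' Aggregate a subject's visit history into one feature vector
#'
#' Numerical columns are averaged, ordinal columns take the median (lower of
#' the two middle values on even counts), nominal columns take the mode
#' (ties broken by first occurrence) — the standard featurization that
#' collapses longitudinal visits for non-temporal models.
#'
#' @param feature_matrix numeric matrix, one row per visit (time order
#'   irrelevant: every rule is permutation-invariant).
#' @param column_kinds character vector (`"numerical"`, `"ordinal"`,
#'   `"nominal"`), one per column.
#' @return numeric vector, one aggregated value per column.
#' @export
aggregate_history <- function(feature_matrix, column_kinds) {
  if (nrow(feature_matrix) < 1)
    stop("argument error: at least one visit required")
  if (length(column_kinds) != ncol(feature_matrix))
    stop("dimension error: one column kind per feature column required")
  bad <- setdiff(unique(column_kinds), c("numerical", "ordinal", "nominal"))
  if (length(bad) > 0)
    stop("configuration error: unknown column kind '", bad[1], "'")
  lower_median <- function(x) sort(x)[floor((length(x) + 1) / 2)]
  mode_first <- function(x) {
    ux <- unique(x)
    ux[which.max(tabulate(match(x, ux)))]
  }
  vapply(seq_len(ncol(feature_matrix)), function(j) {
    x <- feature_matrix[, j]
    switch(column_kinds[j],
           numerical = mean(x),
           ordinal = lower_median(x),
           nominal = mode_first(x))
  }, numeric(1))
}

# Column kinds over the full feature block: genes numerical, clinical kinds
# from the cohort (simulator default) or all numerical.
resolve_column_kinds <- function(cohort, column_kinds = NULL) {
  clin <- column_kinds %||% cohort$column_kinds %||%
    setNames(rep("numerical", length(cohort$clinical_columns)),
             cohort$clinical_columns)
  c(setNames(rep("numerical", length(cohort$gene_columns)),
             cohort$gene_columns),
    clin[cohort$clinical_columns])
}

# Aggregated samples for a subject subset: full history (visits 1..N-1)
# aggregated per column kind, target = score at visit N.  Numerical columns
# aggregate on the scaled features; ordinal/nominal on the raw values (their
# statistics are invariant to the monotone z-scoring anyway).
build_aggregated_samples <- function(cohort, ids, kinds) {
  rows_list <- list(); targets <- numeric(0); tps <- numeric(0)
  subj <- character(0)
  feat_cols <- c(cohort$gene_columns, cohort$clinical_columns)
  numerical <- kinds[feat_cols] == "numerical"
  for (id in ids) {
    rows <- subject_rows(cohort, id)
    n_vis <- length(rows)
    if (n_vis < 2) next
    hist_rows <- rows[seq_len(n_vis - 1)]
    mat <- cohort$scaled[hist_rows, feat_cols, drop = FALSE]
    raw <- cohort$features[hist_rows, feat_cols, drop = FALSE]
    mat[, !numerical] <- raw[, !numerical]
    rows_list[[length(rows_list) + 1]] <-
      aggregate_history(mat, kinds[feat_cols])
    targets <- c(targets, cohort$visits$score_total[rows[n_vis]])
    tps <- c(tps, n_vis)
    subj <- c(subj, id)
  }
  if (length(rows_list) == 0)
    return(NULL)
  list(x = do.call(rbind, rows_list), y = targets,
       time_point = tps, subject_id = subj)
}

fit_predict_baseline <- function(name, train, test, seed) {
  tr <- data.frame(train$x); tr$.y <- train$y
  te <- data.frame(test$x)
  withr::with_seed(seed, switch(name,
    linear_regression = {
      fit <- stats::lm(.y ~ ., data = tr)
      co <- stats::coef(fit)
      co[is.na(co)] <- 0  # rank-deficient designs: drop aliased columns
      as.numeric(cbind(1, as.matrix(te[, names(co)[-1], drop = FALSE])) %*% co)
    },
    svm = {
      fit <- e1071::svm(.y ~ ., data = tr)
      as.numeric(stats::predict(fit, te))
    },
    decision_tree = {
      fit <- rpart::rpart(.y ~ ., data = tr)
      as.numeric(stats::predict(fit, te))
    },
    random_forest = {
      fit <- randomForest::randomForest(x = train$x, y = train$y)
      as.numeric(stats::predict(fit, test$x))
    },
    stop("unknown baseline model '", name, "'")))
}

#' Run the classical baselines over shared cross-validation folds
#'
#' Each subject's historical visits (all but the last) are aggregated per
#' column kind, and linear regression, support-vector regression, a decision
#' tree and a random forest are fit to predict the final-visit score.
#' Evaluation reuses the PIE/PIC machinery; folds must be the same
#' [make_folds()] object used for the recurrent model so the comparison is
#' paired.
#'
#' @param cohort an (unscaled) `prog_cohort`.
#' @param folds a [make_folds()] object.
#' @param seed seed for the stochastic learners (forest, SVR internals).
#' @param column_kinds optional named kinds over clinical columns; defaults
#'   to the cohort's simulator-recorded kinds, else all-numerical.
#' @param models subset of the four baseline names to run.
#' @return list per model: `folds` (per-fold `metric_report`s) and `summary`
#'   (mean ± SE of PIE/PIC), plus the settings used.
#' @export
run_baselines <- function(cohort, folds, seed = 1, column_kinds = NULL,
                          models = c("linear_regression", "svm",
                                     "decision_tree", "random_forest")) {
  check_folds(folds, cohort)
  kinds <- resolve_column_kinds(cohort, column_kinds)
  all_ids <- cohort_subjects(cohort)
  out <- setNames(vector("list", length(models)), models)
  for (m in models) out[[m]] <- list(folds = vector("list", folds$n_folds))

  for (f in seq_len(folds$n_folds)) {
    test_ids <- names(folds$assignment)[folds$assignment == f]
    train_ids <- setdiff(all_ids, test_ids)
    scaled <- scale_cohort(cohort, fit_scaling(cohort, train_ids))
    train <- build_aggregated_samples(scaled, train_ids, kinds)
    test <- build_aggregated_samples(scaled, test_ids, kinds)
    if (is.null(train) || is.null(test))
      stop("argument error: a fold has no subjects with >= 2 visits")
    for (m in models) {
      pred <- fit_predict_baseline(m, train, test, derive_seed(seed, f))
      ps <- data.frame(subject_id = test$subject_id,
                       target_visit_index = test$time_point,
                       history_length = test$time_point - 1,
                       y_true = test$y, y_pred = pred,
                       stringsAsFactors = FALSE)
      out[[m]]$folds[[f]] <- metric_report(ps)
    }
  }
  for (m in models) {
    pies <- vapply(out[[m]]$folds, function(r) r$pie, numeric(1))
    pics <- vapply(out[[m]]$folds, function(r) r$pic, numeric(1))
    out[[m]]$summary <- data.frame(
      metric = c("PIE", "PIC"),
      mean = c(mean(pies), mean(pics)),
      se = c(stats::sd(pies), stats::sd(pics)) / sqrt(folds$n_folds))
  }
  attr(out, "folds") <- folds
  attr(out, "seed") <- seed
  out
}
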