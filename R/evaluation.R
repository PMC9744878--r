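# A prediction set is a data.frame with one record per (subject, target
# visit, history length): subject_id, target_visit_index (1-based visit
# position of the target, 2..N), history_length, y_true, y_pred.  Rows with
# history_length == target_visit_index - 1 carry the full history.

check_predset <- function(preds) {
  req <- c("subject_id", "target_visit_index", "history_length",
           "y_true", "y_pred")
  miss <- setdiff(req, names(preds))
  if (length(miss) > 0)
    stop("format error: prediction set lacks column(s) ",
         paste(miss, collapse = ", "))
  if (nrow(preds) == 0)
    stop("empty-input error: prediction set has no records")
  if (any(preds$y_true < 0 | preds$y_true > SCORE_MAX))
    stop("range error: y_true outside [0, 272]")
  invisible(preds)
}

full_history_rows <- function(preds) {
  preds[preds$history_length == preds$target_visit_index - 1, , drop = FALSE]
}

#' Progression Identification Error (PIE)
#'
#' Per prediction time point `t` (the target visit position), the RMSE
#' between predicted and true scores over subjects; PIE is the unweighted
#' mean of these per-time-point RMSEs.  With `pooled = TRUE`, a single RMSE
#' over all records is reported instead.
#'
#' @param preds a prediction-set data.frame; only full-history records are
#'   used (history length = target visit position - 1).
#' @param pooled pool all records into one RMSE instead of averaging
#'   per-time-point RMSEs.
#' @return list with `pie`, `rmse_by_timepoint` (data.frame: `time_point`,
#'   `rmse`, `n`) and `pooled_rmse`.
#' @export
compute_pie <- function(preds, pooled = FALSE) {
  check_predset(preds)
  fh <- full_history_rows(preds)
  if (nrow(fh) == 0)
    stop("empty-input error: no full-history records in prediction set")
  by_tp <- split(fh, fh$target_visit_index)
  tab <- data.frame(
    time_point = as.numeric(names(by_tp)),
    rmse = vapply(by_tp, function(d) rmse(d$y_true, d$y_pred), numeric(1)),
    n = vapply(by_tp, nrow, integer(1)),
    row.names = NULL
  )
  list(pie = if (pooled) rmse(fh$y_true, fh$y_pred) else mean(tab$rmse),
       rmse_by_timepoint = tab,
       pooled_rmse = rmse(fh$y_true, fh$y_pred))
}

#' Progression Identification Correlation (PIC)
#'
#' Per prediction time point, the Spearman rank-order correlation between
#' predicted and true scores; PIC is their unweighted mean.  Time points
#' with fewer than `min_n` records or constant true scores cannot support a
#' rank correlation and are excluded with a message.
#'
#' @param preds a prediction-set data.frame (full-history records used).
#' @param min_n minimum records per time point (default 3).
#' @return list with `pic`, `cor_by_timepoint` (data.frame: `time_point`,
#'   `rho`, `n`) and `excluded` time points.
#' @export
compute_pic <- function(preds, min_n = 3) {
  check_predset(preds)
  fh <- full_history_rows(preds)
  if (nrow(fh) == 0)
    stop("empty-input error: no full-history records in prediction set")
  by_tp <- split(fh, fh$target_visit_index)
  ok <- vapply(by_tp, function(d)
    nrow(d) >= min_n && stats::sd(d$y_true) > 0, logical(1))
  if (!any(ok))
    stop("empty-input error: no time point supports a rank correlation")
  if (any(!ok))
    message("excluded time point(s) from PIC: ",
            paste(names(by_tp)[!ok], collapse = ", "))
  kept <- by_tp[ok]
  tab <- data.frame(
    time_point = as.numeric(names(kept)),
    rho = vapply(kept, function(d) {
      # constant predictions cannot be ranked against the truth: NA, not 0
      if (stats::sd(d$y_pred) == 0) NA_real_
      else stats::cor(d$y_true, d$y_pred, method = "spearman")
    }, numeric(1)),
    n = vapply(kept, nrow, integer(1)),
    row.names = NULL
  )
  list(pic = mean(tab$rho), cor_by_timepoint = tab,
       excluded = as.numeric(names(by_tp)[!ok]))
}

#' Full metric report for a prediction set
#'
#' @param preds a prediction-set data.frame.
#' @param pooled see [compute_pie()].
#' @return list of class `metric_report` with `pie`, `pic`, the per-time-point
#'   tables and record counts.
#' @export
metric_report <- function(preds, pooled = FALSE) {
  pie <- compute_pie(preds, pooled = pooled)
  pic <- tryCatch(compute_pic(preds),
                  error = function(e) list(pic = NA_real_,
                                           cor_by_timepoint = NULL,
                                           excluded = numeric(0)))
  structure(list(pie = pie$pie, pic = pic$pic,
                 rmse_by_timepoint = pie$rmse_by_timepoint,
                 cor_by_timepoint = pic$cor_by_timepoint,
                 pooled_rmse = pie$pooled_rmse,
                 n = nrow(full_history_rows(preds))),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric_report: PIE %.3f, PIC %s (%d full-history records)\n",
              x$pie, ifelse(is.na(x$pic), "NA", sprintf("%.3f", x$pic)), x$n))
  invisible(x)
}

#' Truncated-history evaluation (RMSE by history depth)
#'
#' For each depth `k`, predicts every eligible subject's final-visit score
#' using only the `k` most recent prior visits (subjects with fewer than
#' `k` prior visits are excluded at that depth), and reports the RMSE and
#' subject count per depth.
#'
#' @param model trained `prog_model`.
#' @param cohort scaled `prog_cohort`.
#' @param max_history largest history depth to evaluate.
#' @param include_nontranscriptomic drop clinical columns when `FALSE`.
#' @return data.frame: `k`, `rmse` (NA when no subject qualifies), `n`.
#' @export
history_ablation <- function(model, cohort, max_history,
                             include_nontranscriptomic = TRUE) {
  if (!is.numeric(max_history) || max_history < 1)
    stop("argument error: max_history must be >= 1")
  rows <- lapply(seq_len(max_history), function(k) {
    samples <- build_truncated_samples(cohort, k, include_nontranscriptomic)
    if (length(samples) == 0)
      return(data.frame(k = k, rmse = NA_real_, n = 0L))
    ps <- predict_samples(model, samples)
    data.frame(k = k, rmse = rmse(ps$y_true, ps$y_pred), n = nrow(ps))
  })
  do.call(rbind, rows)
}

#' Subject-level fold assignment
#'
#' @param cohort a `prog_cohort`.
#' @param n_folds number of folds.
#' @param seed assignment seed (identical seed, identical folds).
#' @return object of class `prog_folds`: `assignment` (named integer vector
#'   over subjects with >= 2 visits), `n_folds`, `seed`.
#' @export
make_folds <- function(cohort, n_folds = 5, seed = 1) {
  nv <- table(cohort$visits$subject_id)
  eligible <- names(nv)[nv >= 2]
  if (length(eligible) < n_folds)
    stop("argument error: need at least ", n_folds,
         " subjects with >= 2 visits")
  assignment <- withr::with_seed(seed, {
    setNames(sample(rep(seq_len(n_folds), length.out = length(eligible))),
             eligible)
  })
  structure(list(assignment = assignment, n_folds = n_folds, seed = seed),
            class = "prog_folds")
}

check_folds <- function(folds, cohort) {
  if (!inherits(folds, "prog_folds"))
    stop("integrity error: folds must come from make_folds()")
  if (length(setdiff(names(folds$assignment), cohort_subjects(cohort))) > 0)
    stop("integrity error: fold subjects are not all present in the cohort")
  invisible(folds)
}

#' Subject-level k-fold cross-validation of the dense recurrent model
#'
#' Folds partition the subjects with at least two visits; single-visit
#' subjects join every training split (they inform feature scaling but yield
#' no windows).  Per fold, feature scaling is fit on training subjects only,
#' the model is trained from a fresh initialization, and PIE/PIC are
#' computed on the held-out subjects.  Fold metrics are aggregated as mean
#' and standard error (sd / sqrt(n_folds)).
#'
#' @param cohort an (unscaled) `prog_cohort`.
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @param n_folds number of folds (5 in the reference protocol).
#' @param seed fold-assignment seed.
#' @param folds optional pre-made [make_folds()] object (shared with
#'   [run_baselines()] so comparisons use identical splits).
#' @param include_nontranscriptomic drop clinical columns when `FALSE`.
#' @return list with `folds` (per-fold `metric_report`s), `fold_assignment`,
#'   and `summary` (mean and SE of PIE and PIC across folds).
#' @export
crossvalidate <- function(cohort, model_cfg, train_cfg, n_folds = 5,
                          seed = 1, folds = NULL,
                          include_nontranscriptomic = TRUE) {
  if (is.null(folds)) folds <- make_folds(cohort, n_folds, seed)
  check_folds(folds, cohort)
  all_ids <- cohort_subjects(cohort)
  reports <- vector("list", folds$n_folds)
  for (f in seq_len(folds$n_folds)) {
    test_ids <- names(folds$assignment)[folds$assignment == f]
    train_ids <- setdiff(all_ids, test_ids)
    scaling <- fit_scaling(cohort, train_ids)
    scaled <- scale_cohort(cohort, scaling)
    tr_samples <- build_history_samples_for(scaled, train_ids,
                                            include_nontranscriptomic)
    te_samples <- build_history_samples_for(scaled, test_ids,
                                            include_nontranscriptomic)
    fold_model_cfg <- model_cfg
    fold_model_cfg$seed <- derive_seed(model_cfg$seed, f)
    fold_train_cfg <- train_cfg
    fold_train_cfg$seed <- derive_seed(train_cfg$seed, f)
    model <- init_model(fold_model_cfg, ncol(tr_samples[[1]]$x_seq))
    fit <- train_model(model, tr_samples, fold_train_cfg)
    preds <- predict_samples(fit$model, te_samples)
    reports[[f]] <- metric_report(preds)
  }
  pies <- vapply(reports, function(r) r$pie, numeric(1))
  pics <- vapply(reports, function(r) r$pic, numeric(1))
  list(folds = reports, fold_assignment = folds,
       summary = data.frame(
         metric = c("PIE", "PIC"),
         mean = c(mean(pies), mean(pics)),
         se = c(stats::sd(pies), stats::sd(pics)) / sqrt(folds$n_folds)))
}

# History windows restricted to a subject subset.
build_history_samples_for <- function(cohort, ids, include_nontranscriptomic) {
  samples <- build_history_samples(cohort, include_nontranscriptomic)
  keep <- vapply(samples, function(s) s$subject_id %in% ids, logical(1))
  samples[keep]
}

#' Aggregate fold-level metrics as mean and standard error
#'
#' @param values numeric vector of fold metrics.
#' @return list with `mean` and `se` (sd / sqrt(n)).
#' @export
fold_mean_se <- function(values) {
  list(mean = mean(values), se = stats::sd(values) / sqrt(length(values)))
}
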