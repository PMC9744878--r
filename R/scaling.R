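#' Fit per-column feature scaling on training subjects only
#'
#' Gene columns are transformed as `log2(x + 1)` (standard for TPM-scale
#' abundances) and then centred/scaled; clinical columns are z-scored on the
#' raw values.  Location and scale are estimated exclusively from the visits
#' of `train_subject_ids`, so applying the result to held-out subjects leaks
#' no test statistics.  Zero-variance columns get scale 1 (pass-through to 0
#' after centring) and are reported via a message.
#'
#' @param cohort a `prog_cohort`.
#' @param train_subject_ids non-empty subset of the cohort's subject ids.
#' @return object of class `prog_scaling` (`center`, `scale` named vectors
#'   over all feature columns, plus bookkeeping).
#' @export
fit_scaling <- function(cohort, train_subject_ids) {
  stopifnot(inherits(cohort, "prog_cohort"))
  if (length(train_subject_ids) == 0)
    stop("train subject set must be non-empty")
  unknown <- setdiff(train_subject_ids, cohort_subjects(cohort))
  if (length(unknown) > 0)
    stop("key error: unknown subject id(s): ", paste(head(unknown, 3), collapse = ", "))

  rows <- cohort$visits$subject_id %in% train_subject_ids
  mat <- cohort$features[rows, , drop = FALSE]
  if (length(cohort$gene_columns) > 0)
    mat[, cohort$gene_columns] <- log2(mat[, cohort$gene_columns, drop = FALSE] + 1)

  ctr <- colMeans(mat)
  scl <- apply(mat, 2, stats::sd)
  zero_var <- colnames(mat)[!is.finite(scl) | scl == 0]
  scl[!is.finite(scl) | scl == 0] <- 1
  if (length(zero_var) > 0)
    message(length(zero_var), " zero-variance column(s) passed through with scale 1")

  structure(list(center = ctr, scale = scl,
                 gene_columns = cohort$gene_columns,
                 zero_variance = zero_var,
                 train_subject_ids = sort(unique(train_subject_ids))),
            class = "prog_scaling")
}

#' Apply a fitted scaling to a cohort
#'
#' @param cohort a `prog_cohort`.
#' @param scaling a `prog_scaling` from [fit_scaling()].
#' @return the cohort with `$scaling` set and `$scaled` holding the
#'   transformed feature matrix.
#' @export
scale_cohort <- function(cohort, scaling) {
  stopifnot(inherits(cohort, "prog_cohort"), inherits(scaling, "prog_scaling"))
  if (!identical(names(scaling$center), colnames(cohort$features)))
    stop("dimension error: scaling columns do not match cohort feature columns")
  mat <- cohort$features
  if (length(scaling$gene_columns) > 0)
    mat[, scaling$gene_columns] <-
      log2(mat[, scaling$gene_columns, drop = FALSE] + 1)
  mat <- sweep(mat, 2, scaling$center, "-")
  mat <- sweep(mat, 2, scaling$scale, "/")
  cohort$scaling <- scaling
  cohort$scaled <- mat
  cohort
}

# One history window: rows `hist_idx` (cohort row indices, consecutive visits
# of one subject) predicting the visit at row `target_idx`.  Each step's
# augmented vector is [scaled features, dt to the next visit in years,
# observed score / 272].
make_window_sample <- function(cohort, hist_idx, target_idx, feat_cols) {
  months <- cohort$visits$visit_month[c(hist_idx, target_idx)]
  dts <- diff(months) / 12
  scores <- cohort$visits$score_total[hist_idx]
  x <- cbind(cohort$scaled[hist_idx, feat_cols, drop = FALSE],
             dt = dts, y_prev = scores / SCORE_MAX)
  structure(list(
    subject_id = cohort$visits$subject_id[hist_idx[1]],
    x_seq = unname(x),
    n = length(hist_idx),
    target = cohort$visits$score_total[target_idx],
    target_visit_index = match(target_idx, subject_rows(
      cohort, cohort$visits$subject_id[target_idx])),
    target_month = cohort$visits$visit_month[target_idx],
    last_score = scores[length(scores)]
  ), class = "prog_sample")
}

#' Build next-visit history-window training samples
#'
#' For every subject with `N >= 2` visits, emits `N - 1` samples whose
#' histories are the first `1, 2, ..., N-1` visits, each targeting the score
#' at the immediately following visit.  Step `i` of a history is the scaled
#' feature vector at visit `i` augmented with the time gap to visit `i + 1`
#' (years) and the observed score at visit `i` divided by 272, so every step
#' has length `Q + 2`.  Subjects with a single visit yield no samples.
#'
#' @param cohort a scaled `prog_cohort` (see [scale_cohort()]).
#' @param include_nontranscriptomic drop clinical columns from the feature
#'   block when `FALSE` (RNA-seq-features-only ablation).
#' @return list of `prog_sample` objects.
#' @export
build_history_samples <- function(cohort, include_nontranscriptomic = TRUE) {
  stopifnot(inherits(cohort, "prog_cohort"))
  if (is.null(cohort$scaled))
    stop("state error: cohort must be scaled (fit_scaling + scale_cohort) first")
  feat_cols <- if (include_nontranscriptomic)
    c(cohort$gene_columns, cohort$clinical_columns) else cohort$gene_columns

  samples <- list()
  for (id in cohort_subjects(cohort)) {
    rows <- subject_rows(cohort, id)
    n_vis <- length(rows)
    if (n_vis < 2) next
    for (n in seq_len(n_vis - 1)) {
      samples[[length(samples) + 1]] <-
        make_window_sample(cohort, rows[seq_len(n)], rows[n + 1], feat_cols)
    }
  }
  samples
}

# Truncated-history samples for the evaluation scheme: the k most recent
# visits before each subject's final visit, predicting the final visit.
build_truncated_samples <- function(cohort, k, include_nontranscriptomic = TRUE) {
  if (is.null(cohort$scaled))
    stop("state error: cohort must be scaled first")
  feat_cols <- if (include_nontranscriptomic)
    c(cohort$gene_columns, cohort$clinical_columns) else cohort$gene_columns
  samples <- list()
  for (id in cohort_subjects(cohort)) {
    rows <- subject_rows(cohort, id)
    n_vis <- length(rows)
    if (n_vis < 2 || n_vis - 1 < k) next
    hist_idx <- rows[(n_vis - k):(n_vis - 1)]
    samples[[length(samples) + 1]] <-
      make_window_sample(cohort, hist_idx, rows[n_vis], feat_cols)
  }
  samples
}
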