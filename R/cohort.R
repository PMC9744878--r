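#' Construct a longitudinal cohort object
#'
#' A `prog_cohort` couples a visit table (one row per subject-visit, sorted by
#' subject then visit month) with a numeric feature matrix whose rows align
#' with the visit table and whose columns are genes followed by clinical
#' (non-transcriptomic) features in a fixed cohort-wide order.
#'
#' @param visits data.frame with columns `subject_id`, `visit_id`,
#'   `visit_month`, `updrs_p1`..`updrs_p4` (non-negative integer part scores)
#'   and `score_total` (their sum, 0--272).
#' @param features numeric matrix, `nrow(visits)` rows, genes then clinical
#'   columns; gene values must be non-negative (TPM-like abundances).
#' @param gene_columns,clinical_columns ordered column-name character vectors.
#' @param column_kinds optional named character vector over clinical columns
#'   with values `"numerical"`, `"ordinal"` or `"nominal"` (used by the
#'   visit-aggregation baselines).
#' @param latent optional data.frame of simulator ground truth
#'   (`subject_id`, `visit_month`, `baseline`, `rate`, `latent`).
#' @return object of class `prog_cohort`.
#' @export
new_cohort <- function(visits, features, gene_columns, clinical_columns,
                       column_kinds = NULL, latent = NULL) {
  req <- c("subject_id", "visit_id", "visit_month",
           paste0("updrs_p", 1:4), "score_total")
  miss <- setdiff(req, names(visits))
  if (length(miss) > 0)
    stop("format error: visit table lacks column(s) ", paste(miss, collapse = ", "))
  if (nrow(visits) != nrow(features))
    stop("dimension error: visit table and feature matrix row counts differ")
  cols <- c(gene_columns, clinical_columns)
  if (!identical(colnames(features), cols))
    stop("dimension error: feature matrix columns must be genes then clinical, in order")
  if (any(!is.finite(features)))
    stop("integrity error: feature matrix contains missing or non-finite values")
  if (length(gene_columns) > 0 && any(features[, gene_columns, drop = FALSE] < 0))
    stop("integrity error: gene expression values must be non-negative")

  ord <- order(visits$subject_id, visits$visit_month)
  visits <- visits[ord, , drop = FALSE]
  features <- features[ord, , drop = FALSE]
  rownames(visits) <- NULL

  key <- paste(visits$subject_id, visits$visit_id)
  if (anyDuplicated(key))
    stop("integrity error: duplicate subject-visit row for key ",
         key[duplicated(key)][1])
  by_subj <- split(visits$visit_month, visits$subject_id)
  bad <- names(by_subj)[vapply(by_subj, function(m) any(diff(m) <= 0), logical(1))]
  if (length(bad) > 0)
    stop("integrity error: visit months not strictly increasing for subject ",
         bad[1])
  if (any(visits$score_total !=
          rowSums(visits[, paste0("updrs_p", 1:4)])))
    stop("integrity error: score_total must equal the sum of the four part scores")
  if (any(visits$score_total < 0 | visits$score_total > SCORE_MAX))
    stop("range error: score_total outside [0, 272]")

  structure(list(
    visits = visits,
    features = features,
    gene_columns = gene_columns,
    clinical_columns = clinical_columns,
    column_kinds = column_kinds,
    latent = latent,
    scaling = NULL,
    scaled = NULL
  ), class = "prog_cohort")
}

#' @export
print.prog_cohort <- function(x, ...) {
  nv <- table(x$visits$subject_id)
  cat(sprintf("prog_cohort: %d subjects, %d visits (%d-%d per subject)\n",
              length(nv), nrow(x$visits), min(nv), max(nv)))
  cat(sprintf("  features: %d genes + %d clinical = %d\n",
              length(x$gene_columns), length(x$clinical_columns),
              ncol(x$features)))
  cat(sprintf("  scaled: %s\n", if (is.null(x$scaled)) "no" else "yes"))
  invisible(x)
}

#' Number of subjects / subject ids
#' @param cohort a `prog_cohort`.
#' @return character vector of subject ids.
#' @export
cohort_subjects <- function(cohort) unique(cohort$visits$subject_id)

# Row indices of one subject's visits, in month order.
subject_rows <- function(cohort, id) which(cohort$visits$subject_id == id)

#' Assemble the total severity score from its four parts
#'
#' The target is the total MDS-UPDRS score, the sum of the Part I-IV
#' questionnaire scores, bounded by 0 (normal) and 272 (most severe).
#'
#' @param parts numeric vector of four non-negative integers.
#' @return integer total.
#' @export
assemble_target <- function(parts) {
  if (length(parts) != 4 || any(!is.finite(parts)) || any(parts != round(parts)))
    stop("range error: parts must be four integers")
  if (any(parts < 0))
    stop("range error: part scores must be non-negative")
  total <- sum(parts)
  if (total > SCORE_MAX)
    stop("range error: part scores sum to ", total, " > ", SCORE_MAX)
  as.integer(total)
}

read_table_auto <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.csv(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Load a cohort from long-format expression and clinical tables
#'
#' Inner-joins the two tables on (`subject_id`, `visit_id`); rows present in
#' only one table are dropped with a message, subjects left without any joined
#' visit are dropped.  The total severity target is assembled from the four
#' part-score columns of the clinical table.
#'
#' @param expression_path delimited table (.csv or .tsv/.txt): `subject_id`,
#'   `visit_id`, `visit_month`, one column per gene (non-negative numeric).
#' @param clinical_path delimited table: `subject_id`, `visit_id`,
#'   `visit_month`, clinical feature columns, `updrs_p1`..`updrs_p4`.
#' @param meta_path optional JSON sidecar written by [write_cohort()]
#'   restoring column kinds and simulator ground truth.
#' @return a [new_cohort()] object.
#' @export
load_cohort <- function(expression_path, clinical_path, meta_path = NULL) {
  expr <- read_table_auto(expression_path)
  clin <- read_table_auto(clinical_path)
  keys <- c("subject_id", "visit_id", "visit_month")
  for (tab in list(expression = expr, clinical = clin)) {
    miss <- setdiff(keys, names(tab))
    if (length(miss) > 0)
      stop("format error: missing key column(s) ", paste(miss, collapse = ", "))
  }
  if (nrow(clin) == 0) {
    warning("clinical table is empty: returning an empty cohort")
    empty <- data.frame(subject_id = character(), visit_id = character(),
                        visit_month = numeric(), updrs_p1 = integer(),
                        updrs_p2 = integer(), updrs_p3 = integer(),
                        updrs_p4 = integer(), score_total = integer())
    genes <- setdiff(names(expr), keys)
    return(new_cohort(empty, matrix(0, 0, length(genes),
                                    dimnames = list(NULL, genes)),
                      genes, character()))
  }
  part_cols <- paste0("updrs_p", 1:4)
  miss <- setdiff(part_cols, names(clin))
  if (length(miss) > 0)
    stop("format error: clinical table lacks part-score column(s) ",
         paste(miss, collapse = ", "))

  for (tab_name in c("expr", "clin")) {
    tab <- get(tab_name)
    key <- paste(tab$subject_id, tab$visit_id)
    if (anyDuplicated(key))
      stop("integrity error: duplicate subject-visit row for key ",
           key[duplicated(key)][1], " in ", tab_name, " table")
  }

  merged <- merge(clin, expr[, c("subject_id", "visit_id",
                                 setdiff(names(expr), keys))],
                  by = c("subject_id", "visit_id"))
  n_dropped <- (nrow(expr) - nrow(merged)) + (nrow(clin) - nrow(merged))
  if (n_dropped > 0)
    message("dropped ", n_dropped, " unmatched subject-visit row(s) during join")

  gene_cols <- setdiff(names(expr), keys)
  clin_cols <- setdiff(names(clin), c(keys, part_cols, "score_total"))
  feat_cols <- c(gene_cols, clin_cols)
  feats <- as.matrix(merged[, feat_cols, drop = FALSE])
  if (!is.numeric(feats) || any(is.na(feats)))
    stop("integrity error: feature columns must be numeric with no missing values")

  parts <- as.matrix(merged[, part_cols])
  visits <- data.frame(
    subject_id = as.character(merged$subject_id),
    visit_id = as.character(merged$visit_id),
    visit_month = as.numeric(merged$visit_month),
    stringsAsFactors = FALSE
  )
  visits[part_cols] <- lapply(as.data.frame(parts), as.integer)
  visits$score_total <- vapply(seq_len(nrow(parts)),
                               function(i) assemble_target(parts[i, ]),
                               integer(1))

  kinds <- NULL; latent <- NULL
  if (!is.null(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$column_kinds))
      kinds <- setNames(unlist(meta$column_kinds), names(meta$column_kinds))
    if (!is.null(meta$latent)) latent <- as.data.frame(meta$latent)
  }
  new_cohort(visits, feats, gene_cols, clin_cols,
             column_kinds = kinds, latent = latent)
}

#' Write a cohort as long-format delimited tables plus a JSON sidecar
#'
#' Produces `expression.csv` (keys + gene columns), `clinical.csv` (keys +
#' clinical columns + part scores) and `cohort_meta.json` (simulation config,
#' column kinds, and latent trajectories when present, enabling
#' parameter-recovery tests).
#'
#' @param cohort a `prog_cohort`.
#' @param dir output directory, created if needed.
#' @return invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  keys <- cohort$visits[, c("subject_id", "visit_id", "visit_month")]
  expr <- cbind(keys, as.data.frame(
    cohort$features[, cohort$gene_columns, drop = FALSE]))
  clin <- cbind(keys, as.data.frame(
    cohort$features[, cohort$clinical_columns, drop = FALSE]),
    cohort$visits[, paste0("updrs_p", 1:4)])
  p_expr <- file.path(dir, "expression.csv")
  p_clin <- file.path(dir, "clinical.csv")
  p_meta <- file.path(dir, "cohort_meta.json")
  utils::write.csv(expr, p_expr, row.names = FALSE)
  utils::write.csv(clin, p_clin, row.names = FALSE)
  meta <- list(config = attr(cohort, "sim_config"),
               column_kinds = as.list(cohort$column_kinds),
               latent = cohort$latent)
  jsonlite::write_json(meta, p_meta, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(expression = p_expr, clinical = p_clin, meta = p_meta))
}
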