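#' Configuration for the synthetic longitudinal cohort simulator
#'
#' The simulator emulates the statistical shape of a longitudinal PD
#' transcriptomic study: a few hundred subjects followed over up to four
#' years at irregular month intervals, tens of thousands of TPM-like gene
#' columns (configurable, small by default), a block of clinical columns, and
#' a bounded integer severity target (0--272) that trends upward with a
#' subject-specific rate.
#'
#' @param n_subjects number of subjects.
#' @param n_genes number of gene columns (log-normal TPM-like background).
#' @param n_clinical number of clinical (non-transcriptomic) columns; the
#'   first few form a motor-subscore block correlated with the target, the
#'   rest are ordinal / nominal / numerical noise.
#' @param visit_months allowed visit schedule in months from baseline.
#' @param dropout_prob probability follow-up stops after each visit (applied
#'   from `min_visits` onward, so every subject reaches at least
#'   `min_visits` visits when the schedule allows).
#' @param n_signal_genes number of progression-linked genes.
#' @param effect_size mean slope of signal genes (natural-log expression per
#'   unit latent severity, latent scaled to `[0, 1]` by 272).
#' @param base_score mean baseline severity; `base_sd` its between-subject sd
#'   (0 = deterministic baseline).
#' @param base_sd between-subject sd of the baseline severity.
#' @param rate_mean,rate_sd per-subject progression rate distribution
#'   (score points per year).
#' @param score_noise_sd observation noise sd on the severity score.
#' @param expr_log_mean,expr_log_sd per-gene log-normal background
#'   (natural-log mean / sd of baseline TPM).
#' @param expr_noise_sd within-gene log-scale observation noise.
#' @param min_visits earliest visit after which dropout may occur (default 2,
#'   so every subject contributes at least one training window; set 1 to
#'   allow single-visit subjects).
#' @param part_props proportions by which the total score is partitioned into
#'   the four instrument parts (Part-III dominant by default).
#' @param seed RNG seed; same seed and config give byte-identical tables.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 200, n_genes = 500, n_clinical = 30,
                       visit_months = c(0, 6, 12, 24, 36, 48),
                       dropout_prob = 0.15, n_signal_genes = 50,
                       effect_size = 1, base_score = 25, base_sd = 0,
                       rate_mean = 8, rate_sd = 4, score_noise_sd = 3,
                       expr_log_mean = 2, expr_log_sd = 1.2,
                       expr_noise_sd = 0.5, min_visits = 2,
                       part_props = c(0.10, 0.15, 0.65, 0.10), seed = 1) {
  cfg <- list(
    n_subjects = check_count(n_subjects, "n_subjects"),
    n_genes = check_count(n_genes, "n_genes", min = 0L),
    n_clinical = check_count(n_clinical, "n_clinical", min = 0L),
    visit_months = visit_months,
    dropout_prob = check_number(dropout_prob, "dropout_prob", 0, 1),
    n_signal_genes = check_count(n_signal_genes, "n_signal_genes", min = 0L),
    effect_size = check_number(effect_size, "effect_size"),
    base_score = check_number(base_score, "base_score", 0, SCORE_MAX),
    base_sd = check_number(base_sd, "base_sd", 0),
    rate_mean = check_number(rate_mean, "rate_mean"),
    rate_sd = check_number(rate_sd, "rate_sd", 0),
    score_noise_sd = check_number(score_noise_sd, "score_noise_sd", 0),
    expr_log_mean = check_number(expr_log_mean, "expr_log_mean"),
    expr_log_sd = check_number(expr_log_sd, "expr_log_sd", 0),
    expr_noise_sd = check_number(expr_noise_sd, "expr_noise_sd", 0),
    min_visits = check_count(min_visits, "min_visits"),
    part_props = part_props,
    seed = check_count(seed, "seed", min = 0L)
  )
  if (length(visit_months) < 1 || any(diff(visit_months) <= 0) ||
      any(visit_months < 0))
    stop_config("visit_months", "must be non-negative and strictly increasing")
  if (cfg$n_signal_genes > cfg$n_genes)
    stop_config("n_signal_genes", "cannot exceed n_genes")
  if (length(part_props) != 4 || any(part_props < 0) || sum(part_props) <= 0)
    stop_config("part_props", "must be four non-negative proportions")
  cfg$min_visits <- min(cfg$min_visits, length(visit_months))
  structure(cfg, class = "sim_config")
}

#' Simulate a longitudinal cohort
#'
#' Each subject draws a baseline severity and a progression rate; latent
#' severity is `clip(baseline + rate * years, 0, 272)` and the observed total
#' score is `round(clip(latent + noise, 0, 272))`, partitioned into four part
#' scores by fixed proportions.  Signal genes follow a log-normal background
#' with an additive log-scale term proportional to latent severity (scaled to
#' `[0, 1]`); non-signal genes are progression-independent log-normal noise.
#' Clinical columns comprise a motor-subscore block correlated with Part III,
#' plus ordinal, nominal and numerical noise blocks.
#'
#' @param config a [sim_config()].
#' @return a `prog_cohort` carrying the latent trajectories in `$latent` and
#'   the config in attribute `"sim_config"`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n_max <- length(cfg$visit_months)
  ids <- sprintf("S%04d", seq_len(cfg$n_subjects))

  n_visits <- vapply(ids, function(id) {
    nv <- min(cfg$min_visits, n_max)
    while (nv < n_max && stats::runif(1) >= cfg$dropout_prob) nv <- nv + 1
    nv
  }, numeric(1))
  # dropout_prob = 0 keeps every subject on the full schedule
  baseline <- cfg$base_score + stats::rnorm(cfg$n_subjects, 0, cfg$base_sd)
  rate <- stats::rnorm(cfg$n_subjects, cfg$rate_mean, cfg$rate_sd)

  visit_rows <- list(); latent_rows <- list()
  for (i in seq_along(ids)) {
    months <- cfg$visit_months[seq_len(n_visits[i])]
    lat <- clip(baseline[i] + rate[i] * months / 12, 0, SCORE_MAX)
    obs <- as.integer(round(clip(
      lat + stats::rnorm(length(months), 0, cfg$score_noise_sd), 0, SCORE_MAX)))
    parts <- t(vapply(obs, split_integer, integer(4), props = cfg$part_props))
    visit_rows[[i]] <- data.frame(
      subject_id = ids[i],
      visit_id = sprintf("V%02d", match(months, cfg$visit_months)),
      visit_month = months,
      updrs_p1 = parts[, 1], updrs_p2 = parts[, 2],
      updrs_p3 = parts[, 3], updrs_p4 = parts[, 4],
      score_total = obs, stringsAsFactors = FALSE)
    latent_rows[[i]] <- data.frame(
      subject_id = ids[i], visit_month = months,
      baseline = baseline[i], rate = rate[i], latent = lat,
      stringsAsFactors = FALSE)
  }
  visits <- do.call(rbind, visit_rows)
  latent <- do.call(rbind, latent_rows)
  n_rows <- nrow(visits)

  # expression: log-normal background + log-additive progression signal
  gene_names <- sprintf("gene_%04d", seq_len(cfg$n_genes))
  signal_genes <- gene_names[seq_len(cfg$n_signal_genes)]
  mu_g <- stats::rnorm(cfg$n_genes, cfg$expr_log_mean, cfg$expr_log_sd)
  beta_g <- numeric(cfg$n_genes)
  if (cfg$n_signal_genes > 0)
    beta_g[seq_len(cfg$n_signal_genes)] <-
      stats::rnorm(cfg$n_signal_genes, cfg$effect_size,
                   0.25 * abs(cfg$effect_size))
  s <- latent$latent / SCORE_MAX
  log_expr <- outer(rep(1, n_rows), mu_g) + outer(s, beta_g) +
    matrix(stats::rnorm(n_rows * cfg$n_genes, 0, cfg$expr_noise_sd),
           n_rows, cfg$n_genes)
  expr <- exp(log_expr)
  colnames(expr) <- gene_names

  # clinical block: motor subscores tracking Part III, then ordinal /
  # nominal / numerical noise
  n_motor <- min(5L, cfg$n_clinical)
  rest <- cfg$n_clinical - n_motor
  n_ord <- rest %/% 3; n_nom <- rest %/% 6
  n_num <- rest - n_ord - n_nom
  clin <- matrix(0, n_rows, 0)
  kinds <- character(0)
  if (n_motor > 0) {
    w <- stats::runif(n_motor, 0.3, 0.9)
    motor <- outer(visits$updrs_p3, w) +
      matrix(stats::rnorm(n_rows * n_motor, 0, 2), n_rows, n_motor)
    colnames(motor) <- sprintf("clin_motor_%02d", seq_len(n_motor))
    clin <- cbind(clin, motor)
    kinds <- c(kinds, setNames(rep("numerical", n_motor), colnames(motor)))
  }
  if (n_ord > 0) {
    ord <- matrix(sample(0:4, n_rows * n_ord, replace = TRUE), n_rows, n_ord)
    colnames(ord) <- sprintf("clin_ord_%02d", seq_len(n_ord))
    clin <- cbind(clin, ord)
    kinds <- c(kinds, setNames(rep("ordinal", n_ord), colnames(ord)))
  }
  if (n_nom > 0) {
    nom <- matrix(sample(1:3, n_rows * n_nom, replace = TRUE), n_rows, n_nom)
    colnames(nom) <- sprintf("clin_nom_%02d", seq_len(n_nom))
    clin <- cbind(clin, nom)
    kinds <- c(kinds, setNames(rep("nominal", n_nom), colnames(nom)))
  }
  if (n_num > 0) {
    num <- matrix(stats::rnorm(n_rows * n_num), n_rows, n_num)
    colnames(num) <- sprintf("clin_num_%02d", seq_len(n_num))
    clin <- cbind(clin, num)
    kinds <- c(kinds, setNames(rep("numerical", n_num), colnames(num)))
  }

  cohort <- new_cohort(visits, cbind(expr, clin), gene_names, colnames(clin),
                       column_kinds = kinds, latent = latent)
  attr(cohort, "sim_config") <- unclass(cfg)
  attr(cohort, "signal_genes") <- signal_genes
  cohort
}

#' Diagnostic: per-gene correlation with latent severity
#'
#' Computes the Pearson correlation of every gene column with the latent
#' severity and summarizes signal vs non-signal genes.  Used by the test
#' suite to confirm the simulator injects a detectable progression signal.
#'
#' @param cohort a cohort produced by [simulate_cohort()].
#' @param config the `sim_config` it was produced with.
#' @return list with `signal` / `nonsignal` data.frames (`gene`, `r`) and the
#'   two mean absolute correlations.
#' @export
expected_signal_check <- function(cohort, config) {
  stopifnot(inherits(cohort, "prog_cohort"), inherits(config, "sim_config"))
  if (length(cohort$gene_columns) != config$n_genes)
    stop("dimension error: cohort gene count does not match config n_genes")
  if (is.null(cohort$latent))
    stop("cohort carries no latent trajectories; use simulate_cohort()")
  lat <- cohort$latent$latent
  r <- apply(cohort$features[, cohort$gene_columns, drop = FALSE], 2,
             function(g) if (stats::sd(g) == 0) 0 else stats::cor(g, lat))
  sig <- cohort$gene_columns[seq_len(config$n_signal_genes)]
  non <- setdiff(cohort$gene_columns, sig)
  list(
    signal = data.frame(gene = sig, r = unname(r[sig])),
    nonsignal = data.frame(gene = non, r = unname(r[non])),
    mean_abs_signal = if (length(sig) > 0) mean(abs(r[sig])) else NA_real_,
    mean_abs_nonsignal = if (length(non) > 0) mean(abs(r[non])) else NA_real_
  )
}
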