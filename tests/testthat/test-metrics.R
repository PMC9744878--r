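predset <- function(tp, truth, pred, hist = tp - 1) {
  data.frame(subject_id = sprintf("S%02d", seq_along(truth)),
             target_visit_index = tp, history_length = hist,
             y_true = truth, y_pred = pred, stringsAsFactors = FALSE)
}

test_that("PIE averages per-time-point RMSEs", {
  ps <- rbind(predset(2, c(10, 20), c(11, 19)),
              predset(3, 30, 33))
  out <- compute_pie(ps)
  expect_equal(out$rmse_by_timepoint$rmse, c(1, 3))
  expect_equal(out$pie, 2.0)
  # perfect predictions
  expect_equal(compute_pie(predset(2, c(5, 9, 40), c(5, 9, 40)))$pie, 0)
  # a single time point: PIE is that RMSE
  one <- predset(2, c(10, 14), c(12, 14))
  expect_equal(compute_pie(one)$pie, sqrt(2))
  expect_error(compute_pie(predset(2, 1, 1)[0, ]), "empty-input")
})

test_that("PIE matches a brute-force recomputation from raw records", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      tps <- sample(2:5, 40, replace = TRUE)
      ps <- predset(tps, sample(0:272, 40, TRUE), runif(40, 0, 272))
      brute <- mean(vapply(sort(unique(tps)), function(t) {
        d <- ps[ps$target_visit_index == t, ]
        sqrt(sum((d$y_pred - d$y_true)^2) / nrow(d))
      }, numeric(1)))
      expect_equal(compute_pie(ps)$pie, brute, tolerance = 1e-10)
    }
  })
})

test_that("PIE ignores truncated-history records and is order-invariant", {
  full <- predset(2, c(10, 20), c(12, 18))
  trunc <- predset(4, c(50, 60), c(0, 0), hist = 1)  # not full history
  expect_equal(compute_pie(rbind(full, trunc))$pie,
               compute_pie(full)$pie)
  shuffled <- full[c(2, 1), ]
  expect_equal(compute_pie(shuffled)$pie, compute_pie(full)$pie)
})

test_that("PIC is the mean per-time-point Spearman correlation", {
  expect_equal(compute_pic(predset(2, c(1, 2, 3), c(2, 4, 6)))$pic, 1.0)
  expect_equal(compute_pic(predset(2, c(1, 2, 3), c(6, 4, 2)))$pic, -1.0)
  # classical rank formula: 1 - 6 * sum(d^2) / (n^3 - n) = 0.8
  expect_equal(compute_pic(predset(2, c(1, 2, 3, 4), c(1, 3, 2, 4)))$pic, 0.8)
})

test_that("PIC excludes unsupported time points and errors when none remain", {
  ps <- rbind(predset(2, c(1, 2, 3, 4), c(1, 3, 2, 4)),
              predset(3, c(7, 7, 7), c(1, 2, 3)),   # constant truth
              predset(4, c(1, 2), c(1, 2)))          # too few records
  expect_message(out <- compute_pic(ps), "excluded")
  expect_equal(out$pic, 0.8)
  expect_setequal(out$excluded, c(3, 4))
  expect_error(compute_pic(predset(2, c(5, 5, 5), c(1, 2, 3))),
               "empty-input")
})

test_that("PIC is invariant to increasing transforms of predictions", {
  ps <- predset(2, c(3, 9, 27, 5), c(10, 30, 20, 12))
  ps2 <- ps; ps2$y_pred <- exp(ps$y_pred / 10) + 5
  expect_equal(compute_pic(ps)$pic, compute_pic(ps2)$pic)
})

test_that("fold metrics aggregate as mean and standard error", {
  agg <- fold_mean_se(c(6.0, 5.5, 6.5, 6.2, 5.8))
  expect_equal(agg$mean, 6.0)
  expect_equal(agg$se, sd(c(6.0, 5.5, 6.5, 6.2, 5.8)) / sqrt(5))
  expect_equal(agg$se, 0.1703, tolerance = 1e-4)
})

test_that("fold assignments partition eligible subjects deterministically", {
  co <- tiny_cohort(n_subjects = 23, seed = 30)
  f1 <- make_folds(co, 5, seed = 3)
  f2 <- make_folds(co, 5, seed = 3)
  expect_identical(f1$assignment, f2$assignment)
  nv <- table(co$visits$subject_id)
  eligible <- names(nv)[nv >= 2]
  expect_setequal(names(f1$assignment), eligible)
  expect_equal(sort(unique(f1$assignment)), 1:5)
  expect_error(make_folds(tiny_cohort(n_subjects = 3), 5), "argument error")
})

test_that("history ablation respects availability and reduces to full history", {
  co <- simulate_cohort(sim_config(n_subjects = 12, n_genes = 8,
                                   n_signal_genes = 2, n_clinical = 4,
                                   visit_months = c(0, 6),
                                   dropout_prob = 0, seed = 31))
  sc <- scale_cohort(co, fit_scaling(co, cohort_subjects(co)))
  cfg <- model_config(cells_per_cb = 4, cbs_per_db = 1, n_dbs = 1,
                      batch_norm = FALSE, seed = 32)
  m <- init_model(cfg, ncol(sc$scaled) + 2)
  m$head$w <- matrix(withr::with_seed(1, rnorm(m$dims$head_in, sd = 0.1)))
  tab <- history_ablation(m, sc, max_history = 3)
  # all subjects have exactly 2 visits: only depth 1 is populated
  expect_equal(tab$n, c(12L, 0L, 0L))
  expect_true(is.na(tab$rmse[2]) && is.na(tab$rmse[3]))
  # depth 1 here IS the full history: equals the standard prediction set
  samples <- build_history_samples(sc)
  ps <- predict_samples(m, samples)
  expect_equal(tab$rmse[1], sqrt(mean((ps$y_pred - ps$y_true)^2)))
  expect_error(history_ablation(m, sc, 0), "argument error")
})

test_that("cross-validation is a disjoint subject partition with aggregates", {
  co <- simulate_cohort(sim_config(n_subjects = 15, n_genes = 6,
                                   n_signal_genes = 2, n_clinical = 4,
                                   seed = 33))
  mc <- model_config(cells_per_cb = 3, cbs_per_db = 1, n_dbs = 1, seed = 34)
  tc <- train_config(max_epochs = 2, early_stop_patience = 2, seed = 34)
  cv <- crossvalidate(co, mc, tc, n_folds = 5, seed = 35)
  expect_length(cv$folds, 5)
  expect_s3_class(cv$folds[[1]], "metric_report")
  pies <- vapply(cv$folds, function(r) r$pie, numeric(1))
  expect_equal(cv$summary$mean[cv$summary$metric == "PIE"], mean(pies))
  expect_equal(cv$summary$se[cv$summary$metric == "PIE"],
               sd(pies) / sqrt(5))
  asn <- cv$fold_assignment$assignment
  expect_equal(sort(unique(asn)), 1:5)
  expect_equal(anyDuplicated(names(asn)), 0)
})
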