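test_that("target assembly sums the four part scores within range", {
  expect_identical(assemble_target(c(10, 12, 30, 4)), 56L)
  expect_identical(assemble_target(c(0, 0, 0, 0)), 0L)
  expect_identical(assemble_target(c(0, 0, 272, 0)), 272L)
  expect_error(assemble_target(c(-1, 0, 0, 0)), "range error")
  expect_error(assemble_target(c(200, 200, 0, 0)), "range error")
  expect_error(assemble_target(c(1, 2, 3)), "range error")
})

test_that("write + load round-trips a simulated cohort", {
  co <- tiny_cohort(n_subjects = 8, seed = 9)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  back <- load_cohort(paths["expression"], paths["clinical"], paths["meta"])
  expect_equal(back$visits, co$visits)
  expect_equal(back$features, co$features, tolerance = 1e-12)
  expect_identical(back$gene_columns, co$gene_columns)
  expect_identical(back$clinical_columns, co$clinical_columns)
  expect_equal(back$column_kinds, co$column_kinds)
})

test_that("join drops unmatched visits with a logged count", {
  co <- tiny_cohort(n_subjects = 4, seed = 10)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expr <- read.csv(paths["expression"], check.names = FALSE)
  extra <- expr[1, ]
  extra$visit_id <- "V99"
  write.csv(rbind(expr, extra), paths["expression"], row.names = FALSE)
  expect_message(back <- load_cohort(paths["expression"], paths["clinical"]),
                 "dropped 1")
  expect_equal(nrow(back$visits), nrow(co$visits))
})

test_that("an empty clinical table gives an empty cohort with a warning", {
  co <- tiny_cohort(n_subjects = 3, seed = 11)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  clin <- read.csv(paths["clinical"], check.names = FALSE)
  write.csv(clin[0, ], paths["clinical"], row.names = FALSE)
  expect_warning(back <- load_cohort(paths["expression"], paths["clinical"]),
                 "empty")
  expect_equal(nrow(back$visits), 0)
})

test_that("malformed tables raise format/integrity errors", {
  co <- tiny_cohort(n_subjects = 3, seed = 12)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  clin <- read.csv(paths["clinical"], check.names = FALSE)
  # missing key column
  write.csv(clin[, setdiff(names(clin), "visit_id")],
            file.path(dir, "bad1.csv"), row.names = FALSE)
  expect_error(load_cohort(paths["expression"], file.path(dir, "bad1.csv")),
               "format error")
  # duplicated subject-visit row
  write.csv(rbind(clin, clin[1, ]), file.path(dir, "bad2.csv"),
            row.names = FALSE)
  expect_error(load_cohort(paths["expression"], file.path(dir, "bad2.csv")),
               "integrity error")
})

test_that("scaling transforms genes as log2(x+1) z-scores", {
  co <- manual_cohort()
  sc <- fit_scaling(co, c("A", "B", "C"))
  # gene_a over all six visits: log2(x + 1)
  lg <- log2(c(0, 3, 7, 1, 15, 2) + 1)
  expect_equal(unname(sc$center["gene_a"]), mean(lg))
  expect_equal(unname(sc$scale["gene_a"]), sd(lg))
  # constant gene column passes through with scale 1, scaled values 0
  expect_equal(unname(sc$scale["gene_b"]), 1)
  scaled <- scale_cohort(co, sc)
  expect_equal(unname(scaled$scaled[, "gene_b"]), rep(0, 6))
})

test_that("two-value gene column matches the hand-computed transform", {
  # values {0, 3}: log2 transform gives {0, 2}, mean 1, sd sqrt(2)
  lg <- log2(c(0, 3) + 1)
  expect_equal(lg, c(0, 2))
  expect_equal(mean(lg), 1)
  expect_equal(sd(lg), sqrt(2))
})

test_that("scaling fit on fold-train subjects leaks no test statistics", {
  co <- tiny_cohort(n_subjects = 10, seed = 13)
  ids <- cohort_subjects(co)
  train <- ids[1:7]
  full <- fit_scaling(co, train)
  # recompute from a cohort containing only the training subjects
  keep <- co$visits$subject_id %in% train
  sub <- new_cohort(co$visits[keep, ], co$features[keep, , drop = FALSE],
                    co$gene_columns, co$clinical_columns)
  only <- fit_scaling(sub, train)
  expect_equal(full$center, only$center)
  expect_equal(full$scale, only$scale)
  # idempotency
  again <- fit_scaling(co, train)
  expect_equal(full$center, again$center)
  expect_equal(full$scale, again$scale)
  expect_error(fit_scaling(co, c(train, "NOBODY")), "key error")
})

test_that("history windows enumerate every prefix with correct gaps", {
  co <- manual_cohort()
  sc <- scale_cohort(co, fit_scaling(co, c("A", "B", "C")))
  samples <- build_history_samples(sc)
  # A has 3 visits -> 2 samples, B has 2 -> 1, C has 1 -> 0
  expect_length(samples, 3)
  subj <- vapply(samples, function(s) s$subject_id, character(1))
  expect_equal(sum(subj == "A"), 2)
  expect_equal(sum(subj == "C"), 0)
  a <- samples[subj == "A"]
  lens <- vapply(a, function(s) s$n, numeric(1))
  s1 <- a[[which(lens == 1)]]
  s2 <- a[[which(lens == 2)]]
  # visits at months 0, 6, 12: dt sequences (0.5) and (0.5, 0.5) years
  expect_equal(s1$x_seq[, ncol(s1$x_seq) - 1], 0.5)
  expect_equal(s2$x_seq[, ncol(s2$x_seq) - 1], c(0.5, 0.5))
  # targets are the next visit's observed totals
  ord <- co$visits[co$visits$subject_id == "A", "score_total"]
  expect_equal(s1$target, ord[2])
  expect_equal(s2$target, ord[3])
  # past scores normalized by 272
  expect_equal(s2$x_seq[, ncol(s2$x_seq)], ord[1:2] / 272)
  # augmented dimension Q + 2
  expect_equal(ncol(s1$x_seq), ncol(co$features) + 2)
})

test_that("sample counts and dimensions follow the window rules", {
  co <- tiny_cohort(n_subjects = 15, seed = 14)
  sc <- scale_cohort(co, fit_scaling(co, cohort_subjects(co)))
  samples <- build_history_samples(sc)
  nv <- table(co$visits$subject_id)
  expect_length(samples, sum(pmax(nv - 1, 0)))
  # a 5-visit subject yields history lengths 1..4
  five <- names(nv)[nv == 5][1]
  if (!is.na(five)) {
    lens <- sort(vapply(samples[vapply(samples, function(s)
      s$subject_id == five, logical(1))], function(s) s$n, numeric(1)))
    expect_equal(lens, 1:4)
  }
  # RNA-only flag drops clinical columns
  rna <- build_history_samples(sc, include_nontranscriptomic = FALSE)
  expect_equal(ncol(rna[[1]]$x_seq), length(co$gene_columns) + 2)
  expect_error(build_history_samples(co), "state error")
})
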