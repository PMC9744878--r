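# Shared fixtures and independent oracles, built in code at test time.

# Small simulated cohort for pipeline tests.
tiny_cohort <- function(n_subjects = 20, n_genes = 10, seed = 42, ...) {
  simulate_cohort(sim_config(n_subjects = n_subjects, n_genes = n_genes,
                             n_clinical = 6, n_signal_genes = 3,
                             seed = seed, ...))
}

# Hand-built two-gene cohort where everything is known exactly.
manual_cohort <- function() {
  visits <- data.frame(
    subject_id = c("A", "A", "A", "B", "B", "C"),
    visit_id = c("V01", "V02", "V03", "V01", "V02", "V01"),
    visit_month = c(0, 6, 12, 0, 12, 0),
    updrs_p1 = c(2L, 3L, 4L, 1L, 2L, 5L),
    updrs_p2 = c(3L, 4L, 5L, 2L, 3L, 5L),
    updrs_p3 = c(10L, 12L, 14L, 8L, 11L, 20L),
    updrs_p4 = c(1L, 1L, 2L, 0L, 1L, 2L),
    stringsAsFactors = FALSE)
  visits$score_total <- as.integer(rowSums(visits[paste0("updrs_p", 1:4)]))
  feats <- cbind(gene_a = c(0, 3, 7, 1, 15, 2),
                 gene_b = c(5, 5, 5, 5, 5, 5),
                 clin_x = c(0.1, 0.5, -0.3, 1.2, 0.7, -1))
  new_cohort(visits, feats, c("gene_a", "gene_b"), "clin_x")
}

rand_steps <- function(B, T_len, p) {
  lapply(seq_len(T_len), function(t) matrix(stats::rnorm(B * p), B, p))
}

# Independent loop-unrolled vanilla recurrence: one sequence at a time,
# explicit per-step updates; the oracle the batched path must reproduce.
unrolled_vanilla <- function(x_list, W, U, b) {
  B <- nrow(x_list[[1]])
  C <- ncol(W)
  out <- vector("list", length(x_list))
  for (bi in seq_len(B)) {
    h <- rep(0, C)
    for (t in seq_along(x_list)) {
      h <- tanh(as.numeric(x_list[[t]][bi, ] %*% W) + as.numeric(h %*% U) + b)
      if (is.null(out[[t]])) out[[t]] <- matrix(0, B, C)
      out[[t]][bi, ] <- h
    }
  }
  out
}

# Build a list of hand-made history samples with given targets: x random,
# shared input dimension p.
manual_samples <- function(targets, lengths, p = 4, seed = 1) {
  withr::with_seed(seed, lapply(seq_along(targets), function(i) {
    structure(list(
      subject_id = sprintf("S%03d", i),
      x_seq = matrix(stats::rnorm(lengths[i] * p), lengths[i], p),
      n = lengths[i],
      target = targets[i],
      target_visit_index = lengths[i] + 1,
      target_month = 12 * lengths[i],
      last_score = targets[i]
    ), class = "prog_sample")
  }))
}

# Train-mode forward once to populate batch-norm running statistics.
warm_bn <- function(model, p, T_len = 2, B = 4, seed = 99) {
  withr::with_seed(seed, {
    x <- rand_steps(B, T_len, p)
    model_forward(x, model, "train")$model
  })
}
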