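#' Training configuration
#'
#' Defaults follow the reference recipe: mini-batches of 16 same-length
#' histories, mean-squared-error loss, Nadam, and a plateau schedule that
#' multiplies the learning rate by 1/5 after every 10 epochs without
#' validation improvement.
#'
#' @param batch_size sequences per mini-batch.
#' @param max_epochs maximum training epochs.
#' @param initial_lr starting learning rate.
#' @param lr_factor multiplicative learning-rate decay (in (0,1)).
#' @param lr_patience epochs without improvement per decay step.
#' @param l2_coeff optional override of the model config's L2 coefficient.
#' @param early_stop_patience epochs without validation improvement before
#'   training stops.
#' @param val_fraction fraction of training *subjects* held out for
#'   validation (subject-level, so no leakage across a subject's windows).
#' @param seed seed controlling the validation split and batch shuffling.
#' @return object of class `train_config`.
#' @export
train_config <- function(batch_size = 16, max_epochs = 200,
                         initial_lr = 1e-3, lr_factor = 0.2,
                         lr_patience = 10, l2_coeff = NULL,
                         early_stop_patience = 30, val_fraction = 0.1,
                         seed = 1) {
  cfg <- list(
    batch_size = check_count(batch_size, "batch_size"),
    max_epochs = check_count(max_epochs, "max_epochs"),
    initial_lr = check_number(initial_lr, "initial_lr", 1e-12),
    lr_factor = check_number(lr_factor, "lr_factor", 1e-12, 1 - 1e-12),
    lr_patience = check_count(lr_patience, "lr_patience"),
    l2_coeff = if (!is.null(l2_coeff)) check_number(l2_coeff, "l2_coeff", 0),
    early_stop_patience = check_count(early_stop_patience,
                                      "early_stop_patience"),
    val_fraction = check_number(val_fraction, "val_fraction", 1e-12,
                                1 - 1e-12),
    seed = check_count(seed, "seed", min = 0L)
  )
  structure(cfg, class = "train_config")
}

#' Group samples into same-length mini-batches
#'
#' Histories are grouped by length so every mini-batch contains sequences of
#' identical visit counts; within a group samples are shuffled and chunked,
#' and the batch order itself is shuffled.  Every sample appears in exactly
#' one batch.
#'
#' @param samples list of `prog_sample` objects.
#' @param batch_size maximum batch size.
#' @param seed optional seed for the shuffle (reshuffled per epoch by
#'   [train_model()] via per-epoch derived seeds).
#' @return list of integer index vectors into `samples`.
#' @export
make_length_batches <- function(samples, batch_size, seed = NULL) {
  if (length(samples) == 0) stop("empty-input error: no samples to batch")
  build <- function() {
    lens <- vapply(samples, function(s) s$n, numeric(1))
    batches <- list()
    for (grp in split(seq_along(samples), lens)) {
      grp <- grp[sample.int(length(grp))]
      idx <- split(grp, ceiling(seq_along(grp) / batch_size))
      batches <- c(batches, unname(idx))
    }
    batches[sample.int(length(batches))]
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Plateau learning-rate step
#'
#' Multiplies the learning rate by `factor` whenever the number of epochs
#' since the last validation improvement reaches a positive multiple of
#' `patience` (default: 1/5 every 10 stale epochs).
#'
#' @param current_lr positive learning rate.
#' @param epochs_since_improvement non-negative integer counter.
#' @param factor,patience schedule parameters.
#' @return the (possibly reduced) learning rate.
#' @export
lr_step <- function(current_lr, epochs_since_improvement,
                    factor = 0.2, patience = 10) {
  if (current_lr <= 0) stop("argument error: current_lr must be positive")
  e <- epochs_since_improvement
  if (!is.numeric(e) || length(e) != 1 || e < 0 || e != round(e))
    stop("argument error: epochs_since_improvement must be a non-negative integer")
  if (e > 0 && e %% patience == 0) current_lr * factor else current_lr
}

# Stack same-length samples into the per-step list form plus targets.
assemble_batch <- function(samples) {
  T_len <- samples[[1]]$n
  p <- ncol(samples[[1]]$x_seq)
  x_list <- lapply(seq_len(T_len), function(t)
    do.call(rbind, lapply(samples, function(s) s$x_seq[t, , drop = FALSE])))
  list(x = x_list,
       y = vapply(samples, function(s) s$target, numeric(1)) / SCORE_MAX)
}

batch_mse <- function(model, samples, batch_size = 64) {
  lens <- vapply(samples, function(s) s$n, numeric(1))
  se <- 0; n <- 0
  for (grp in split(seq_along(samples), lens)) {
    for (idx in split(grp, ceiling(seq_along(grp) / batch_size))) {
      b <- assemble_batch(samples[idx])
      pred <- model_forward(b$x, model, "infer")$pred
      se <- se + sum((pred - b$y)^2)
      n <- n + length(idx)
    }
  }
  se / n
}

l2_penalty <- function(model, lambda) {
  if (lambda == 0) return(0)
  s <- 0
  for (db in model$dbs) for (cb in db$cbs)
    s <- s + sum(cb$cell$W^2) + sum(cb$cell$U^2)
  lambda * s
}

#' Train the dense recurrent model
#'
#' Minimizes mean squared error between the predicted and observed
#' next-visit scores (on the 0--1 normalized scale) plus an L2 penalty on
#' the recurrent layers' input and recurrent weight matrices, using Nadam
#' over same-length mini-batches.  A subject-level validation split drives
#' the plateau learning-rate schedule, early stopping and best-checkpoint
#' selection: the returned model is the parameter state with the lowest
#' validation loss seen.
#'
#' @param model a freshly initialized (or warm) `prog_model`.
#' @param samples list of `prog_sample` training windows.
#' @param train_cfg a [train_config()].
#' @param quiet suppress per-epoch messages.
#' @return list with `model` (best-validation states), `history`
#'   (data.frame: epoch, train_loss, val_loss, lr) and `best_epoch`.
#' @export
train_model <- function(model, samples, train_cfg = train_config(),
                        quiet = TRUE) {
  stopifnot(inherits(model, "prog_model"), inherits(train_cfg, "train_config"))
  if (length(samples) == 0) stop("empty-input error: no training samples")
  lambda <- train_cfg$l2_coeff %||% model$config$l2_coeff

  # subject-level validation split, stratified by the subject's maximum
  # history length so every length group is represented in validation
  subj <- vapply(samples, function(s) s$subject_id, character(1))
  max_len <- tapply(vapply(samples, function(s) s$n, numeric(1)), subj, max)
  val_ids <- withr::with_seed(train_cfg$seed, {
    unlist(lapply(split(names(max_len), max_len), function(ids) {
      n_val <- max(1L, round(train_cfg$val_fraction * length(ids)))
      if (length(ids) <= 1) character(0) else sample(ids, n_val)
    }), use.names = FALSE)
  })
  val_samples <- samples[subj %in% val_ids]
  tr_samples <- samples[!(subj %in% val_ids)]
  if (length(tr_samples) == 0 || length(val_samples) == 0) {
    tr_samples <- samples
    val_samples <- samples
  }

  params <- get_params(model)
  opt <- nadam_init(params)
  lr <- train_cfg$initial_lr
  best_val <- Inf; best_model <- model; best_epoch <- 0L
  since_improve <- 0L
  history <- vector("list", train_cfg$max_epochs)

  for (epoch in seq_len(train_cfg$max_epochs)) {
    batches <- make_length_batches(tr_samples, train_cfg$batch_size,
                                   seed = derive_seed(train_cfg$seed, epoch))
    ep_loss <- 0; ep_n <- 0
    for (idx in batches) {
      b <- assemble_batch(tr_samples[idx])
      fw <- model_forward(b$x, model, "train", keep_cache = TRUE)
      model <- fw$model  # running statistics advanced
      resid <- fw$pred - b$y
      mse <- mean(resid^2)
      loss <- mse + l2_penalty(model, lambda)
      if (!is.finite(loss))
        stop("divergence: non-finite training loss at epoch ", epoch)
      grads <- model_backward(model, fw$cache, 2 * resid / length(resid))
      glist <- grads_to_params(model, grads)
      if (lambda > 0) {
        for (k in grep("\\.(W|U)$", names(glist), value = TRUE))
          glist[[k]] <- glist[[k]] + 2 * lambda * params[[k]]
      }
      upd <- nadam_update(params, glist, opt, lr)
      params <- upd$params
      opt <- upd$state
      model <- set_params(model, params)
      ep_loss <- ep_loss + mse * length(idx)
      ep_n <- ep_n + length(idx)
    }
    train_loss <- ep_loss / ep_n
    val_loss <- batch_mse(model, val_samples)
    if (!is.finite(val_loss))
      stop("divergence: non-finite validation loss at epoch ", epoch)
    history[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                   val_loss = val_loss, lr = lr)
    if (!quiet)
      message(sprintf("epoch %3d  train %.5f  val %.5f  lr %.2e",
                      epoch, train_loss, val_loss, lr))
    if (val_loss < best_val - 1e-12) {
      best_val <- val_loss
      best_model <- model
      best_epoch <- epoch
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
    }
    lr <- lr_step(lr, since_improve, train_cfg$lr_factor,
                  train_cfg$lr_patience)
    if (since_improve >= train_cfg$early_stop_patience) break
  }

  list(model = best_model,
       history = do.call(rbind, history[!vapply(history, is.null, logical(1))]),
       best_epoch = best_epoch, best_val_loss = best_val)
}

#' Predict next-visit scores for a set of history windows
#'
#' Runs the model in inference mode (frozen normalization statistics, so
#' results are independent of batch composition) and returns one record per
#' window on the original 0--272 score scale.
#'
#' @param model a trained `prog_model`.
#' @param samples list of `prog_sample` windows.
#' @return a prediction-set data.frame: `subject_id`, `target_visit_index`,
#'   `history_length`, `y_true`, `y_pred`.
#' @export
predict_samples <- function(model, samples) {
  if (length(samples) == 0) stop("empty-input error: no samples to predict")
  preds <- numeric(length(samples))
  lens <- vapply(samples, function(s) s$n, numeric(1))
  for (grp in split(seq_along(samples), lens)) {
    for (idx in split(grp, ceiling(seq_along(grp) / 64))) {
      b <- assemble_batch(samples[idx])
      preds[idx] <- model_forward(b$x, model, "infer")$pred * SCORE_MAX
    }
  }
  data.frame(
    subject_id = vapply(samples, function(s) s$subject_id, character(1)),
    target_visit_index = vapply(samples, function(s) s$target_visit_index,
                                numeric(1)),
    history_length = lens,
    y_true = vapply(samples, function(s) s$target, numeric(1)),
    y_pred = preds,
    stringsAsFactors = FALSE
  )
}

#' Carry-forward-last-score baseline predictions
#'
#' Predicts every next-visit score as the last observed score in the window
#' (the natural "no-progression" reference for an upward-trending target).
#'
#' @param samples list of `prog_sample` windows.
#' @return a prediction-set data.frame (same shape as [predict_samples()]).
#' @export
carry_forward_predictions <- function(samples) {
  if (length(samples) == 0) stop("empty-input error: no samples")
  data.frame(
    subject_id = vapply(samples, function(s) s$subject_id, character(1)),
    target_visit_index = vapply(samples, function(s) s$target_visit_index,
                                numeric(1)),
    history_length = vapply(samples, function(s) s$n, numeric(1)),
    y_true = vapply(samples, function(s) s$target, numeric(1)),
    y_pred = vapply(samples, function(s) s$last_score, numeric(1)),
    stringsAsFactors = FALSE
  )
}
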