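#' Architecture configuration
#'
#' Defaults follow the reference recipe: 256 vanilla RNN cells per composite
#' block (CB), 4 CBs per dense block (DB), 3 DBs, dense connections and batch
#' normalization on.  A CB is a recurrent layer followed by batch
#' normalization of its output activations; a DB concatenates (along the
#' feature axis, per time step) its input with every earlier CB output as
#' the input to each CB, and DBs are themselves densely connected with the
#' same concatenation rule.  The final DB's last-time-step output feeds a
#' single affine neuron (no activation).
#'
#' @param cell_type `"vanilla"` (tanh), `"gru"` or `"lstm"`.
#' @param cells_per_cb hidden width C of each recurrent layer.
#' @param cbs_per_db number of composite blocks K per dense block.
#' @param n_dbs number of dense blocks D.
#' @param dense_connections concatenation links on/off (off = plain chain).
#' @param batch_norm batch normalization inside each CB on/off.
#' @param l2_coeff L2 penalty applied to the recurrent layers' input and
#'   recurrent weight matrices (not biases, not BN parameters, not the head).
#' @param bn_epsilon variance-stabilizing constant of the normalizer.
#' @param bn_momentum running-statistics update rate.
#' @param seed initialization seed (same seed, same weights).
#' @return object of class `model_config`.
#' @export
model_config <- function(cell_type = c("vanilla", "gru", "lstm"),
                         cells_per_cb = 256, cbs_per_db = 4, n_dbs = 3,
                         dense_connections = TRUE, batch_norm = TRUE,
                         l2_coeff = 1e-4, bn_epsilon = 1e-3,
                         bn_momentum = 0.1, seed = 1) {
  cfg <- list(
    cell_type = match.arg(cell_type),
    cells_per_cb = check_count(cells_per_cb, "cells_per_cb"),
    cbs_per_db = check_count(cbs_per_db, "cbs_per_db"),
    n_dbs = check_count(n_dbs, "n_dbs"),
    dense_connections = isTRUE(dense_connections),
    batch_norm = isTRUE(batch_norm),
    l2_coeff = check_number(l2_coeff, "l2_coeff", 0),
    bn_epsilon = check_number(bn_epsilon, "bn_epsilon", 1e-12),
    bn_momentum = check_number(bn_momentum, "bn_momentum", 0, 1),
    seed = check_count(seed, "seed", min = 0L)
  )
  structure(cfg, class = "model_config")
}

# Input/output dimension bookkeeping implied by the concatenation rule.
model_dims <- function(config, input_dim) {
  C <- config$cells_per_cb; K <- config$cbs_per_db; D <- config$n_dbs
  dense <- config$dense_connections
  db_in <- integer(D); db_out <- integer(D)
  cb_in <- matrix(0L, D, K)
  prev_outs <- integer(0)
  for (d in seq_len(D)) {
    db_in[d] <- if (dense) input_dim + sum(prev_outs)
                else if (d == 1) input_dim else db_out[d - 1]
    for (j in seq_len(K)) {
      cb_in[d, j] <- if (dense) db_in[d] + (j - 1L) * C
                     else if (j == 1) db_in[d] else C
    }
    db_out[d] <- if (dense) db_in[d] + K * C else C
    prev_outs <- c(prev_outs, db_out[d])
  }
  list(db_in = db_in, db_out = db_out, cb_in = cb_in,
       head_in = db_out[D])
}

init_composite_block <- function(input_dim, config) {
  list(cell = init_cell(input_dim, config$cells_per_cb, config$cell_type),
       bn = if (config$batch_norm)
         init_bn(config$cells_per_cb, config$bn_epsilon, config$bn_momentum))
}

#' Instantiate model weights and normalization state
#'
#' @param config a [model_config()].
#' @param input_dim length of each time step's input vector (for history
#'   windows this is Q + 2: scaled features, time gap, past score).
#' @return object of class `prog_model`.
#' @export
init_model <- function(config, input_dim) {
  stopifnot(inherits(config, "model_config"))
  input_dim <- check_count(input_dim, "input_dim")
  dims <- model_dims(config, input_dim)
  withr::with_seed(config$seed, {
    dbs <- lapply(seq_len(config$n_dbs), function(d) {
      list(cbs = lapply(seq_len(config$cbs_per_db), function(j)
        init_composite_block(dims$cb_in[d, j], config)))
    })
    # regression head starts at zero so early training calibrates the
    # output scale to the target instead of fighting O(1) activations
    head <- list(w = matrix(0, dims$head_in, 1), b = 0)
    structure(list(config = config, input_dim = input_dim, dims = dims,
                   dbs = dbs, head = head, target_scale = SCORE_MAX),
              class = "prog_model")
  })
}

#' @export
print.prog_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "prog_model: %s cells, C=%d, K=%d CBs/DB, D=%d DBs, dense=%s, BN=%s\n",
    cfg$cell_type, cfg$cells_per_cb, cfg$cbs_per_db, cfg$n_dbs,
    cfg$dense_connections, cfg$batch_norm))
  cat(sprintf("  input dim %d, head input %d, %d parameters\n",
              x$input_dim, x$dims$head_in,
              count_parameters(cfg, x$input_dim)))
  invisible(x)
}

# Canonicalize sequence input: a T x p matrix is one sequence; a B x T x p
# array is a batch; a list of B x p matrices is the internal form.
as_step_list <- function(x) {
  if (is.list(x)) return(x)
  if (is.matrix(x))
    return(lapply(seq_len(nrow(x)), function(t) x[t, , drop = FALSE]))
  if (is.array(x) && length(dim(x)) == 3)
    return(lapply(seq_len(dim(x)[2]), function(t)
      matrix(x[, t, ], dim(x)[1], dim(x)[3])))
  stop("shape error: sequences must be a T x p matrix, B x T x p array, ",
       "or list of per-step B x p matrices")
}

check_batch <- function(x_list) {
  dims <- vapply(x_list, dim, integer(2))
  if (length(unique(dims[1, ])) != 1 || length(unique(dims[2, ])) != 1)
    stop("shape error: ragged batch; all steps must share batch size and ",
         "input dimension")
  invisible(x_list)
}

#' Composite block forward pass
#'
#' Runs the recurrent layer over the sequence batch, then batch-normalizes
#' the output activations at every time step (statistics from the current
#' mini-batch in train mode, from running estimates in infer mode).  The
#' full output sequence is returned, as required for stacking.
#'
#' @param x_seq batch of same-length sequences (see [model_forward()]).
#' @param state a composite-block state (element of `model$dbs[[d]]$cbs`).
#' @param mode `"train"` or `"infer"`.
#' @return list with `h` (per-step list of B x C matrices), the updated
#'   `state` (running statistics advance in train mode) and a `cache` for
#'   the backward pass.
#' @export
composite_block_forward <- function(x_seq, state, mode = c("train", "infer")) {
  mode <- match.arg(mode)
  x_list <- check_batch(as_step_list(x_seq))
  if (ncol(x_list[[1]]) != nrow(state$cell$W))
    stop("shape error: input dimension ", ncol(x_list[[1]]),
         " does not match cell input dimension ", nrow(state$cell$W))
  fw <- cell_forward(x_list, state$cell)
  if (is.null(state$bn))
    return(list(h = fw$h, state = state,
                cache = list(cell = fw$cache, bn = NULL)))
  bnf <- bn_forward(fw$h, state$bn, mode)
  state$bn <- bnf$bn
  list(h = bnf$out, state = state,
       cache = list(cell = fw$cache, bn = bnf$cache))
}

composite_block_backward <- function(dH_list, cache, state) {
  grads <- list()
  if (!is.null(cache$bn)) {
    bnb <- bn_backward(dH_list, cache$bn, state$bn)
    dH_list <- bnb$dh
    grads$bn <- list(gamma = bnb$dgamma, beta = bnb$dbeta)
  }
  cb <- cell_backward(dH_list, cache$cell, state$cell)
  grads$cell <- list(W = cb$dW, U = cb$dU, b = cb$db)
  list(dx = cb$dx, grads = grads)
}

#' Dense block forward pass
#'
#' With dense connections, composite block `j` receives the per-time-step
#' concatenation of the block input with all earlier CB outputs, and the
#' block returns `concat(input, H1, ..., HK)`; without, the CBs are chained
#' and the block returns the last CB's output.
#'
#' @param x_seq batch of same-length sequences.
#' @param block_states list of K composite-block states.
#' @param dense logical, concatenation links on/off.
#' @param mode `"train"` or `"infer"`.
#' @return list with `out` (per-step list), updated `block_states`, `cache`.
#' @export
dense_block_forward <- function(x_seq, block_states, dense = TRUE,
                                mode = c("train", "infer")) {
  mode <- match.arg(mode)
  x_list <- check_batch(as_step_list(x_seq))
  K <- length(block_states)
  cur <- x_list
  caches <- vector("list", K)
  for (j in seq_len(K)) {
    expect <- nrow(block_states[[j]]$cell$W)
    if (ncol(cur[[1]]) != expect)
      stop("shape error: composite block ", j, " expects input dimension ",
           expect, " but received ", ncol(cur[[1]]))
    cbf <- composite_block_forward(cur, block_states[[j]], mode)
    block_states[[j]] <- cbf$state
    caches[[j]] <- cbf$cache
    # dense: the running concat already carries x and earlier outputs
    cur <- if (dense) Map(cbind, cur, cbf$h) else cbf$h
  }
  list(out = cur, block_states = block_states,
       cache = list(cbs = caches, dense = dense,
                    input_dim = ncol(x_list[[1]]),
                    C = ncol(caches[[1]]$cell$h[[1]])))
}

dense_block_backward <- function(dout_list, cache, block_states) {
  K <- length(block_states)
  p <- cache$input_dim
  C <- cache$C
  grads <- vector("list", K)
  if (cache$dense) {
    # output = concat(x, H1..HK); accumulate slice gradients
    din <- lapply(dout_list, function(d) d[, seq_len(p), drop = FALSE])
    dH <- lapply(seq_len(K), function(j)
      lapply(dout_list, function(d)
        d[, p + (j - 1L) * C + seq_len(C), drop = FALSE]))
    for (j in rev(seq_len(K))) {
      cbb <- composite_block_backward(dH[[j]], cache$cbs[[j]],
                                      block_states[[j]])
      grads[[j]] <- cbb$grads
      # CB j consumed concat(x, H1..H_{j-1}): route input gradient back
      din <- Map(function(a, b) a + b[, seq_len(p), drop = FALSE],
                 din, cbb$dx)
      if (j > 1) {
        for (k in seq_len(j - 1)) {
          dH[[k]] <- Map(function(a, b)
            a + b[, p + (k - 1L) * C + seq_len(C), drop = FALSE],
            dH[[k]], cbb$dx)
        }
      }
    }
  } else {
    cur <- dout_list
    for (j in rev(seq_len(K))) {
      cbb <- composite_block_backward(cur, cache$cbs[[j]], block_states[[j]])
      grads[[j]] <- cbb$grads
      cur <- cbb$dx
    }
    din <- cur
  }
  list(dx = din, grads = grads)
}

#' Full model forward pass
#'
#' Dense blocks are stacked with the same concatenation rule as within a
#' block; the final block's output at the last time step passes through a
#' single affine neuron, yielding one real-valued score per sequence (on the
#' normalized 0--1 scale used in training).
#'
#' @param x_seq_batch a T x p matrix (one sequence), a B x T x p array, or a
#'   list over time steps of B x p matrices.
#' @param model a `prog_model`.
#' @param mode `"train"` (mini-batch normalization statistics, running
#'   estimates advance) or `"infer"` (frozen statistics).
#' @param keep_cache retain intermediate activations for the backward pass.
#' @return list with `pred` (numeric, one per sequence), the updated `model`
#'   and (if requested) `cache`.
#' @export
model_forward <- function(x_seq_batch, model, mode = c("train", "infer"),
                          keep_cache = FALSE) {
  mode <- match.arg(mode)
  x_list <- check_batch(as_step_list(x_seq_batch))
  if (ncol(x_list[[1]]) != model$input_dim)
    stop("shape error: input dimension ", ncol(x_list[[1]]),
         " does not match model input dimension ", model$input_dim)
  cfg <- model$config
  D <- cfg$n_dbs
  dense <- cfg$dense_connections
  cur_in <- x_list         # model-level running concat when dense
  db_out <- vector("list", D)
  db_caches <- vector("list", D)
  db_in_dims <- integer(D)
  for (d in seq_len(D)) {
    db_in_dims[d] <- ncol(cur_in[[1]])
    dbf <- dense_block_forward(cur_in, model$dbs[[d]]$cbs, dense, mode)
    model$dbs[[d]]$cbs <- dbf$block_states
    db_caches[[d]] <- dbf$cache
    db_out[[d]] <- dbf$out
    if (any(!vapply(dbf$out, function(m) all(is.finite(m)), logical(1))))
      stop("numeric error: non-finite activations in dense block ", d)
    cur_in <- if (dense) Map(cbind, cur_in, dbf$out) else dbf$out
  }
  final <- db_out[[D]]
  last <- final[[length(final)]]
  pred <- as.numeric(last %*% model$head$w + model$head$b)
  out <- list(pred = pred, model = model)
  if (keep_cache)
    out$cache <- list(x = x_list, dbs = db_caches, db_out_dim =
                        vapply(db_out, function(o) ncol(o[[1]]), integer(1)),
                      db_in_dims = db_in_dims, last = last,
                      T_len = length(x_list), B = nrow(last))
  out
}

# Reverse-mode pass for the whole architecture.  dpred: gradient of the loss
# wrt each sequence's prediction.  Returns gradients congruent with the
# trainable parameters.
model_backward <- function(model, cache, dpred) {
  cfg <- model$config
  D <- cfg$n_dbs
  dense <- cfg$dense_connections
  B <- cache$B; T_len <- cache$T_len
  dpred <- matrix(dpred, ncol = 1)

  head_grads <- list(w = crossprod(cache$last, dpred),
                     b = sum(dpred))
  dlast <- dpred %*% t(model$head$w)

  # gradient wrt each DB's output sequence
  zero_seq <- function(width) lapply(seq_len(T_len), function(t)
    matrix(0, B, width))
  dO <- lapply(seq_len(D), function(d) zero_seq(cache$db_out_dim[d]))
  dO[[D]][[T_len]] <- dO[[D]][[T_len]] + dlast

  dx_model <- zero_seq(model$input_dim)
  db_grads <- vector("list", D)
  for (d in rev(seq_len(D))) {
    dbb <- dense_block_backward(dO[[d]], cache$dbs[[d]], model$dbs[[d]]$cbs)
    db_grads[[d]] <- dbb$grads
    din <- dbb$dx  # gradient wrt DB d's (possibly concatenated) input
    if (dense) {
      # DB d input = concat(model_x, O1, ..., O_{d-1})
      p0 <- model$input_dim
      dx_model <- Map(function(a, b) a + b[, seq_len(p0), drop = FALSE],
                      dx_model, din)
      off <- p0
      if (d > 1) {
        for (k in seq_len(d - 1)) {
          w <- cache$db_out_dim[k]
          dO[[k]] <- Map(function(a, b)
            a + b[, off + seq_len(w), drop = FALSE], dO[[k]], din)
          off <- off + w
        }
      }
    } else {
      if (d > 1) dO[[d - 1]] <- Map(`+`, dO[[d - 1]], din)
      else dx_model <- Map(`+`, dx_model, din)
    }
  }
  list(dbs = db_grads, head = head_grads, dx = dx_model)
}

#' Closed-form trainable-parameter count
#'
#' Counts weights, biases and batch-normalization scale/shift parameters
#' implied by the concatenation dimension rules, without instantiating the
#' model.  Matches introspection of [init_model()] exactly.
#'
#' @param config a [model_config()].
#' @param input_dim input vector length per time step.
#' @return integer parameter count.
#' @export
count_parameters <- function(config, input_dim) {
  stopifnot(inherits(config, "model_config"))
  dims <- model_dims(config, input_dim)
  C <- config$cells_per_cb
  g <- n_gates(config$cell_type)
  total <- 0
  for (d in seq_len(config$n_dbs)) {
    for (j in seq_len(config$cbs_per_db)) {
      p <- dims$cb_in[d, j]
      total <- total + p * g * C + C * g * C + g * C
      if (config$batch_norm) total <- total + 2 * C
    }
  }
  total + dims$head_in + 1
}
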