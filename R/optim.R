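# Trainable-parameter bookkeeping (flat named list of arrays, in a fixed
# traversal order) and the Nadam update rule (Adam with Nesterov momentum).

get_params <- function(model) {
  out <- list()
  for (d in seq_along(model$dbs)) {
    for (j in seq_along(model$dbs[[d]]$cbs)) {
      cb <- model$dbs[[d]]$cbs[[j]]
      key <- sprintf("db%d.cb%d", d, j)
      out[[paste0(key, ".W")]] <- cb$cell$W
      out[[paste0(key, ".U")]] <- cb$cell$U
      out[[paste0(key, ".b")]] <- cb$cell$b
      if (!is.null(cb$bn)) {
        out[[paste0(key, ".gamma")]] <- cb$bn$gamma
        out[[paste0(key, ".beta")]] <- cb$bn$beta
      }
    }
  }
  out[["head.w"]] <- model$head$w
  out[["head.b"]] <- model$head$b
  out
}

set_params <- function(model, params) {
  for (d in seq_along(model$dbs)) {
    for (j in seq_along(model$dbs[[d]]$cbs)) {
      key <- sprintf("db%d.cb%d", d, j)
      model$dbs[[d]]$cbs[[j]]$cell$W <- params[[paste0(key, ".W")]]
      model$dbs[[d]]$cbs[[j]]$cell$U <- params[[paste0(key, ".U")]]
      model$dbs[[d]]$cbs[[j]]$cell$b <- params[[paste0(key, ".b")]]
      if (!is.null(model$dbs[[d]]$cbs[[j]]$bn)) {
        model$dbs[[d]]$cbs[[j]]$bn$gamma <- params[[paste0(key, ".gamma")]]
        model$dbs[[d]]$cbs[[j]]$bn$beta <- params[[paste0(key, ".beta")]]
      }
    }
  }
  model$head$w <- params[["head.w"]]
  model$head$b <- params[["head.b"]]
  model
}

grads_to_params <- function(model, grads) {
  out <- list()
  for (d in seq_along(model$dbs)) {
    for (j in seq_along(model$dbs[[d]]$cbs)) {
      g <- grads$dbs[[d]][[j]]
      key <- sprintf("db%d.cb%d", d, j)
      out[[paste0(key, ".W")]] <- g$cell$W
      out[[paste0(key, ".U")]] <- g$cell$U
      out[[paste0(key, ".b")]] <- g$cell$b
      if (!is.null(g$bn)) {
        out[[paste0(key, ".gamma")]] <- g$bn$gamma
        out[[paste0(key, ".beta")]] <- g$bn$beta
      }
    }
  }
  out[["head.w"]] <- grads$head$w
  out[["head.b"]] <- grads$head$b
  out
}

nadam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

nadam_update <- function(params, grads, state, lr,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    m_hat <- state$m[[k]] / bc1
    v_hat <- state$v[[k]] / bc2
    step <- lr * (beta1 * m_hat + (1 - beta1) * g / bc1) /
      (sqrt(v_hat) + eps)
    params[[k]] <- params[[k]] - step
  }
  list(params = params, state = state)
}
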