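# Batch normalization of recurrent output activations.  Gamma/beta are
# shared across time steps; one running-statistics accumulator per composite
# block pools over all (batch x time-step) rows.  Train mode normalizes with
# the current mini-batch's pooled mean/variance (biased); infer mode uses
# the frozen running estimates, so predictions are independent of batch
# composition.

init_bn <- function(C, epsilon = 1e-3, momentum = 0.1) {
  list(gamma = rep(1, C), beta = rep(0, C),
       run_mean = rep(0, C), run_var = rep(1, C),
       epsilon = epsilon, momentum = momentum,
       n_updates = 0L, initialized = FALSE)
}

bn_forward <- function(h_list, bn, mode) {
  B <- nrow(h_list[[1]])
  if (mode == "train") {
    H <- do.call(rbind, h_list)
    N <- nrow(H)
    mu <- colMeans(H)
    v <- colMeans(sweep(H, 2, mu)^2)  # biased, as in the normalizer
    inv <- 1 / sqrt(v + bn$epsilon)
    m <- bn$momentum
    bn$run_mean <- (1 - m) * bn$run_mean + m * mu
    bn$run_var <- (1 - m) * bn$run_var + m * v
    bn$n_updates <- bn$n_updates + 1L
    bn$initialized <- TRUE
  } else {
    if (!isTRUE(bn$initialized))
      stop("uninitialized-statistics error: batch normalization has no ",
           "running estimates; run at least one train-mode forward pass")
    mu <- bn$run_mean
    inv <- 1 / sqrt(bn$run_var + bn$epsilon)
    N <- NA_integer_
  }
  xhat_list <- lapply(h_list, function(h)
    sweep(sweep(h, 2, mu), 2, inv, "*"))
  out <- lapply(xhat_list, function(xh)
    add_bias(xh * rep(bn$gamma, each = B), bn$beta))
  list(out = out, bn = bn,
       cache = list(xhat = xhat_list, inv = inv, N = N, B = B))
}

# Gradient through train-mode normalization, including the dependence of the
# pooled mean/variance on every row.
bn_backward <- function(dout_list, cache, bn) {
  B <- cache$B
  gamma_row <- rep(bn$gamma, each = B)
  dxhat_list <- lapply(dout_list, function(d) d * gamma_row)
  dgamma <- Reduce(`+`, Map(function(d, xh) colSums(d * xh),
                            dout_list, cache$xhat))
  dbeta <- Reduce(`+`, lapply(dout_list, colSums))
  s1 <- Reduce(`+`, lapply(dxhat_list, colSums))
  s2 <- Reduce(`+`, Map(function(dxh, xh) colSums(dxh * xh),
                        dxhat_list, cache$xhat))
  N <- cache$N
  dh_list <- Map(function(dxh, xh) {
    sweep(N * dxh - rep(s1, each = B) - xh * rep(s2, each = B),
          2, cache$inv / N, "*")
  }, dxhat_list, cache$xhat)
  list(dh = dh_list, dgamma = dgamma, dbeta = dbeta)
}
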