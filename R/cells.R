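# Recurrent cells (vanilla / GRU / LSTM): forward pass over a same-length
# mini-batch and exact reverse-mode gradients (BPTT).  Sequences are lists
# over time steps of B x p matrices; hidden states are B x C.
#
# Parameter layout per cell: W (p x gC), U (C x gC), b (gC) with g gate
# blocks in column order — GRU: (z, r, n); LSTM: (i, f, g, o).

sigmoid <- function(x) 1 / (1 + exp(-x))

add_bias <- function(m, b) m + rep(b, each = nrow(m))

n_gates <- function(cell_type) {
  switch(cell_type, vanilla = 1L, gru = 3L, lstm = 4L,
         stop_config("cell_type", "must be one of vanilla, gru, lstm"))
}

# column indices of gate block k
gate_cols <- function(k, C) ((k - 1L) * C + 1L):(k * C)

# Orthogonal matrix via QR of a Gaussian, sign-fixed for a unique
# decomposition; standard recurrent-weight initialization.
orthogonal_init <- function(n) {
  qrd <- qr(matrix(stats::rnorm(n * n), n, n))
  q <- qr.Q(qrd)
  q * rep(sign(diag(qr.R(qrd))), each = n)
}

init_cell <- function(input_dim, C, cell_type) {
  g <- n_gates(cell_type)
  lim <- sqrt(6 / (input_dim + C))
  W <- matrix(stats::runif(input_dim * g * C, -lim, lim), input_dim, g * C)
  U <- do.call(cbind, lapply(seq_len(g), function(k) orthogonal_init(C)))
  b <- numeric(g * C)
  if (cell_type == "lstm") b[gate_cols(2L, C)] <- 1  # forget-gate bias
  list(W = W, U = U, b = b, C = C, input_dim = input_dim, type = cell_type)
}

cell_forward <- function(x_list, cell) {
  T_len <- length(x_list)
  B <- nrow(x_list[[1]])
  C <- cell$C
  h_prev <- matrix(0, B, C)
  h_list <- vector("list", T_len)
  cache <- list(type = cell$type, x = x_list)
  switch(cell$type,
    vanilla = {
      for (t in seq_len(T_len)) {
        h_prev <- tanh(add_bias(x_list[[t]] %*% cell$W + h_prev %*% cell$U,
                                cell$b))
        h_list[[t]] <- h_prev
      }
      cache$h <- h_list
    },
    gru = {
      zs <- rs <- ns <- hs <- vector("list", T_len)
      iz <- gate_cols(1L, C); ir <- gate_cols(2L, C); inn <- gate_cols(3L, C)
      for (t in seq_len(T_len)) {
        x <- x_list[[t]]
        z <- sigmoid(add_bias(x %*% cell$W[, iz] + h_prev %*% cell$U[, iz],
                              cell$b[iz]))
        r <- sigmoid(add_bias(x %*% cell$W[, ir] + h_prev %*% cell$U[, ir],
                              cell$b[ir]))
        n <- tanh(add_bias(x %*% cell$W[, inn] +
                           (r * h_prev) %*% cell$U[, inn], cell$b[inn]))
        h <- (1 - z) * n + z * h_prev
        zs[[t]] <- z; rs[[t]] <- r; ns[[t]] <- n; hs[[t]] <- h
        h_prev <- h
        h_list[[t]] <- h
      }
      cache$z <- zs; cache$r <- rs; cache$n <- ns; cache$h <- hs
    },
    lstm = {
      c_prev <- matrix(0, B, C)
      is <- fs <- gs <- os <- cs <- vector("list", T_len)
      ii <- gate_cols(1L, C); if_ <- gate_cols(2L, C)
      ig <- gate_cols(3L, C); io <- gate_cols(4L, C)
      for (t in seq_len(T_len)) {
        a <- add_bias(x_list[[t]] %*% cell$W + h_prev %*% cell$U, cell$b)
        i_g <- sigmoid(a[, ii, drop = FALSE])
        f_g <- sigmoid(a[, if_, drop = FALSE])
        g_g <- tanh(a[, ig, drop = FALSE])
        o_g <- sigmoid(a[, io, drop = FALSE])
        c_prev <- f_g * c_prev + i_g * g_g
        h_prev <- o_g * tanh(c_prev)
        is[[t]] <- i_g; fs[[t]] <- f_g; gs[[t]] <- g_g; os[[t]] <- o_g
        cs[[t]] <- c_prev
        h_list[[t]] <- h_prev
      }
      cache$i <- is; cache$f <- fs; cache$g <- gs; cache$o <- os
      cache$c <- cs; cache$h <- h_list
    })
  list(h = h_list, cache = cache)
}

# dh_list: gradient of the loss wrt each time step's hidden output.
# Returns dx per step and parameter gradients.
cell_backward <- function(dh_list, cache, cell) {
  T_len <- length(dh_list)
  B <- nrow(dh_list[[1]])
  C <- cell$C
  dW <- cell$W * 0; dU <- cell$U * 0; db <- cell$b * 0
  dx_list <- vector("list", T_len)
  zero_h <- matrix(0, B, C)
  h_at <- function(t) if (t >= 1) cache$h[[t]] else zero_h

  switch(cache$type,
    vanilla = {
      dcarry <- zero_h
      for (t in rev(seq_len(T_len))) {
        h <- cache$h[[t]]
        da <- (dh_list[[t]] + dcarry) * (1 - h * h)
        dW <- dW + crossprod(cache$x[[t]], da)
        dU <- dU + crossprod(h_at(t - 1), da)
        db <- db + colSums(da)
        dx_list[[t]] <- da %*% t(cell$W)
        dcarry <- da %*% t(cell$U)
      }
    },
    gru = {
      iz <- gate_cols(1L, C); ir <- gate_cols(2L, C); inn <- gate_cols(3L, C)
      dcarry <- zero_h
      for (t in rev(seq_len(T_len))) {
        z <- cache$z[[t]]; r <- cache$r[[t]]; n <- cache$n[[t]]
        h_prev <- h_at(t - 1)
        dh <- dh_list[[t]] + dcarry
        dn <- dh * (1 - z)
        dz <- dh * (h_prev - n)
        dhp <- dh * z
        dan <- dn * (1 - n * n)
        drh <- dan %*% t(cell$U[, inn])
        dr <- drh * h_prev
        dhp <- dhp + drh * r
        daz <- dz * z * (1 - z)
        dar <- dr * r * (1 - r)
        x <- cache$x[[t]]
        dW[, iz] <- dW[, iz] + crossprod(x, daz)
        dW[, ir] <- dW[, ir] + crossprod(x, dar)
        dW[, inn] <- dW[, inn] + crossprod(x, dan)
        dU[, iz] <- dU[, iz] + crossprod(h_prev, daz)
        dU[, ir] <- dU[, ir] + crossprod(h_prev, dar)
        dU[, inn] <- dU[, inn] + crossprod(r * h_prev, dan)
        db[iz] <- db[iz] + colSums(daz)
        db[ir] <- db[ir] + colSums(dar)
        db[inn] <- db[inn] + colSums(dan)
        dx_list[[t]] <- daz %*% t(cell$W[, iz]) + dar %*% t(cell$W[, ir]) +
          dan %*% t(cell$W[, inn])
        dcarry <- dhp + daz %*% t(cell$U[, iz]) + dar %*% t(cell$U[, ir])
      }
    },
    lstm = {
      ii <- gate_cols(1L, C); if_ <- gate_cols(2L, C)
      ig <- gate_cols(3L, C); io <- gate_cols(4L, C)
      dcarry_h <- zero_h; dcarry_c <- zero_h
      zero_c <- zero_h
      for (t in rev(seq_len(T_len))) {
        i_g <- cache$i[[t]]; f_g <- cache$f[[t]]
        g_g <- cache$g[[t]]; o_g <- cache$o[[t]]
        c_now <- cache$c[[t]]
        c_prev <- if (t >= 2) cache$c[[t - 1]] else zero_c
        tc <- tanh(c_now)
        dh <- dh_list[[t]] + dcarry_h
        do_ <- dh * tc
        dc <- dcarry_c + dh * o_g * (1 - tc * tc)
        da <- cbind(dc * g_g * i_g * (1 - i_g),
                    dc * c_prev * f_g * (1 - f_g),
                    dc * i_g * (1 - g_g * g_g),
                    do_ * o_g * (1 - o_g))
        dcarry_c <- dc * f_g
        x <- cache$x[[t]]
        h_prev <- h_at(t - 1)
        dW <- dW + crossprod(x, da)
        dU <- dU + crossprod(h_prev, da)
        db <- db + colSums(da)
        dx_list[[t]] <- da %*% t(cell$W)
        dcarry_h <- da %*% t(cell$U)
      }
    })
  list(dx = dx_list, dW = dW, dU = dU, db = db)
}
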