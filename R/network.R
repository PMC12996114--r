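# Low-level recurrent network: LSTM stack + player embedding + dense head,
# with exact backpropagation-through-time. Everything is batched: the batch
# dimension is always the first dimension of every matrix, and one call
# processes all samples of a minibatch with dense matrix products.
#
# Dropout is variational (Gal-style): one Bernoulli mask per sample drawn per
# forward pass and reused across all time steps — applied to the recurrent
# state inside each LSTM layer, to the final hidden state entering the head,
# and to each dense hidden activation. The same masks stay fixed during one
# Monte-Carlo forward pass at inference, which is what makes MC-dropout
# predictive samples coherent over a recursive rollout.

sigmoid <- function(x) 1 / (1 + exp(-x))

unif_mat <- function(nr, nc, scale) {
  matrix(runif(nr * nc, -scale, scale), nr, nc)
}

# Parameter initialisation. Gate layout in the 4H-wide matrices is
# [input, forget, candidate, output]; the forget-gate bias starts at +1.
nn_init <- function(n_channels, units, n_layers, emb_dim, dense_widths,
                    n_players, n_targets = 6) {
  lstm <- vector("list", n_layers)
  d_in <- n_channels
  for (l in seq_len(n_layers)) {
    s <- 1 / sqrt(units)
    b <- rep(0, 4 * units)
    b[(units + 1):(2 * units)] <- 1
    lstm[[l]] <- list(Wx = unif_mat(d_in, 4 * units, s),
                      Wh = unif_mat(units, 4 * units, s),
                      b = b)
    d_in <- units
  }
  emb <- matrix(rnorm(n_players * emb_dim, 0, 0.1), n_players, emb_dim)
  dense <- list()
  d_in <- units + emb_dim + 1  # hidden state + embedding + next-step exo flag
  for (w in dense_widths) {
    dense[[length(dense) + 1]] <- list(W = unif_mat(d_in, w, sqrt(2 / d_in)),
                                       b = rep(0, w))
    d_in <- w
  }
  out <- list(W = unif_mat(d_in, n_targets, 1 / sqrt(d_in)), b = rep(0, n_targets))
  list(lstm = lstm, emb = emb, dense = dense, out = out)
}

# Draw one set of inverted-dropout masks for a batch of size B.
nn_masks <- function(B, units, n_layers, dense_widths, rate) {
  if (rate <= 0) return(NULL)
  keep <- 1 - rate
  msk <- function(n, m) matrix(rbinom(n * m, 1, keep) / keep, n, m)
  list(rec = lapply(seq_len(n_layers), function(l) msk(B, units)),
       top = msk(B, units),
       dense = lapply(dense_widths, function(w) msk(B, w)))
}

# Forward pass.
#   x:        B x L x C array of (already normalised) input windows
#   exo_next: length-B 0/1 vector, session type of the step being predicted
#   player:   length-B integer index into the embedding table
# Returns list(y = B x 6 predictions, cache = activations for backprop).
nn_forward <- function(params, cfg, x, exo_next, player, masks = NULL,
                       channel_mask = NULL, exo_mask = 1,
                       keep_cache = FALSE) {
  B <- dim(x)[1]; L <- dim(x)[2]; C <- dim(x)[3]
  H <- cfg$lstm_units
  inp <- lapply(seq_len(L), function(t) {
    xt <- matrix(x[, t, ], nrow = B)
    if (!is.null(channel_mask)) xt <- xt * rep(channel_mask, each = B)
    xt
  })
  layer_cache <- if (keep_cache) vector("list", length(params$lstm)) else NULL
  for (l in seq_along(params$lstm)) {
    W <- params$lstm[[l]]
    rmask <- if (!is.null(masks)) masks$rec[[l]] else NULL
    h <- matrix(0, B, H); cs <- matrix(0, B, H)
    steps <- if (keep_cache) vector("list", L) else NULL
    out_seq <- vector("list", L)
    for (t in seq_len(L)) {
      hprev <- h; cprev <- cs
      hdrop <- if (is.null(rmask)) hprev else hprev * rmask
      a <- inp[[t]] %*% W$Wx + hdrop %*% W$Wh
      a <- a + rep(W$b, each = B)
      i <- sigmoid(a[, 1:H, drop = FALSE])
      f <- sigmoid(a[, (H + 1):(2 * H), drop = FALSE])
      g <- tanh(a[, (2 * H + 1):(3 * H), drop = FALSE])
      o <- sigmoid(a[, (3 * H + 1):(4 * H), drop = FALSE])
      cs <- f * cprev + i * g
      tc <- tanh(cs)
      h <- o * tc
      if (keep_cache) {
        steps[[t]] <- list(xt = inp[[t]], hdrop = hdrop, cprev = cprev,
                           i = i, f = f, g = g, o = o, tc = tc)
      }
      out_seq[[t]] <- h
    }
    if (keep_cache) layer_cache[[l]] <- steps
    inp <- out_seq
  }
  hL <- inp[[L]]
  topmask <- if (!is.null(masks)) masks$top else NULL
  hdropped <- if (is.null(topmask)) hL else hL * topmask
  embeds <- params$emb[player, , drop = FALSE]
  exo_col <- matrix(exo_next * exo_mask, ncol = 1)
  z <- cbind(hdropped, embeds, exo_col)
  dense_cache <- if (keep_cache) vector("list", length(params$dense)) else NULL
  for (j in seq_along(params$dense)) {
    lin <- z %*% params$dense[[j]]$W
    lin <- lin + rep(params$dense[[j]]$b, each = B)
    act <- pmax(lin, 0)
    dmask <- if (!is.null(masks)) masks$dense[[j]] else NULL
    actd <- if (is.null(dmask)) act else act * dmask
    if (keep_cache) dense_cache[[j]] <- list(zin = z, lin = lin)
    z <- actd
  }
  y <- z %*% params$out$W
  y <- y + rep(params$out$b, each = B)
  cache <- NULL
  if (keep_cache) {
    cache <- list(lstm = layer_cache, dense = dense_cache, z_final = z,
                  hL = hL, player = player, masks = masks,
                  dims = c(B = B, L = L, C = C),
                  channel_mask = channel_mask, exo_mask = exo_mask)
  }
  list(y = y, cache = cache)
}

# Backward pass: given dY = dLoss/dy (B x 6), returns gradients for every
# parameter plus the gradient with respect to the input window (B x L x C)
# and the next-step exogenous flag.
nn_backward <- function(params, cfg, cache, dY) {
  B <- cache$dims["B"]; L <- cache$dims["L"]; C <- cache$dims["C"]
  H <- cfg$lstm_units
  masks <- cache$masks
  g_out <- list(W = t(cache$z_final) %*% dY, b = colSums(dY))
  dz <- dY %*% t(params$out$W)
  g_dense <- vector("list", length(params$dense))
  for (j in rev(seq_along(params$dense))) {
    cc <- cache$dense[[j]]
    dmask <- if (!is.null(masks)) masks$dense[[j]] else NULL
    dact <- if (is.null(dmask)) dz else dz * dmask
    dlin <- dact * (cc$lin > 0)
    g_dense[[j]] <- list(W = t(cc$zin) %*% dlin, b = colSums(dlin))
    dz <- dlin %*% t(params$dense[[j]]$W)
  }
  E <- ncol(params$emb)
  dh_top <- dz[, 1:H, drop = FALSE]
  demb_rows <- dz[, (H + 1):(H + E), drop = FALSE]
  dexo_next <- dz[, H + E + 1] * cache$exo_mask
  g_emb <- matrix(0, nrow(params$emb), E)
  acc <- rowsum(demb_rows, group = cache$player)
  g_emb[as.integer(rownames(acc)), ] <- acc

  topmask <- if (!is.null(masks)) masks$top else NULL
  dhL <- if (is.null(topmask)) dh_top else dh_top * topmask

  g_lstm <- vector("list", length(params$lstm))
  # gradient flowing into each layer's output at each time step
  d_out <- c(rep(list(matrix(0, B, H)), L - 1), list(dhL))
  for (l in rev(seq_along(params$lstm))) {
    W <- params$lstm[[l]]
    steps <- cache$lstm[[l]]
    rmask <- if (!is.null(masks)) masks$rec[[l]] else NULL
    dWx <- matrix(0, nrow(W$Wx), ncol(W$Wx))
    dWh <- matrix(0, H, 4 * H)
    db <- rep(0, 4 * H)
    dh_carry <- matrix(0, B, H)
    dc <- matrix(0, B, H)
    dx_seq <- vector("list", L)
    for (t in rev(seq_len(L))) {
      st <- steps[[t]]
      dh <- d_out[[t]] + dh_carry
      do_ <- dh * st$tc
      dc <- dc + dh * st$o * (1 - st$tc^2)
      di <- dc * st$g
      df <- dc * st$cprev
      dg <- dc * st$i
      dc <- dc * st$f
      da <- cbind(di * st$i * (1 - st$i),
                  df * st$f * (1 - st$f),
                  dg * (1 - st$g^2),
                  do_ * st$o * (1 - st$o))
      dWx <- dWx + crossprod(st$xt, da)
      dWh <- dWh + crossprod(st$hdrop, da)
      db <- db + colSums(da)
      dh_carry <- da %*% t(W$Wh)
      if (!is.null(rmask)) dh_carry <- dh_carry * rmask
      dx_seq[[t]] <- da %*% t(W$Wx)
    }
    g_lstm[[l]] <- list(Wx = dWx, Wh = dWh, b = db)
    d_out <- dx_seq
  }
  dx <- array(0, dim = c(B, L, C))
  cm <- cache$channel_mask
  for (t in seq_len(L)) {
    dxt <- d_out[[t]]
    if (!is.null(cm)) dxt <- dxt * rep(cm, each = B)
    dx[, t, ] <- dxt
  }
  list(lstm = g_lstm, emb = g_emb, dense = g_dense, out = g_out,
       dx = dx, dexo_next = dexo_next)
}

# ---- Adam over the nested parameter list ------------------------------------

adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else p * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  tt <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      res <- purrr::pmap(list(p, g, m, v), upd)
      return(list(p = lapply(res, `[[`, "p"), m = lapply(res, `[[`, "m"),
                  v = lapply(res, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^tt)
    vhat <- v / (1 - beta2^tt)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  res <- upd(params, grads[c("lstm", "emb", "dense", "out")],
             state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = tt))
}
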