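# Minimal neural-network engine for the sequence classifiers: batched
# forward/backward passes in vectorized base R, ADAM updates.  Index 0 is
# the padding token; embedding row 1 (pad) is pinned to zero.

sigmoid <- function(x) 1 / (1 + exp(-x))

nn_init_params <- function(arch, V, d, H, filters, kernels, K,
                           pretrained_E = NULL) {
  gl <- function(nr, nc) {  # Glorot-uniform init
    lim <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }
  E <- if (!is.null(pretrained_E)) rbind(0, pretrained_E)
       else rbind(0, matrix(rnorm(V * d, sd = 0.1), V, d))
  p <- list(E = E)
  if (arch == "lstm") {
    p$W <- gl(d + H, 4 * H)
    p$b <- c(rep(0, H), rep(1, H), rep(0, 2 * H))  # forget-gate bias 1
    p$W_out <- gl(H, K)
    p$b_out <- rep(0, K)
  } else {
    for (k in kernels) {
      p[[paste0("Wk", k)]] <- gl(k * d, filters)
      p[[paste0("bk", k)]] <- rep(0, filters)
    }
    p$W_out <- gl(filters * length(kernels), K)
    p$b_out <- rep(0, K)
  }
  p
}

# ids: B x T integer matrix, 0 = pad.  Returns list(probs, loss, grads).
# With y = NULL only the forward pass runs.
nn_pass <- function(params, arch, kernels, ids, y = NULL) {
  B <- nrow(ids)
  d <- ncol(params$E)
  K <- length(params$b_out)
  lens <- rowSums(ids > 0)
  Tmax <- max(1L, max(lens))
  if (arch != "lstm") Tmax <- max(Tmax, max(kernels))
  Tmax <- min(Tmax, ncol(ids))
  ids <- ids[, seq_len(Tmax), drop = FALSE]

  emb <- function(t) params$E[ids[, t] + 1L, , drop = FALSE]

  if (arch == "lstm") {
    H <- nrow(params$W_out)
    h <- matrix(0, B, H); cc <- matrix(0, B, H)
    cache <- vector("list", Tmax)
    for (t in seq_len(Tmax)) {
      m <- as.numeric(ids[, t] > 0)
      x <- emb(t)
      z <- cbind(h, x) %*% params$W +
        matrix(params$b, B, 4 * H, byrow = TRUE)
      i <- sigmoid(z[, 1:H, drop = FALSE])
      f <- sigmoid(z[, H + 1:H, drop = FALSE])
      o <- sigmoid(z[, 2 * H + 1:H, drop = FALSE])
      g <- tanh(z[, 3 * H + 1:H, drop = FALSE])
      c_new <- f * cc + i * g
      tc <- tanh(c_new)
      h_new <- o * tc
      cache[[t]] <- list(m = m, x = x, h_prev = h, c_prev = cc,
                         i = i, f = f, o = o, g = g, tc = tc)
      h <- m * h_new + (1 - m) * h
      cc <- m * c_new + (1 - m) * cc
    }
    logits <- h %*% params$W_out +
      matrix(params$b_out, B, K, byrow = TRUE)
    probs <- softmax_rows(logits)
    if (is.null(y)) return(list(probs = probs))

    Y <- matrix(0, B, K); Y[cbind(seq_len(B), y)] <- 1
    loss <- -mean(log(pmax(probs[cbind(seq_len(B), y)], 1e-12)))
    dlogits <- (probs - Y) / B
    g_ <- list(W_out = crossprod(h, dlogits), b_out = colSums(dlogits),
               W = matrix(0, d + H, 4 * H), b = rep(0, 4 * H))
    dh <- dlogits %*% t(params$W_out)
    dc <- matrix(0, B, H)
    emb_rows <- vector("list", Tmax)
    for (t in rev(seq_len(Tmax))) {
      cch <- cache[[t]]
      m <- cch$m
      dh_new <- m * dh
      dc_new <- m * dc
      dh_pass <- (1 - m) * dh
      dc_pass <- (1 - m) * dc
      do_ <- dh_new * cch$tc
      dc_new <- dc_new + dh_new * cch$o * (1 - cch$tc^2)
      di <- dc_new * cch$g
      df <- dc_new * cch$c_prev
      dg <- dc_new * cch$i
      dc <- dc_new * cch$f + dc_pass
      dz <- cbind(di * cch$i * (1 - cch$i),
                  df * cch$f * (1 - cch$f),
                  do_ * cch$o * (1 - cch$o),
                  dg * (1 - cch$g^2))
      hx <- cbind(cch$h_prev, cch$x)
      g_$W <- g_$W + crossprod(hx, dz)
      g_$b <- g_$b + colSums(dz)
      dhx <- dz %*% t(params$W)
      dh <- dhx[, 1:H, drop = FALSE] + dh_pass
      dx <- dhx[, H + 1:d, drop = FALSE]
      emb_rows[[t]] <- list(idx = ids[, t] + 1L, grad = m * dx)
    }
    g_$E <- accumulate_embedding_grad(emb_rows, nrow(params$E), d)
    return(list(probs = probs, loss = loss, grads = g_))
  }

  # 1D CNN (single- or multi-kernel), relu + max-over-time per filter
  Fn <- ncol(params[[paste0("Wk", kernels[1])]])
  X <- lapply(seq_len(Tmax), emb)
  pooled <- NULL
  pool_info <- list()
  for (k in kernels) {
    Wk <- params[[paste0("Wk", k)]]
    bk <- params[[paste0("bk", k)]]
    best <- matrix(-Inf, B, Fn)
    argt <- matrix(1L, B, Fn)
    for (t in seq_len(Tmax - k + 1L)) {
      Xc <- do.call(cbind, X[t:(t + k - 1L)])
      Z <- Xc %*% Wk + matrix(bk, B, Fn, byrow = TRUE)
      upd <- Z > best
      best[upd] <- Z[upd]
      argt[upd] <- t
    }
    pool_info[[as.character(k)]] <- list(best = best, argt = argt)
    pooled <- cbind(pooled, pmax(best, 0))
  }
  logits <- pooled %*% params$W_out +
    matrix(params$b_out, B, K, byrow = TRUE)
  probs <- softmax_rows(logits)
  if (is.null(y)) return(list(probs = probs))

  Y <- matrix(0, B, K); Y[cbind(seq_len(B), y)] <- 1
  loss <- -mean(log(pmax(probs[cbind(seq_len(B), y)], 1e-12)))
  dlogits <- (probs - Y) / B
  g_ <- list(W_out = crossprod(pooled, dlogits),
             b_out = colSums(dlogits))
  dpooled <- dlogits %*% t(params$W_out)
  emb_rows <- list()
  dX <- lapply(seq_len(Tmax), function(t) matrix(0, B, d))
  for (ki in seq_along(kernels)) {
    k <- kernels[ki]
    info <- pool_info[[as.character(k)]]
    dM <- dpooled[, (ki - 1L) * Fn + seq_len(Fn), drop = FALSE]
    dM <- dM * (info$best > 0)  # relu gate at the pooled winner
    Wk <- params[[paste0("Wk", k)]]
    dWk <- matrix(0, k * d, Fn)
    dbk <- rep(0, Fn)
    for (t in seq_len(Tmax - k + 1L)) {
      sel <- dM * (info$argt == t)
      if (!any(sel != 0)) next
      Xc <- do.call(cbind, X[t:(t + k - 1L)])
      dWk <- dWk + crossprod(Xc, sel)
      dbk <- dbk + colSums(sel)
      dXc <- sel %*% t(Wk)
      for (j in seq_len(k)) {
        dX[[t + j - 1L]] <- dX[[t + j - 1L]] +
          dXc[, (j - 1L) * d + seq_len(d), drop = FALSE]
      }
    }
    g_[[paste0("Wk", k)]] <- dWk
    g_[[paste0("bk", k)]] <- dbk
  }
  emb_rows <- lapply(seq_len(Tmax), function(t) {
    list(idx = ids[, t] + 1L, grad = dX[[t]])
  })
  g_$E <- accumulate_embedding_grad(emb_rows, nrow(params$E), d)
  list(probs = probs, loss = loss, grads = g_)
}

accumulate_embedding_grad <- function(emb_rows, n_rows, d) {
  idx <- unlist(lapply(emb_rows, `[[`, "idx"), use.names = FALSE)
  G <- do.call(rbind, lapply(emb_rows, `[[`, "grad"))
  agg <- rowsum(G, group = idx)
  dE <- matrix(0, n_rows, d)
  dE[as.integer(rownames(agg)), ] <- agg
  dE[1L, ] <- 0  # pad row is pinned
  dE
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr = 0.01,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  params$E[1L, ] <- 0
  list(params = params, state = state)
}
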