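# Hand-derived backpropagation for the VAE-FPC generator. The forward pass
# mirrors vae_encode / fpc_scores / apply_fpc / vae_decode_logits / vae_loss
# exactly; correctness is pinned by numerical gradient checks in the test
# suite.

zero_like <- function(params) lapply(params, function(p) p * 0)

# Backward through a stacked masked LSTM. d_top: list over time of gradients
# w.r.t. the (masked) top-layer hidden state. Returns parameter gradients and
# the gradients w.r.t. the layer-1 inputs at every step.
lstm_backward <- function(params, prefix, layers, run, mask, grads) {
  T <- length(run$cache)
  B <- nrow(run$top[[1]]); H <- ncol(run$top[[1]])
  d_top <- run$d_top
  dh_next <- lapply(seq_len(layers), function(l) matrix(0, B, H))
  dc_next <- lapply(seq_len(layers), function(l) matrix(0, B, H))
  dxs <- vector("list", T)
  for (t in rev(seq_len(T))) {
    m <- mask[, t]
    dx_upper <- NULL
    for (l in rev(seq_len(layers))) {
      cc <- run$cache[[t]][[l]]
      st <- cc$st
      dh_total <- dh_next[[l]]
      if (l == layers) {
        if (!is.null(d_top[[t]])) dh_total <- dh_total + d_top[[t]]
      } else if (!is.null(dx_upper)) {
        dh_total <- dh_total + dx_upper
      }
      dc_total <- dc_next[[l]]
      dh_new <- dh_total * m
      dh_carry <- dh_total * (1 - m)
      dc_new <- dc_total * m
      dc_carry <- dc_total * (1 - m)
      tc <- tanh(st$c)
      do_ <- dh_new * tc
      dct <- dh_new * st$o * (1 - tc^2) + dc_new
      df <- dct * cc$c_prev
      di <- dct * st$g
      dg <- dct * st$i
      dc_prev <- dct * st$f + dc_carry
      dgates <- cbind(di * st$i * (1 - st$i),
                      df * st$f * (1 - st$f),
                      dg * (1 - st$g^2),
                      do_ * st$o * (1 - st$o))
      W <- params[[paste0(prefix, l, "_W")]]
      U <- params[[paste0(prefix, l, "_U")]]
      grads[[paste0(prefix, l, "_W")]] <-
        grads[[paste0(prefix, l, "_W")]] + crossprod(cc$x, dgates)
      grads[[paste0(prefix, l, "_U")]] <-
        grads[[paste0(prefix, l, "_U")]] + crossprod(cc$h_prev, dgates)
      grads[[paste0(prefix, l, "_b")]] <-
        grads[[paste0(prefix, l, "_b")]] + colSums(dgates)
      dx_upper <- tcrossprod(dgates, W)
      dh_next[[l]] <- tcrossprod(dgates, U) + dh_carry
      dc_next[[l]] <- dc_prev
    }
    dxs[[t]] <- dx_upper
  }
  list(grads = grads, dxs = dxs)
}

accumulate_emb_grad <- function(gemb, ids_col, dx) {
  agg <- rowsum(dx, ids_col + 1L)
  rows <- as.integer(rownames(agg))
  gemb[rows, ] <- gemb[rows, , drop = FALSE] + agg
  gemb
}

# Full forward + backward for one mini-batch. ids: framed padded 0-based id
# matrix; cond: per-row condition value; eps: B x Z reparameterization noise.
vae_forward_backward <- function(model, ids, cond, eps, kl_weight = NULL) {
  cfg <- model$config; p <- model$params
  alpha <- model$alphabet
  pad <- special_id(alpha, "pad")
  B <- nrow(ids); Tfull <- ncol(ids)
  Z <- cfg$latent_dim
  V <- length(alpha$tokens)
  L <- cfg$encoder_rnn_layers; Ld <- cfg$decoder_rnn_layers

  # ---- forward: encoder ----
  enc_mask <- (ids != pad) * 1
  enc_xs <- lapply(seq_len(Tfull), function(t) p$emb[ids[, t] + 1L, , drop = FALSE])
  enc <- lstm_run(p, "enc_l", L, enc_xs, enc_mask, cfg$encoder_rnn_dim)
  hT <- enc$h_final[[L]]
  mu <- hT %*% p$mu_W + rep(p$mu_b, each = B)
  ls <- hT %*% p$ls_W + rep(p$ls_b, each = B)
  z <- mu + exp(ls) * eps

  # ---- forward: FPC ----
  a0 <- cbind(z, cond)
  a1 <- tanh(a0 %*% p$fpc_W1 + rep(p$fpc_b1, each = B))
  a2 <- tanh(a1 %*% p$fpc_W2 + rep(p$fpc_b2, each = B))
  e_sc <- a2 %*% p$fpc_W3 + rep(p$fpc_b3, each = B)
  s <- softmax_rows(e_sc)
  r_fac <- if (cfg$fpc_rescale) Z else 1
  zc <- s * z * r_fac

  # ---- forward: decoder ----
  teacher <- ids[, 1:(Tfull - 1L), drop = FALSE]
  target <- ids[, 2:Tfull, drop = FALSE]
  T <- ncol(teacher)
  dec_mask <- matrix(1, B, T)
  dec_xs <- lapply(seq_len(T), function(t)
    cbind(p$emb[teacher[, t] + 1L, , drop = FALSE], zc, cond))
  dec <- lstm_run(p, "dec_l", Ld, dec_xs, dec_mask, cfg$decoder_rnn_dim)

  n_tok <- sum(target != pad)
  ce <- 0; n_hit <- 0
  dtops <- vector("list", T)
  grads <- zero_like(p)
  for (t in seq_len(T)) {
    logits <- dec$top[[t]] %*% p$out_W + rep(p$out_b, each = B)
    pr <- softmax_rows(logits)
    live <- target[, t] != pad
    dlog <- pr
    idx <- cbind(seq_len(B), target[, t] + 1L)
    dlog[idx] <- dlog[idx] - 1
    dlog[!live, ] <- 0
    dlog <- dlog / n_tok
    ce <- ce - sum(log(pmax(pr[idx][live], 1e-12)))
    n_hit <- n_hit + sum((max.col(logits) == target[, t] + 1L)[live])
    grads$out_W <- grads$out_W + crossprod(dec$top[[t]], dlog)
    grads$out_b <- grads$out_b + colSums(dlog)
    dtops[[t]] <- tcrossprod(dlog, p$out_W)
  }
  recon <- ce / n_tok
  kl <- vae_loss_kl(mu, ls)
  klw <- if (is.null(kl_weight)) cfg$kl_weight else kl_weight
  total <- recon + klw * kl
  acc <- n_hit / n_tok

  # ---- backward: decoder ----
  dec$d_top <- dtops
  bd <- lstm_backward(p, "dec_l", Ld, dec, dec_mask, grads)
  grads <- bd$grads
  E <- cfg$embedding_dim
  dzc <- matrix(0, B, Z)
  for (t in seq_len(T)) {
    dx <- bd$dxs[[t]]
    grads$emb <- accumulate_emb_grad(grads$emb, teacher[, t], dx[, 1:E, drop = FALSE])
    dzc <- dzc + dx[, (E + 1):(E + Z), drop = FALSE]
  }

  # ---- backward: FPC ----
  dzc_eff <- dzc * r_fac
  ds <- dzc_eff * z
  dz <- dzc_eff * s
  de <- s * (ds - rowSums(ds * s))
  grads$fpc_W3 <- grads$fpc_W3 + crossprod(a2, de)
  grads$fpc_b3 <- grads$fpc_b3 + colSums(de)
  da2 <- tcrossprod(de, p$fpc_W3)
  dp2 <- da2 * (1 - a2^2)
  grads$fpc_W2 <- grads$fpc_W2 + crossprod(a1, dp2)
  grads$fpc_b2 <- grads$fpc_b2 + colSums(dp2)
  da1 <- tcrossprod(dp2, p$fpc_W2)
  dp1 <- da1 * (1 - a1^2)
  grads$fpc_W1 <- grads$fpc_W1 + crossprod(a0, dp1)
  grads$fpc_b1 <- grads$fpc_b1 + colSums(dp1)
  da0 <- tcrossprod(dp1, p$fpc_W1)
  dz <- dz + da0[, 1:Z, drop = FALSE]

  # ---- backward: reparameterization + KL ----
  dmu <- dz + klw * mu / B
  dls <- dz * eps * exp(ls) + klw * (exp(2 * ls) - 1) / B

  # ---- backward: heads + encoder ----
  grads$mu_W <- grads$mu_W + crossprod(hT, dmu)
  grads$mu_b <- grads$mu_b + colSums(dmu)
  grads$ls_W <- grads$ls_W + crossprod(hT, dls)
  grads$ls_b <- grads$ls_b + colSums(dls)
  dhT <- tcrossprod(dmu, p$mu_W) + tcrossprod(dls, p$ls_W)
  enc$d_top <- c(vector("list", Tfull - 1L), list(dhT))
  be <- lstm_backward(p, "enc_l", L, enc, enc_mask, grads)
  grads <- be$grads
  for (t in seq_len(Tfull))
    grads$emb <- accumulate_emb_grad(grads$emb, ids[, t], be$dxs[[t]])

  list(total = total, reconstruction = recon, kl = kl, accuracy = acc,
       grads = grads)
}

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_update <- function(params, grads, state, lr, betas = c(0.9, 0.999),
                        eps = 1e-8) {
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  bc1 <- 1 - b1^state$t; bc2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
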