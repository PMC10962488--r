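#' Generator architecture configuration
#'
#' Defaults mirror the full-scale architecture: 200-dim token embeddings,
#' three 512-unit LSTM layers on both sides, a 200-dim latent space, and a
#' `[z; c] -> 64 -> 64 -> 200` feature-property-correlation (FPC) attention
#' network whose softmax output reweights the latent dimensions by their
#' learned relevance to the condition property (QED). Tests and examples use
#' much smaller settings.
#'
#' @param embedding_dim token embedding width.
#' @param encoder_rnn_dim,encoder_rnn_layers encoder LSTM size.
#' @param latent_dim dimension of the latent code z.
#' @param fpc_hidden_dims two hidden widths of the FPC network.
#' @param decoder_rnn_dim,decoder_rnn_layers decoder LSTM size.
#' @param kl_weight weight on the KL term of the loss.
#' @param kl_anneal_steps linear KL annealing: the effective KL weight ramps
#'   from 0 to `kl_weight` over this many optimizer steps (0 = off).
#' @param fpc_rescale multiply the FPC-conditioned latent by `latent_dim`
#'   (compensates the shrinkage of multiplying by a probability vector);
#'   off by default.
#' @param max_len maximum decoded sequence length (content tokens).
#' @return object of class `gen_config`.
#' @export
gen_config <- function(embedding_dim = 200L, encoder_rnn_dim = 512L,
                       encoder_rnn_layers = 3L, latent_dim = 200L,
                       fpc_hidden_dims = c(64L, 64L), decoder_rnn_dim = 512L,
                       decoder_rnn_layers = 3L, kl_weight = 1.0,
                       kl_anneal_steps = 0L, fpc_rescale = FALSE,
                       max_len = 120L) {
  cfg <- list(embedding_dim = as.integer(embedding_dim),
              encoder_rnn_dim = as.integer(encoder_rnn_dim),
              encoder_rnn_layers = as.integer(encoder_rnn_layers),
              latent_dim = as.integer(latent_dim),
              fpc_hidden_dims = as.integer(fpc_hidden_dims),
              decoder_rnn_dim = as.integer(decoder_rnn_dim),
              decoder_rnn_layers = as.integer(decoder_rnn_layers),
              kl_weight = kl_weight,
              kl_anneal_steps = as.integer(kl_anneal_steps),
              fpc_rescale = isTRUE(fpc_rescale),
              max_len = as.integer(max_len))
  stopifnot(all(unlist(cfg[1:7]) > 0))
  structure(cfg, class = "gen_config")
}

#' Optimizer and early-stop configuration
#'
#' Adam with the stated moments and epsilon; the learning rate is multiplied
#' by `1 - lr_decay_rate` every `lr_decay_steps` optimizer steps. Training
#' stops at `max_epochs`, or earlier once the teacher-forced token accuracy
#' exceeds `acc_threshold_delta` for `acc_window_steps` consecutive steps.
#'
#' @param batch_size mini-batch size.
#' @param base_lr initial Adam learning rate.
#' @param lr_decay_rate multiplicative decay fraction per decay interval.
#' @param lr_decay_steps steps between decays.
#' @param adam_betas,adam_eps Adam moment parameters.
#' @param max_epochs epoch cap.
#' @param acc_threshold_delta accuracy threshold for the early stop.
#' @param acc_window_steps consecutive steps the threshold must hold.
#' @param seed RNG seed controlling shuffling and the reparameterization draws.
#' @return object of class `train_config`.
#' @export
train_config <- function(batch_size = 64L, base_lr = 5e-4,
                         lr_decay_rate = 0.03, lr_decay_steps = 1000L,
                         adam_betas = c(0.9, 0.999), adam_eps = 1e-8,
                         max_epochs = 8L, acc_threshold_delta = 0.95,
                         acc_window_steps = 500L, seed = 1L) {
  stopifnot(batch_size >= 1, acc_threshold_delta > 0, acc_threshold_delta < 1)
  structure(list(batch_size = as.integer(batch_size), base_lr = base_lr,
                 lr_decay_rate = lr_decay_rate,
                 lr_decay_steps = as.integer(lr_decay_steps),
                 adam_betas = adam_betas, adam_eps = adam_eps,
                 max_epochs = as.integer(max_epochs),
                 acc_threshold_delta = acc_threshold_delta,
                 acc_window_steps = as.integer(acc_window_steps),
                 seed = as.integer(seed)),
            class = "train_config")
}

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

lstm_param_block <- function(prefix, layers, input_dim, hidden_dim) {
  p <- list()
  for (l in seq_len(layers)) {
    ind <- if (l == 1L) input_dim else hidden_dim
    b <- rep(0, 4 * hidden_dim)
    b[(hidden_dim + 1):(2 * hidden_dim)] <- 1  # forget-gate bias
    p[[paste0(prefix, l, "_W")]] <- glorot(ind, 4 * hidden_dim)
    p[[paste0(prefix, l, "_U")]] <- glorot(hidden_dim, 4 * hidden_dim)
    p[[paste0(prefix, l, "_b")]] <- b
  }
  p
}

#' Initialize a VAE-FPC generator
#'
#' @param config a [gen_config()].
#' @param alphabet a [build_alphabet()] token alphabet.
#' @param seed RNG seed for the weight initialization.
#' @return object of class `vae_fpc` with fields `params`, `config`,
#'   `alphabet`.
#' @export
vae_init <- function(config, alphabet, seed = 1L) {
  stopifnot(inherits(config, "gen_config"), inherits(alphabet, "token_alphabet"))
  set.seed(seed)
  V <- length(alphabet$tokens)
  E <- config$embedding_dim; H <- config$encoder_rnn_dim
  Z <- config$latent_dim; Hd <- config$decoder_rnn_dim
  h1 <- config$fpc_hidden_dims[1]; h2 <- config$fpc_hidden_dims[2]
  params <- c(
    list(emb = glorot(V, E)),
    lstm_param_block("enc_l", config$encoder_rnn_layers, E, H),
    list(mu_W = glorot(H, Z), mu_b = rep(0, Z),
         ls_W = glorot(H, Z), ls_b = rep(0, Z),
         fpc_W1 = glorot(Z + 1L, h1), fpc_b1 = rep(0, h1),
         fpc_W2 = glorot(h1, h2), fpc_b2 = rep(0, h2),
         fpc_W3 = glorot(h2, Z), fpc_b3 = rep(0, Z)),
    lstm_param_block("dec_l", config$decoder_rnn_layers, E + Z + 1L, Hd),
    list(out_W = glorot(Hd, V), out_b = rep(0, V)))
  structure(list(params = params, config = config, alphabet = alphabet),
            class = "vae_fpc")
}

#' @export
print.vae_fpc <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat("vae_fpc generator:", length(x$alphabet$tokens), "tokens, latent",
      x$config$latent_dim, ",", format(np, big.mark = ","), "parameters\n")
  invisible(x)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# One LSTM step for a whole batch. gates columns are [i | f | g | o].
lstm_step <- function(x, h_prev, c_prev, W, U, b) {
  H <- ncol(U)
  gates <- x %*% W + h_prev %*% U + rep(b, each = nrow(x))
  Hn <- H / 4
  i <- sigmoid(gates[, 1:Hn, drop = FALSE])
  f <- sigmoid(gates[, (Hn + 1):(2 * Hn), drop = FALSE])
  g <- tanh(gates[, (2 * Hn + 1):(3 * Hn), drop = FALSE])
  o <- sigmoid(gates[, (3 * Hn + 1):(4 * Hn), drop = FALSE])
  c_new <- f * c_prev + i * g
  h_new <- o * tanh(c_new)
  list(h = h_new, c = c_new, i = i, f = f, g = g, o = o)
}

# Run a stacked LSTM over a sequence of input matrices with per-step masks
# (1 = real token, 0 = pad: state carries through unchanged). Returns the top
# layer's hidden states and the caches needed for backprop.
lstm_run <- function(params, prefix, layers, xs, mask, hidden_dim) {
  B <- nrow(xs[[1]]); T <- length(xs)
  hs <- lapply(seq_len(layers), function(l) matrix(0, B, hidden_dim))
  cs <- lapply(seq_len(layers), function(l) matrix(0, B, hidden_dim))
  cache <- vector("list", T)
  top <- vector("list", T)
  for (t in seq_len(T)) {
    m <- mask[, t]
    inp <- xs[[t]]
    step_cache <- vector("list", layers)
    for (l in seq_len(layers)) {
      W <- params[[paste0(prefix, l, "_W")]]
      U <- params[[paste0(prefix, l, "_U")]]
      b <- params[[paste0(prefix, l, "_b")]]
      st <- lstm_step(inp, hs[[l]], cs[[l]], W, U, b)
      h_new <- m * st$h + (1 - m) * hs[[l]]
      c_new <- m * st$c + (1 - m) * cs[[l]]
      step_cache[[l]] <- list(x = inp, h_prev = hs[[l]], c_prev = cs[[l]],
                              st = st)
      hs[[l]] <- h_new; cs[[l]] <- c_new
      inp <- h_new
    }
    cache[[t]] <- step_cache
    top[[t]] <- hs[[layers]]
  }
  list(top = top, h_final = hs, c_final = cs, cache = cache)
}

#' Encode token sequences to latent Gaussians
#'
#' Runs embedding, the stacked encoder LSTM (pad positions carry state
#' through), and the two linear heads producing the posterior mean and
#' log-standard-deviation. Deterministic given parameters and input.
#'
#' @param model a [vae_init()] model.
#' @param ids integer matrix of 0-based token ids (rows = sequences), framed
#'   with start/end and right-padded with the pad id.
#' @return list with matrices `mu` and `log_sigma` (rows = sequences).
#' @export
vae_encode <- function(model, ids) {
  cfg <- model$config; p <- model$params
  if (ncol(ids) > cfg$max_len + 2L) stop("sequence longer than max_len")
  pad <- special_id(model$alphabet, "pad")
  mask <- (ids != pad) * 1
  xs <- lapply(seq_len(ncol(ids)), function(t) p$emb[ids[, t] + 1L, , drop = FALSE])
  run <- lstm_run(p, "enc_l", cfg$encoder_rnn_layers, xs, mask, cfg$encoder_rnn_dim)
  h <- run$h_final[[cfg$encoder_rnn_layers]]
  list(mu = h %*% p$mu_W + rep(p$mu_b, each = nrow(h)),
       log_sigma = h %*% p$ls_W + rep(p$ls_b, each = nrow(h)))
}

#' Reparameterization: z = mu + exp(log_sigma) * epsilon
#'
#' @param mu,log_sigma matrices (or vectors) from [vae_encode()].
#' @param epsilon noise of the same shape.
#' @return latent sample z.
#' @export
reparameterize <- function(mu, log_sigma, epsilon) {
  if (length(mu) != length(log_sigma) || length(mu) != length(epsilon))
    stop("dimension mismatch in reparameterization")
  mu + exp(log_sigma) * epsilon
}

#' FPC correlation scores
#'
#' The feature-property-correlation network scores each latent dimension's
#' relevance to the condition property: `E = MLP([z; c])` with tanh hidden
#' layers, normalized by a row softmax. Scores are nonnegative and each row
#' sums to one.
#'
#' @param model a `vae_fpc` model.
#' @param z latent matrix (rows = molecules) or single vector.
#' @param cond condition property values (QED), one per row.
#' @return score matrix of the same shape as `z`.
#' @export
fpc_scores <- function(model, z, cond) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  stopifnot(all(is.finite(cond)))
  p <- model$params
  a0 <- cbind(z, cond)
  a1 <- tanh(a0 %*% p$fpc_W1 + rep(p$fpc_b1, each = nrow(a0)))
  a2 <- tanh(a1 %*% p$fpc_W2 + rep(p$fpc_b2, each = nrow(a1)))
  e <- a2 %*% p$fpc_W3 + rep(p$fpc_b3, each = nrow(a2))
  softmax_rows(e)
}

# Batch-mean KL divergence of N(mu, sigma) from the standard normal.
vae_loss_kl <- function(mu, log_sigma) {
  mean(-0.5 * rowSums(1 + 2 * log_sigma - mu^2 - exp(2 * log_sigma)))
}

softmax_rows <- function(e) {
  m <- apply(e, 1, max)
  ex <- exp(e - m)
  ex / rowSums(ex)
}

#' Apply FPC scores to the latent code
#'
#' `Zc = scores * z` elementwise; with `fpc_rescale` the product is multiplied
#' by `latent_dim`, undoing the ~1/latent_dim shrinkage of weighting by a
#' probability vector.
#'
#' @param z latent matrix or vector.
#' @param scores matching score matrix from [fpc_scores()].
#' @param rescale logical.
#' @return conditioned latent Zc.
#' @export
apply_fpc <- function(z, scores, rescale = FALSE) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  stopifnot(identical(dim(z), dim(scores)))
  zc <- z * scores
  if (isTRUE(rescale)) zc <- zc * ncol(z)
  zc
}

#' Teacher-forced decoder logits
#'
#' The context `[Zc; c]` is concatenated to every step's token embedding; the
#' stacked decoder LSTM and the output head produce alphabet-sized logits per
#' position.
#'
#' @param model a `vae_fpc` model.
#' @param zc conditioned latent matrix (rows = sequences).
#' @param cond condition values, one per row.
#' @param teacher_ids 0-based id matrix starting with the start token.
#' @return array `(rows, steps, alphabet)` of logits.
#' @export
vae_decode_logits <- function(model, zc, cond, teacher_ids) {
  cfg <- model$config; p <- model$params
  if (is.null(dim(zc))) zc <- matrix(zc, nrow = 1)
  if (!is.matrix(teacher_ids)) teacher_ids <- matrix(teacher_ids, nrow = 1)
  start <- special_id(model$alphabet, "start")
  if (!all(teacher_ids[, 1] == start)) stop("teacher sequences must begin with the start token")
  pad <- special_id(model$alphabet, "pad")
  B <- nrow(teacher_ids); T <- ncol(teacher_ids)
  mask <- matrix(1, B, T)  # decoder consumes every teacher position
  xs <- lapply(seq_len(T), function(t)
    cbind(p$emb[teacher_ids[, t] + 1L, , drop = FALSE], zc, cond))
  run <- lstm_run(p, "dec_l", cfg$decoder_rnn_layers, xs, mask, cfg$decoder_rnn_dim)
  V <- length(model$alphabet$tokens)
  logits <- array(0, c(B, T, V))
  for (t in seq_len(T))
    logits[, t, ] <- run$top[[t]] %*% p$out_W + rep(p$out_b, each = B)
  logits
}

#' VAE loss: masked reconstruction cross-entropy plus weighted KL
#'
#' Reconstruction is the mean per-token cross-entropy over non-pad target
#' positions; the KL term is the closed-form divergence of `N(mu, sigma)` from
#' the standard normal, averaged over the batch:
#' `-0.5 * sum(1 + 2*log_sigma - mu^2 - exp(2*log_sigma))`.
#'
#' @param logits array from [vae_decode_logits()].
#' @param target_ids 0-based targets aligned with the logits' step dimension.
#' @param mu,log_sigma posterior parameters.
#' @param kl_weight weight on the KL term.
#' @param pad_id 0-based pad id (masked out of the reconstruction).
#' @return list with `total`, `reconstruction`, `kl`, `accuracy`.
#' @export
vae_loss <- function(logits, target_ids, mu, log_sigma, kl_weight = 1.0,
                     pad_id = 0L) {
  if (!is.matrix(target_ids)) target_ids <- matrix(target_ids, nrow = 1)
  B <- dim(logits)[1]; T <- dim(logits)[2]
  stopifnot(nrow(target_ids) == B, ncol(target_ids) == T)
  n_tok <- 0; ce <- 0; n_hit <- 0
  for (t in seq_len(T)) {
    live <- which(target_ids[, t] != pad_id)
    if (length(live) == 0L) next
    lg <- logits[live, t, , drop = FALSE]
    lg <- matrix(lg, nrow = length(live))
    pr <- softmax_rows(lg)
    idx <- cbind(seq_along(live), target_ids[live, t] + 1L)
    ce <- ce - sum(log(pmax(pr[idx], 1e-12)))
    n_hit <- n_hit + sum(max.col(lg) == target_ids[live, t] + 1L)
    n_tok <- n_tok + length(live)
  }
  recon <- if (n_tok > 0) ce / n_tok else 0
  kl <- vae_loss_kl(mu, log_sigma)
  list(total = recon + kl_weight * kl, reconstruction = recon, kl = kl,
       accuracy = if (n_tok > 0) n_hit / n_tok else NA_real_)
}
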