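#' Sample molecules from a trained generator
#'
#' Draws latent codes from the standard normal prior, conditions them through
#' the FPC network at the requested property value, and decodes token by
#' token: multinomial sampling from the temperature-scaled softmax, or greedy
#' argmax at `temperature = 0`. Decoding stops at the end token or at the
#' configured maximum length. Returned strings are raw (validity is judged
#' downstream). Reproducible under `seed`.
#'
#' @param model a trained `vae_fpc` model (or a checkpoint path).
#' @param n number of molecules to sample.
#' @param condition condition-property value (QED) supplied to the FPC
#'   network and the decoder context.
#' @param temperature softmax temperature; 0 = greedy.
#' @param seed optional RNG seed.
#' @param batch_size decoding batch size.
#' @return character vector of `n` raw SMILES strings.
#' @export
vae_sample <- function(model, n, condition = 0.9, temperature = 1.0,
                       seed = NULL, batch_size = 64L) {
  if (is.character(model)) model <- vae_load(model)
  stopifnot(inherits(model, "vae_fpc"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- character(0)
  remaining <- n
  while (remaining > 0L) {
    b <- min(batch_size, remaining)
    out <- c(out, sample_batch(model, b, condition, temperature))
    remaining <- remaining - b
  }
  out
}

sample_batch <- function(model, b, condition, temperature) {
  cfg <- model$config; p <- model$params
  alpha <- model$alphabet
  Z <- cfg$latent_dim; Ld <- cfg$decoder_rnn_layers; H <- cfg$decoder_rnn_dim
  V <- length(alpha$tokens)
  start <- special_id(alpha, "start")
  end <- special_id(alpha, "end")

  z <- matrix(stats::rnorm(b * Z), b, Z)
  cond <- rep(condition, b)
  s <- fpc_scores(model, z, cond)
  zc <- apply_fpc(z, s, cfg$fpc_rescale)

  hs <- lapply(seq_len(Ld), function(l) matrix(0, b, H))
  cs <- lapply(seq_len(Ld), function(l) matrix(0, b, H))
  prev <- rep(start, b)
  done <- rep(FALSE, b)
  toks <- matrix(NA_integer_, b, cfg$max_len)
  for (t in seq_len(cfg$max_len)) {
    inp <- cbind(p$emb[prev + 1L, , drop = FALSE], zc, cond)
    for (l in seq_len(Ld)) {
      st <- lstm_step(inp, hs[[l]], cs[[l]],
                      p[[paste0("dec_l", l, "_W")]],
                      p[[paste0("dec_l", l, "_U")]],
                      p[[paste0("dec_l", l, "_b")]])
      hs[[l]] <- st$h; cs[[l]] <- st$c
      inp <- st$h
    }
    logits <- hs[[Ld]] %*% p$out_W + rep(p$out_b, each = b)
    if (temperature <= 0) {
      nxt <- max.col(logits) - 1L
    } else {
      pr <- softmax_rows(logits / temperature)
      nxt <- vapply(seq_len(b), function(i)
        sample.int(V, 1L, prob = pr[i, ]) - 1L, integer(1))
    }
    nxt[done] <- end
    toks[, t] <- nxt
    done <- done | nxt == end
    prev <- nxt
    if (all(done)) break
  }
  vapply(seq_len(b), function(i) {
    row <- toks[i, ]
    row <- row[!is.na(row)]
    stop_at <- which(row == end)
    if (length(stop_at) > 0L) row <- row[seq_len(stop_at[1] - 1L)]
    detokenize(row, alpha)
  }, character(1))
}
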