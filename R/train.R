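lr_at_step <- function(base_lr, step, decay_rate, decay_steps) {
  base_lr * (1 - decay_rate)^(step %/% decay_steps)
}

effective_kl_weight <- function(config, step) {
  if (config$kl_anneal_steps <= 0L) return(config$kl_weight)
  config$kl_weight * min(1, step / config$kl_anneal_steps)
}

make_batches <- function(n, batch_size) {
  idx <- seq_len(n)
  split(idx, ceiling(idx / batch_size))
}

trim_pad_cols <- function(ids, pad) {
  keep <- which(colSums(ids != pad) > 0)
  last <- max(keep, 2L)
  ids[, seq_len(last), drop = FALSE]
}

#' Train the VAE-FPC generator
#'
#' Teacher-forced training with Adam (stated betas/eps), multiplicative
#' learning-rate decay, per-step logging, and the two-part early stop:
#' training ends at `max_epochs` or as soon as the teacher-forced token
#' accuracy has exceeded `acc_threshold_delta` for `acc_window_steps`
#' consecutive steps. The condition value of each molecule is its QED unless
#' `cond` is supplied. Fully reproducible under the config seed.
#'
#' @param smiles training corpus (character vector of valid SMILES).
#' @param alphabet token alphabet; built from the corpus when `NULL`.
#' @param config a [gen_config()].
#' @param train a [train_config()].
#' @param cond optional condition values (defaults to per-molecule QED).
#' @param model optionally continue training an existing model.
#' @param step_override testing hook: a function `(step) -> accuracy` that
#'   replaces the real optimization step (used to exercise the early-stop
#'   logic against a scripted accuracy stream).
#' @param verbose print a line per epoch.
#' @return list with `model`, `log` (one row per step: epoch, step, total,
#'   reconstruction, kl, accuracy, lr) and `stopped_by`
#'   (`"accuracy"` or `"max_epochs"`).
#' @export
vae_train <- function(smiles, alphabet = NULL, config = gen_config(),
                      train = train_config(), cond = NULL, model = NULL,
                      step_override = NULL, verbose = FALSE) {
  if (length(smiles) == 0L) stop("empty corpus")
  if (is.null(alphabet)) alphabet <- build_alphabet(smiles)
  if (is.null(model)) model <- vae_init(config, alphabet, seed = train$seed)
  config <- model$config
  if (is.null(cond)) cond <- compute_qed(canonicalize_smiles(smiles))
  stopifnot(length(cond) == length(smiles))
  tm <- tokenize_matrix(smiles, alphabet)
  pad <- special_id(alphabet, "pad")
  if (length(smiles) < train$batch_size)
    warning("corpus smaller than one batch; using a single smaller batch")

  set.seed(train$seed)
  opt <- adam_init(model$params)
  step <- 0L
  hot <- 0L   # consecutive steps with accuracy above the threshold
  logs <- list()
  stopped_by <- "max_epochs"
  for (epoch in seq_len(train$max_epochs)) {
    ord <- sample(length(smiles))
    batches <- make_batches(length(smiles), train$batch_size)
    for (b in batches) {
      rows <- ord[b]
      step <- step + 1L
      lr <- lr_at_step(train$base_lr, step - 1L, train$lr_decay_rate,
                       train$lr_decay_steps)
      if (is.null(step_override)) {
        ids <- trim_pad_cols(tm$ids[rows, , drop = FALSE], pad)
        eps <- matrix(stats::rnorm(length(rows) * config$latent_dim),
                      length(rows), config$latent_dim)
        klw <- effective_kl_weight(config, step)
        fb <- vae_forward_backward(model, ids, cond[rows], eps, kl_weight = klw)
        up <- adam_update(model$params, fb$grads, opt, lr,
                          train$adam_betas, train$adam_eps)
        model$params <- up$params
        opt <- up$state
      } else {
        fb <- list(total = NA_real_, reconstruction = NA_real_, kl = NA_real_,
                   accuracy = step_override(step))
      }
      logs[[step]] <- c(epoch = epoch, step = step, total = fb$total,
                        reconstruction = fb$reconstruction, kl = fb$kl,
                        accuracy = fb$accuracy, lr = lr)
      hot <- if (!is.na(fb$accuracy) && fb$accuracy > train$acc_threshold_delta)
        hot + 1L else 0L
      if (hot >= train$acc_window_steps) {
        stopped_by <- "accuracy"
        break
      }
    }
    if (verbose) {
      tail_rows <- utils::tail(logs, length(batches))
      cat(sprintf("epoch %d  loss %.4f  acc %.3f\n", epoch,
                  mean(vapply(tail_rows, `[[`, numeric(1), "total")),
                  mean(vapply(tail_rows, `[[`, numeric(1), "accuracy"))))
    }
    if (stopped_by == "accuracy") break
  }
  list(model = model,
       log = as.data.frame(do.call(rbind, logs)),
       stopped_by = stopped_by)
}

#' Finetune with an epoch-loss plateau early stop
#'
#' One transfer-learning stage: trains on the stage corpus until the mean
#' epoch loss has failed to improve for `impatience_n` consecutive epochs
#' (or `epoch_cap` is reached), then restores the parameters of the
#' minimum-mean-loss epoch.
#'
#' @param model a trained `vae_fpc` model (modified copy returned).
#' @param smiles stage corpus.
#' @param train a [train_config()]; the learning-rate schedule restarts.
#' @param cond optional condition values (default QED).
#' @param impatience_n plateau length in epochs.
#' @param epoch_cap hard epoch limit.
#' @param epoch_loss_override testing hook: function `(epoch) -> mean loss`
#'   replacing the real epoch (no parameter updates are applied).
#' @return list with `model` (best-epoch parameters), `epoch_losses`,
#'   `best_epoch`, `stopped_by` (`"plateau"` or `"epoch_cap"`).
#' @export
vae_finetune <- function(model, smiles, train = train_config(), cond = NULL,
                         impatience_n = 5L, epoch_cap = 100L,
                         epoch_loss_override = NULL) {
  stopifnot(inherits(model, "vae_fpc"))
  real <- is.null(epoch_loss_override)
  if (real) {
    if (length(smiles) == 0L) stop("empty stage corpus")
    covered <- vapply(smiles, function(s)
      all(split_smiles(s) %in% names(model$alphabet$index_of)), logical(1))
    if (!all(covered)) {
      bad <- unique(unlist(lapply(smiles[!covered], function(s)
        setdiff(split_smiles(s), names(model$alphabet$index_of)))))
      stop("stage corpus tokens outside the model alphabet: ",
           paste(bad, collapse = " "))
    }
    if (is.null(cond)) cond <- compute_qed(canonicalize_smiles(smiles))
    tm <- tokenize_matrix(smiles, model$alphabet)
    pad <- special_id(model$alphabet, "pad")
    set.seed(train$seed)
    opt <- adam_init(model$params)
  }
  step <- 0L
  best_loss <- Inf; best_epoch <- 0L; best_params <- model$params
  since_best <- 0L
  losses <- numeric(0)
  stopped_by <- "epoch_cap"
  for (epoch in seq_len(epoch_cap)) {
    if (real) {
      ord <- sample(length(smiles))
      batches <- make_batches(length(smiles), train$batch_size)
      tot <- 0
      for (b in batches) {
        rows <- ord[b]
        step <- step + 1L
        lr <- lr_at_step(train$base_lr, step - 1L, train$lr_decay_rate,
                         train$lr_decay_steps)
        ids <- trim_pad_cols(tm$ids[rows, , drop = FALSE], pad)
        eps <- matrix(stats::rnorm(length(rows) * model$config$latent_dim),
                      length(rows), model$config$latent_dim)
        fb <- vae_forward_backward(model, ids, cond[rows], eps)
        up <- adam_update(model$params, fb$grads, opt, lr,
                          train$adam_betas, train$adam_eps)
        model$params <- up$params
        opt <- up$state
        tot <- tot + fb$total
      }
      epoch_loss <- tot / length(batches)
    } else {
      epoch_loss <- epoch_loss_override(epoch)
      if (is.null(epoch_loss)) break
    }
    losses <- c(losses, epoch_loss)
    if (epoch_loss < best_loss) {
      best_loss <- epoch_loss
      best_epoch <- epoch
      best_params <- model$params
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
    }
    if (since_best >= impatience_n) {
      stopped_by <- "plateau"
      break
    }
  }
  model$params <- best_params
  list(model = model, epoch_losses = losses, best_epoch = best_epoch,
       stopped_by = stopped_by)
}

#' Save / load a generator checkpoint
#'
#' The checkpoint holds the parameters, architecture config, alphabet and an
#' alphabet hash for compatibility checks.
#'
#' @param model a `vae_fpc` model.
#' @param path file path.
#' @export
vae_save <- function(model, path) {
  stopifnot(inherits(model, "vae_fpc"))
  obj <- list(params = model$params, config = unclass(model$config),
              alphabet = unclass(model$alphabet),
              alphabet_hash = alphabet_hash(model$alphabet),
              format_version = 1L)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname vae_save
#' @export
vae_load <- function(path) {
  obj <- readRDS(path)
  alpha <- structure(obj$alphabet, class = "token_alphabet")
  if (!identical(alphabet_hash(alpha), obj$alphabet_hash))
    stop("checkpoint alphabet hash mismatch")
  structure(list(params = obj$params,
                 config = structure(obj$config, class = "gen_config"),
                 alphabet = alpha),
            class = "vae_fpc")
}

alphabet_hash <- function(alphabet) {
  x <- paste(alphabet$tokens, collapse = "\x1f")
  h <- 7
  for (ch in utf8ToInt(x)) h <- (h * 131 + ch) %% 2147483647
  h
}
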