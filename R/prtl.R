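#' Transfer-learning configuration
#'
#' Controls partition transfer learning (PTL) and its recurrent variant
#' (PRTL): the per-stage loss-plateau patience, the recurrence cap (50, with
#' the additional stop "no novel qualifying molecules"), the sampling plan
#' (64 molecules per repetition, ten repetitions), the drug-likeness
#' qualification threshold, and how the target domain is updated between
#' recurrences (`append` unions the new qualifiers into the domain;
#' `replace` swaps the domain for them).
#'
#' @param impatience_n epochs without epoch-loss improvement before a stage
#'   stops.
#' @param max_recurrences hard PRTL recurrence cap.
#' @param samples_per_repetition,repetitions sampling plan per recurrence.
#' @param qed_threshold QED qualification bound (strictly greater).
#' @param domain_update_mode `"append"` or `"replace"`.
#' @param epoch_cap per-stage finetuning epoch limit.
#' @param sample_condition condition-property value used when sampling.
#' @param temperature sampling temperature.
#' @param activity_cutoff pIC50 cutoff for regression activity models.
#' @param seed RNG seed; per-recurrence sampling seeds are derived from it.
#' @return object of class `transfer_config`.
#' @export
transfer_config <- function(impatience_n = 5L, max_recurrences = 50L,
                            samples_per_repetition = 64L, repetitions = 10L,
                            qed_threshold = 0.6,
                            domain_update_mode = c("append", "replace"),
                            epoch_cap = 100L, sample_condition = 0.9,
                            temperature = 1.0, activity_cutoff = 5,
                            seed = 1L) {
  domain_update_mode <- match.arg(domain_update_mode)
  stopifnot(max_recurrences >= 1, repetitions >= 1, samples_per_repetition >= 1)
  structure(list(impatience_n = as.integer(impatience_n),
                 max_recurrences = as.integer(max_recurrences),
                 samples_per_repetition = as.integer(samples_per_repetition),
                 repetitions = as.integer(repetitions),
                 qed_threshold = qed_threshold,
                 domain_update_mode = domain_update_mode,
                 epoch_cap = as.integer(epoch_cap),
                 sample_condition = sample_condition,
                 temperature = temperature,
                 activity_cutoff = activity_cutoff,
                 seed = as.integer(seed)),
            class = "transfer_config")
}

derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 17
  for (x in parts) h <- (h * 2654435761 + as.numeric(x)) %% 2147483647
  as.integer(h)
}

domain_smiles <- function(domain) {
  if (is.data.frame(domain)) domain$canonical_smiles else as.character(domain)
}

#' Partition transfer learning: staged finetuning
#'
#' Finetunes a pretrained generator sequentially through the stage domains
#' (high-activity branch: C then A; low-activity branch: D then B). Each
#' stage trains until its mean epoch loss has not improved for
#' `impatience_n` consecutive epochs (or the epoch cap), then restores the
#' minimum-mean-loss parameters before the next stage.
#'
#' @param model pretrained `vae_fpc` model.
#' @param stage_domains ordered list; each element a character vector of
#'   SMILES or a records data.frame with `canonical_smiles`.
#' @param config a [transfer_config()].
#' @param train a [train_config()] for the per-stage optimizer (the learning
#'   rate is re-initialized each stage).
#' @return list with `model` and `stages` (per-stage epoch losses, best
#'   epoch, stop reason).
#' @export
ptl_finetune <- function(model, stage_domains, config = transfer_config(),
                         train = train_config()) {
  stopifnot(inherits(model, "vae_fpc"), length(stage_domains) >= 1)
  stages <- list()
  for (i in seq_along(stage_domains)) {
    smiles <- domain_smiles(stage_domains[[i]])
    if (length(smiles) == 0L) stop("stage domain ", i, " is empty")
    st <- train
    st$seed <- derive_seed(config$seed, 1000L + i)
    res <- vae_finetune(model, smiles, train = st,
                        impatience_n = config$impatience_n,
                        epoch_cap = config$epoch_cap)
    model <- res$model
    stages[[i]] <- list(epoch_losses = res$epoch_losses,
                        best_epoch = res$best_epoch,
                        stopped_by = res$stopped_by)
  }
  list(model = model, stages = stages)
}

#' Qualify generated molecules
#'
#' Applies the five qualification criteria in order, preserving input order:
#' (i) parses to a valid molecule, (ii) first occurrence of its canonical
#' form (deduplication), (iii) QED strictly above the threshold, (iv)
#' predicted active by the activity model, (v) absent from the training and
#' finetune reference sets. Without an activity model, criterion (iv) is
#' skipped with a warning.
#'
#' @param raw_samples character vector of raw sampled strings.
#' @param training_set,finetune_set canonical-SMILES reference sets.
#' @param qed_threshold QED bound.
#' @param activity_model optional [train_activity_model()] bundle.
#' @param activity_cutoff pIC50 cutoff for regression models.
#' @return data.frame with columns `raw_smiles`, `canonical_smiles`, `qed`
#'   for the qualifying novel molecules, in input order.
#' @export
qualify_generated <- function(raw_samples, training_set = character(0),
                              finetune_set = character(0), qed_threshold = 0.6,
                              activity_model = NULL, activity_cutoff = 5) {
  if (length(raw_samples) == 0L)
    return(data.frame(raw_smiles = character(0), canonical_smiles = character(0),
                      qed = numeric(0)))
  tab <- chem_table(raw_samples)
  keep <- tab$valid
  can <- tab$canonical
  keep[keep] <- !duplicated(can[keep])
  qed <- rep(NA_real_, length(raw_samples))
  if (any(keep)) {
    qed[keep] <- compute_qed(can[keep])
    keep[keep] <- qed[keep] > qed_threshold
  }
  if (any(keep)) {
    if (is.null(activity_model)) {
      warning("no activity model: qualification skips the activity criterion")
    } else {
      keep[keep] <- is_active(activity_model, can[keep], activity_cutoff)
    }
  }
  refs <- unique(c(training_set, finetune_set))
  keep[keep] <- !can[keep] %in% refs
  data.frame(raw_smiles = raw_samples[keep], canonical_smiles = can[keep],
             qed = qed[keep], stringsAsFactors = FALSE)
}

default_prtl_sampler <- function(model, config, recurrence) {
  lapply(seq_len(config$repetitions), function(rep) {
    vae_sample(model, config$samples_per_repetition,
               condition = config$sample_condition,
               temperature = config$temperature,
               seed = derive_seed(config$seed, recurrence, rep))
  })
}

#' Partition recurrent transfer learning
#'
#' The recurrent loop over PTL: finetune on the current target domain,
#' sample `samples_per_repetition x repetitions` molecules, qualify them
#' ([qualify_generated()]), and stop if none qualify as novel ("the target
#' domain does not update") or after `max_recurrences`. Otherwise the novel
#' qualifiers accumulate into the result, the target domain is updated per
#' `domain_update_mode`, and the (finetuned) parameters carry forward.
#'
#' @param model pretrained `vae_fpc` model.
#' @param initial_domain starting target domain (SMILES vector or records).
#' @param config a [transfer_config()].
#' @param activity_model optional activity model used in qualification.
#' @param training_set,finetune_set canonical-SMILES reference sets; novel
#'   molecules never intersect them.
#' @param train per-stage [train_config()].
#' @param sampler testing hook: `function(model, config, recurrence)`
#'   returning a list of repetition sample vectors (default: real sampling).
#' @param finetuner testing hook: `function(model, domain_smiles)` returning
#'   the finetuned model (default: real [vae_finetune()]).
#' @param reports compute a [evaluate_generation()] report per recurrence.
#' @return object of class `prtl_result`: `novel_molecules` (records
#'   data.frame), `recurrence_count`, `domain` (final target domain SMILES),
#'   `reports`, `model`.
#' @export
prtl_run <- function(model, initial_domain, config = transfer_config(),
                     activity_model = NULL, training_set = character(0),
                     finetune_set = character(0), train = train_config(),
                     sampler = NULL, finetuner = NULL, reports = FALSE) {
  domain <- domain_smiles(initial_domain)
  stopifnot(length(domain) > 0)
  if (is.null(sampler)) sampler <- default_prtl_sampler
  novel <- data.frame(raw_smiles = character(0), canonical_smiles = character(0),
                      qed = numeric(0))
  rep_reports <- list()
  recurrence <- 0L
  while (recurrence < config$max_recurrences) {
    recurrence <- recurrence + 1L
    if (is.null(finetuner)) {
      st <- train
      st$seed <- derive_seed(config$seed, 7000L + recurrence)
      model <- vae_finetune(model, domain, train = st,
                            impatience_n = config$impatience_n,
                            epoch_cap = config$epoch_cap)$model
    } else {
      model <- finetuner(model, domain)
    }
    samples_by_rep <- sampler(model, config, recurrence)
    qual <- qualify_generated(unlist(samples_by_rep), training_set,
                              finetune_set, config$qed_threshold,
                              activity_model, config$activity_cutoff)
    fresh <- qual[!qual$canonical_smiles %in% novel$canonical_smiles, ,
                  drop = FALSE]
    if (isTRUE(reports))
      rep_reports[[recurrence]] <- evaluate_generation(
        samples_by_rep, training_set, finetune_set, config$qed_threshold,
        activity_model, config$activity_cutoff)
    if (nrow(fresh) == 0L) break  # the target domain does not update
    novel <- rbind(novel, fresh)
    # the domain grows with the raw sampled strings: canonicalized forms can
    # introduce tokens (bracket atoms) outside the generator's alphabet
    domain <- switch(config$domain_update_mode,
                     append = unique(c(domain, fresh$raw_smiles)),
                     replace = fresh$raw_smiles)
  }
  structure(list(novel_molecules = novel, recurrence_count = recurrence,
                 domain = domain, reports = rep_reports, model = model),
            class = "prtl_result")
}

#' @export
print.prtl_result <- function(x, ...) {
  cat("prtl_result:", nrow(x$novel_molecules), "novel molecules after",
      x$recurrence_count, "recurrence(s)\n")
  invisible(x)
}
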