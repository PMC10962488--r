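#' Evaluate a sampling experiment
#'
#' Computes the generation-quality metric suite per repetition and averages
#' over repetitions:
#' * Validity = N_valid / N_sample
#' * Uniqueness = N_unique_valid / N_valid (canonical-SMILES deduplication)
#' * QEDrequest = fraction of unique-valid molecules with QED above the
#'   threshold
#' * Leadrequest = fraction of those predicted active
#' * Novelty = fraction of the active-qualified absent from the training and
#'   finetune reference sets
#' plus the count forms (NumQEDrequest, NumLead, NumNovelLead) via the
#' product identities, which equal the direct counts exactly per repetition.
#' Percentages are reported on the 0-100 scale. Degenerate denominators
#' (no valid or no unique-valid molecules) define the downstream ratio as 0
#' with a warning.
#'
#' @param samples_by_repetition list of character vectors (one per
#'   repetition) of raw sampled strings.
#' @param training_set,finetune_set canonical-SMILES reference sets.
#' @param qed_threshold drug-likeness threshold (default 0.6).
#' @param activity_model optional [train_activity_model()] bundle, or a
#'   predicate `function(smiles)` returning activity as logical/0-1; without
#'   it the lead and novelty fields are `NA` with a warning.
#' @param activity_cutoff for regression models, predicted pIC50 above this
#'   counts as active (default 5, i.e. IC50 below 10 uM).
#' @return object of class `generation_report`: `summary` (averaged metrics)
#'   and `per_repetition` (one row per repetition).
#' @export
evaluate_generation <- function(samples_by_repetition, training_set = character(0),
                                finetune_set = character(0), qed_threshold = 0.6,
                                activity_model = NULL, activity_cutoff = 5) {
  stopifnot(is.list(samples_by_repetition), length(samples_by_repetition) >= 1,
            all(lengths(samples_by_repetition) > 0))
  refs <- unique(c(training_set, finetune_set))
  have_model <- !is.null(activity_model)
  if (!have_model)
    warning("no activity model: lead and novelty metrics are NA")
  rows <- lapply(samples_by_repetition, function(samples) {
    n_sample <- length(samples)
    tab <- chem_table(samples)
    valid_can <- tab$canonical[tab$valid]
    n_valid <- length(valid_can)
    uniq <- unique(valid_can)
    n_unique <- length(uniq)
    validity <- n_valid / n_sample
    uniqueness <- ratio_or_zero(n_unique, n_valid, "no valid molecules")
    qed_ok <- if (n_unique > 0) uniq[compute_qed(uniq) > qed_threshold] else character(0)
    qed_request <- ratio_or_zero(length(qed_ok), n_unique, "no unique-valid molecules")
    if (have_model && length(qed_ok) > 0) {
      act <- is_active(activity_model, qed_ok, activity_cutoff)
      leads <- qed_ok[act]
    } else leads <- character(0)
    lead_request <- if (!have_model) NA_real_ else
      ratio_or_zero(length(leads), length(qed_ok), "no QED-qualified molecules")
    novel <- leads[!leads %in% refs]
    novelty <- if (!have_model) NA_real_ else
      ratio_or_zero(length(novel), length(leads), "no lead molecules")
    c(n_sample = n_sample,
      validity = 100 * validity,
      uniqueness = 100 * uniqueness,
      qed_request = 100 * qed_request,
      num_qed_request = n_sample * validity * uniqueness * qed_request,
      lead_request = 100 * lead_request,
      num_lead = n_sample * validity * uniqueness * qed_request * lead_request,
      novelty = 100 * novelty,
      num_novel_lead = n_sample * validity * uniqueness * qed_request *
        lead_request * novelty)
  })
  per_rep <- as.data.frame(do.call(rbind, rows))
  structure(list(summary = colMeans(per_rep),
                 per_repetition = per_rep,
                 repetitions = length(samples_by_repetition),
                 qed_threshold = qed_threshold),
            class = "generation_report")
}

ratio_or_zero <- function(num, den, why) {
  if (den == 0) {
    warning("degenerate denominator (", why, "); ratio defined as 0")
    0
  } else num / den
}

# An activity model is either a train_activity_model() bundle or a plain
# predicate function(smiles) -> logical/0-1 (useful for plugging in external
# predictors).
is_active <- function(activity_model, smiles, activity_cutoff) {
  if (is.function(activity_model)) return(as.logical(activity_model(smiles)))
  p <- predict_activity(activity_model, smiles)
  if (activity_model$fit$task == "classify") p == 1 else p > activity_cutoff
}

#' @export
print.generation_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("generation report (%d repetitions of %d samples)\n",
                     "  validity    %6.2f%%\n  uniqueness  %6.2f%%\n",
                     "  QED>%.1f     %6.2f%%  (n=%.1f)\n",
                     "  lead        %6.2f%%  (n=%.1f)\n",
                     "  novelty     %6.2f%%  (n=%.1f)\n"),
              x$repetitions, s["n_sample"], s["validity"], s["uniqueness"],
              x$qed_threshold, s["qed_request"], s["num_qed_request"],
              s["lead_request"], s["num_lead"], s["novelty"],
              s["num_novel_lead"]))
  invisible(x)
}

#' Embed molecules in a 2-D chemical space
#'
#' t-SNE on Morgan radius-2 2048-bit fingerprints with a fixed seed. The
#' embedding is deterministic given the input order and seed.
#'
#' @param smiles character vector of valid SMILES (at least 5).
#' @param group optional group labels carried through to the output.
#' @param seed RNG seed.
#' @param perplexity t-SNE perplexity; must satisfy `3 * perplexity < n - 1`.
#' @param max_iter optimization iterations.
#' @return data.frame with columns `smiles`, `group`, `x`, `y`.
#' @export
embed_chemical_space <- function(smiles, group = NULL, seed = 1L,
                                 perplexity = 30, max_iter = 500L) {
  n <- length(smiles)
  if (n < 5L) stop("need at least 5 records")
  if (3 * perplexity >= n - 1)
    stop("perplexity too large for ", n, " records; use perplexity < ",
         floor((n - 1) / 3))
  fp <- compute_fingerprint(smiles, fingerprint_spec("morgan2048"))
  coords <- tsne_exact(fp, seed = seed, perplexity = perplexity,
                       max_iter = max_iter)
  data.frame(smiles = smiles,
             group = if (is.null(group)) rep("all", n) else group,
             x = coords[, 1], y = coords[, 2], stringsAsFactors = FALSE)
}
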