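#' Novelty filter against local reference sets
#'
#' Splits candidates into novel and known by exact canonical-SMILES match
#' against the supplied reference sets (a local surrogate for a registry
#' lookup: novelty here means "absent from every reference set you provided",
#' not absence from the global literature). Order is preserved in both
#' partitions.
#'
#' @param candidates character vector of valid SMILES.
#' @param reference_sets list of character vectors (raw or canonical SMILES;
#'   canonicalized internally).
#' @return list with `novel` and `known` character vectors (original
#'   spellings, partitioning the input).
#' @export
novelty_filter <- function(candidates, reference_sets = list()) {
  can <- canonicalize_smiles(candidates)
  if (anyNA(can)) stop("invalid candidate(s): ",
                       paste(utils::head(candidates[is.na(can)], 5), collapse = ", "))
  refs <- unique(unlist(lapply(reference_sets, function(r) {
    rc <- canonicalize_smiles(as.character(r))
    rc[!is.na(rc)]
  })))
  known <- can %in% refs
  list(novel = candidates[!known], known = candidates[known])
}

#' Rank screening candidates
#'
#' Stable deterministic ordering: descending predicted activity (pIC50) or
#' ascending docking score. Ties are broken by canonical-SMILES
#' lexicographic order.
#'
#' @param candidates character vector of valid SMILES.
#' @param scores named or positional numeric scores, one per candidate.
#' @param mode `"activity_desc"` (higher is better) or `"docking_asc"`
#'   (lower, i.e. more negative, is better).
#' @return data.frame with columns `rank`, `smiles`, `score`.
#' @export
rank_candidates <- function(candidates, scores,
                            mode = c("activity_desc", "docking_asc")) {
  mode <- match.arg(mode)
  if (!is.null(names(scores))) scores <- scores[candidates]
  if (length(scores) != length(candidates) || anyNA(scores))
    stop("missing score for candidate(s): ",
         paste(utils::head(candidates[is.na(scores)], 5), collapse = ", "))
  can <- canonicalize_smiles(candidates)
  key <- if (mode == "activity_desc") -scores else scores
  ord <- order(key, can, method = "radix")
  data.frame(rank = seq_along(candidates), smiles = candidates[ord],
             score = unname(scores[ord]), stringsAsFactors = FALSE)
}

#' Pick synthesis candidates by SA score within rank windows
#'
#' Within each window of the ranked list (default Top 10 and Top 11-20),
#' returns the candidate with the lowest synthetic-accessibility score, ties
#' broken by canonical-SMILES order. Windows beyond the list length are
#' truncated (empty windows are skipped) with a warning.
#'
#' @param ranked data.frame from [rank_candidates()] (or any data.frame with
#'   `rank` and `smiles`).
#' @param windows list of rank intervals.
#' @param frag_scores optional SA fragment table passed to [sa_score()].
#' @return data.frame with one row per non-empty window: `window`, `rank`,
#'   `smiles`, `sa_score`.
#' @export
pick_by_sa <- function(ranked, windows = list(c(1L, 10L), c(11L, 20L)),
                       frag_scores = NULL) {
  stopifnot(is.data.frame(ranked), all(c("rank", "smiles") %in% names(ranked)))
  n <- nrow(ranked)
  out <- list()
  for (w in windows) {
    lo <- w[1]; hi <- min(w[2], n)
    if (lo > n) {
      warning("window [", w[1], ",", w[2], "] empty after truncation; skipped")
      next
    }
    if (hi < w[2]) warning("window [", w[1], ",", w[2], "] truncated to [",
                           lo, ",", hi, "]")
    sub <- ranked[ranked$rank >= lo & ranked$rank <= hi, , drop = FALSE]
    sa <- sa_score(sub$smiles, frag_scores = frag_scores)
    can <- canonicalize_smiles(sub$smiles)
    best <- order(sa, can, method = "radix")[1]
    out[[length(out) + 1L]] <- data.frame(
      window = paste0("[", lo, ",", hi, "]"), rank = sub$rank[best],
      smiles = sub$smiles[best], sa_score = sa[best],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Full screening pass
#'
#' Novelty-filter the candidates, rank the novel ones, and pick one
#' synthesis candidate per SA window — the order used throughout:
#' novelty first, then ranking.
#'
#' @param candidates character vector of valid SMILES.
#' @param scores numeric scores (predicted pIC50 or docking scores).
#' @param mode ranking direction, see [rank_candidates()].
#' @param reference_sets novelty reference sets.
#' @param windows SA pick windows.
#' @param frag_scores optional SA fragment table.
#' @return list with `ranked` (novel candidates with rank, score, qed,
#'   sa_score) and `picks` (one row per window).
#' @export
screen_candidates <- function(candidates, scores,
                              mode = c("activity_desc", "docking_asc"),
                              reference_sets = list(),
                              windows = list(c(1L, 10L), c(11L, 20L)),
                              frag_scores = NULL) {
  mode <- match.arg(mode)
  if (!is.null(names(scores))) scores <- scores[candidates]
  nf <- novelty_filter(candidates, reference_sets)
  keep <- candidates %in% nf$novel
  ranked <- rank_candidates(candidates[keep], scores[keep], mode)
  ranked$qed <- compute_qed(ranked$smiles)
  ranked$sa_score <- sa_score(ranked$smiles, frag_scores = frag_scores)
  list(ranked = ranked,
       picks = pick_by_sa(ranked, windows, frag_scores = frag_scores))
}
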