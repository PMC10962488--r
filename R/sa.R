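# Synthetic-accessibility scoring: fragment contribution plus complexity
# penalty, mapped to [1, 10] (lower = easier to synthesize). The fragment
# contribution follows the standard recipe — log-frequency scores of
# atom-centred circular (Morgan radius-2) fragments in a reference corpus —
# but the contributions here are calibrated on a corpus supplied by the user
# (by default a synthetic fragment-grammar corpus generated in code), not on
# the published table derived from a commercial compound registry. Scores are
# therefore internally consistent and deterministic, and preserve the
# easy-vs-hard ordering, while absolute values differ from the published
# calibration.

.sa_env <- new.env(parent = emptyenv())

mol_fragment_ids <- function(graph, radius = 2L) {
  n <- length(graph$z)
  ids <- vapply(seq_len(n), function(a) {
    hash_ints(c(graph$z[a], graph$deg[a], graph$bond_sum[a], graph$charge[a],
                graph$n_h[a], as.integer(graph$in_ring[a])))
  }, numeric(1))
  all_ids <- ids
  if (nrow(graph$edges) > 0L && radius > 0L) {
    nbrs <- vector("list", n)
    for (j in seq_len(nrow(graph$edges))) {
      a <- graph$edges[j, 1L]; b <- graph$edges[j, 2L]; o <- graph$edges[j, 3L]
      nbrs[[a]] <- rbind(nbrs[[a]], c(b, o))
      nbrs[[b]] <- rbind(nbrs[[b]], c(a, o))
    }
    for (r in seq_len(radius)) {
      ids <- vapply(seq_len(n), function(a) {
        nb <- nbrs[[a]]
        if (is.null(nb)) return(hash_ints(c(r, ids[a])))
        pairs <- cbind(nb[, 2L], ids[nb[, 1L]])
        ord <- order(pairs[, 1L], pairs[, 2L])
        hash_ints(c(r, ids[a], t(pairs[ord, , drop = FALSE])))
      }, numeric(1))
      all_ids <- c(all_ids, ids)
    }
  }
  as.character(all_ids)
}

#' Build a fragment-contribution table from a reference corpus
#'
#' Counts Morgan radius-2 fragment occurrences over the corpus and scores
#' each fragment by its log10 frequency centred on the corpus median, so
#' common (easy) fragments score positive and rare ones negative. Fragments
#' never seen in the corpus score -4.
#'
#' @param corpus_smiles reference corpus (valid SMILES).
#' @return named numeric vector of fragment scores (class
#'   `sa_fragment_scores`).
#' @export
sa_fragment_scores <- function(corpus_smiles) {
  graphs <- mol_graphs(canonicalize_smiles(corpus_smiles))
  counts <- new.env(parent = emptyenv())
  for (g in graphs) {
    if (is.null(g)) next
    for (id in mol_fragment_ids(g))
      assign(id, (if (exists(id, envir = counts)) get(id, envir = counts) else 0) + 1,
             envir = counts)
  }
  ids <- ls(counts)
  cnt <- vapply(ids, function(i) get(i, envir = counts), numeric(1))
  scores <- log10(cnt) - log10(stats::median(cnt))
  structure(setNames(pmin(pmax(scores, -4), 4), ids),
            class = "sa_fragment_scores")
}

default_sa_table <- function() {
  if (!exists("table", envir = .sa_env)) {
    # grammar corpus plus elementary aliphatic series, so that the simplest
    # environments (short alkanes, alcohols, amines, ethers) are represented
    simple <- c(vapply(1:10, function(k) strrep("C", k + 1), character(1)),
                paste0(strrep("C", 1:8), "O"),
                paste0(strrep("C", 1:8), "N"),
                paste0("CCOC", strrep("C", 1:4)))
    corpus <- c(generate_smiles_corpus(1500, seed = 90210L), rep(simple, 10))
    assign("table", sa_fragment_scores(corpus), envir = .sa_env)
  }
  get("table", envir = .sa_env)
}

#' Synthetic-accessibility score
#'
#' Fragment contribution (mean score of the molecule's circular fragments
#' under the reference table) minus a complexity penalty (size, ring
#' complexity via atoms on multiple ring bonds, and stereocentre terms),
#' linearly mapped to `[1, 10]`; lower means easier to synthesize.
#' Deterministic per molecule and invariant to the SMILES spelling.
#'
#' @param smiles character vector of valid SMILES.
#' @param frag_scores a [sa_fragment_scores()] table; the packaged default is
#'   calibrated on a synthetic fragment-grammar corpus built in code.
#' @return numeric vector of scores in `[1, 10]`.
#' @export
sa_score <- function(smiles, frag_scores = NULL) {
  if (is.null(frag_scores)) frag_scores <- default_sa_table()
  can <- canonicalize_smiles(smiles)
  if (anyNA(can)) stop("invalid molecule(s): ",
                       paste(utils::head(smiles[is.na(can)], 5), collapse = ", "))
  graphs <- mol_graphs(can)
  vapply(seq_along(graphs), function(i) {
    g <- graphs[[i]]
    if (is.null(g)) stop("failed to parse molecule: ", smiles[i])
    ids <- mol_fragment_ids(g)
    sc <- frag_scores[ids]
    sc[is.na(sc)] <- -4
    frag_term <- mean(sc)
    n <- length(g$z)
    size_penalty <- n^1.005 - n
    ring_bond_deg <- tabulate(c(g$edges[ring_edges(n, g$edges), 1:2]), nbins = n)
    n_bridge <- sum(ring_bond_deg >= 3)
    ring_penalty <- log10(n_bridge + 1)
    stereo_penalty <- log10(sum(grepl("@", split_smiles(can[i]), fixed = TRUE)) + 1)
    raw <- frag_term - size_penalty - ring_penalty - stereo_penalty
    # map raw range [-4, 2.5] onto [10, 1]
    s <- 11 - (raw + 4) / 6.5 * 9
    min(max(s, 1), 10)
  }, numeric(1))
}
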