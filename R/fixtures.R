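# Deterministic synthetic-data generation. Molecules are composed from a
# fragment grammar rather than by random string mutation: every fragment is a
# self-contained SMILES piece whose first and last atoms can accept one more
# single bond, so plain concatenation always yields a parseable, valence-legal
# molecule built from C/N/O/F/S/Cl/Br. This guarantees that fixture corpora
# pass the corpus filter by construction.

FRAG_STARTS <- c("c1ccccc1", "c1ccncc1", "c1ccc(C)cc1", "C1CCCCC1", "c1ccsc1",
                 "c1ccoc1", "CC(C)", "CCO", "CCC")
FRAG_MIDDLES <- c("CC", "CCC", "CCO", "CCN", "COC", "CC(C)", "CC(=O)N",
                  "CC(=O)O", "CN(C)", "c1ccccc1", "c1ccncc1", "CCS")
FRAG_TERMINALS <- c("C", "O", "N", "F", "Cl", "Br", "C#N", "C(F)(F)F",
                    "CO", "CN", "C(=O)O", "C(=O)N", "")

frag_heavy <- function(frag) {
  if (!nzchar(frag)) return(0L)
  toks <- split_smiles(frag)
  sum(toupper(toks) %in% c("C", "N", "O", "F", "S", "CL", "BR"))
}

#' Generate a deterministic SMILES corpus from the fragment grammar
#'
#' @param n number of molecules.
#' @param seed RNG seed; the same seed reproduces the same corpus.
#' @param criteria a [filter_criteria()]; generated molecules satisfy it by
#'   construction (element palette, heavy-atom range, string length).
#' @param max_middle maximum number of middle fragments per molecule.
#' @param required_fragment optional fragment that every molecule must
#'   contain (used to build marker sub-domains for transfer experiments).
#' @param unique_only drop duplicate structures while possible; if `n`
#'   exceeds the number of distinct structures the grammar can reach within
#'   the attempt budget, duplicates are kept with a warning.
#' @return character vector of `n` SMILES.
#' @export
generate_smiles_corpus <- function(n, seed = 1L, criteria = filter_criteria(),
                                   max_middle = 3L, required_fragment = NULL,
                                   unique_only = TRUE) {
  stopifnot(n >= 1)
  if (!all(c(6L, 7L, 8L, 9L, 16L, 17L, 35L) %in% criteria$allowed_atomic_numbers))
    stop("criteria exclude elements of the fragment grammar palette")
  set.seed(seed)
  out <- character(0)
  attempts <- 0L
  max_attempts <- 60L * n
  while (length(out) < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    k <- sample.int(max_middle + 1L, 1L) - 1L
    frags <- c(sample(FRAG_STARTS, 1L),
               if (k > 0L) sample(FRAG_MIDDLES, k, replace = TRUE),
               sample(FRAG_TERMINALS, 1L))
    if (!is.null(required_fragment) && !required_fragment %in% frags) {
      pos <- if (required_fragment %in% FRAG_STARTS) 1L else
        sample.int(length(frags) - 1L, 1L) + 1L
      if (pos == length(frags) && !required_fragment %in% FRAG_TERMINALS)
        pos <- pos - 1L
      if (pos == 1L && !required_fragment %in% FRAG_STARTS) pos <- 2L
      frags[pos] <- required_fragment
    }
    smi <- renumber_rings(frags)
    heavy <- sum(vapply(frags, frag_heavy, integer(1)))
    if (heavy < criteria$heavy_atom_range[1] ||
        heavy > criteria$heavy_atom_range[2]) next
    if (nchar(smi) > criteria$max_smiles_length) next
    if (unique_only && smi %in% out) next
    out <- c(out, smi)
  }
  if (length(out) < n) {
    warning("grammar capacity reached; filling with duplicates")
    extra <- sample(out, n - length(out), replace = TRUE)
    out <- c(out, extra)
  }
  out
}

# Give each fragment its own ring-closure digits so concatenated fragments
# cannot collide (fragments use digits 1-2; occurrence i is offset mod 1..9).
renumber_rings <- function(frags) {
  used <- 0L
  pieces <- vapply(frags, function(f) {
    if (!grepl("[0-9]", f)) return(f)
    digs <- unique(regmatches(f, gregexpr("[0-9]", f))[[1]])
    g <- f
    for (d in digs) {
      used <<- used + 1L
      g <- gsub(d, as.character(((used - 1L) %% 9L) + 1L), g, fixed = TRUE)
    }
    g
  }, character(1))
  paste(pieces, collapse = "")
}

#' Default structure-activity rule for simulated datasets
#'
#' pIC50 is a base value plus weighted counts of marker substructures
#' (SMARTS) plus Gaussian noise. The defaults reward aromatic nitrogen,
#' fluorine and aromatic sulfur, spreading simulated potency across the
#' high/low-activity boundary of the sub-domain partition.
#'
#' @param base intercept on the pIC50 scale.
#' @param weights named numeric vector: SMARTS pattern -> pIC50 contribution
#'   per match.
#' @return list with `base` and `weights`.
#' @export
activity_rule <- function(base = 5.2,
                          weights = c("[n]" = 0.9, "F" = 0.7, "[s]" = 0.6)) {
  stopifnot(is.numeric(base), length(weights) >= 1, !is.null(names(weights)))
  list(base = base, weights = weights)
}

#' Generate a simulated activity dataset with known signal
#'
#' Draws a fragment-grammar corpus, then assigns
#' `pIC50 = base + sum(w_f * count(substructure_f)) + Normal(0, noise_sigma)`;
#' IC50 (micromolar) is derived from pIC50 and the binary activity label
#' thresholds IC50 at `active_below_uM`. The generating rule is returned with
#' the data so recovery tests can score models against the truth.
#'
#' @param n number of molecules (>= 20).
#' @param seed RNG seed.
#' @param noise_sigma standard deviation of the pIC50 noise.
#' @param rule_spec an [activity_rule()].
#' @param active_below_uM label threshold: active when IC50 is below this
#'   (default 10 uM, the high/low boundary of a 10 uM-capped domain).
#' @return list with `records` (a [molecule_records()] data.frame),
#'   `rule` and `counts` (the substructure count matrix used).
#' @export
generate_activity_dataset <- function(n, seed = 1L, noise_sigma = 0.3,
                                      rule_spec = activity_rule(),
                                      active_below_uM = 10) {
  stopifnot(n >= 20)
  smiles <- generate_smiles_corpus(n, seed = seed)
  set.seed(seed + 104729L)
  refs <- ob_mol_refs(smiles)
  counts <- vapply(names(rule_spec$weights), function(s)
    ob_smarts_count(refs, s), integer(length(smiles)))
  counts <- matrix(counts, nrow = length(smiles),
                   dimnames = list(NULL, names(rule_spec$weights)))
  pic50 <- rule_spec$base + as.vector(counts %*% rule_spec$weights) +
    stats::rnorm(n, 0, noise_sigma)
  ic50 <- pic50_to_ic50(pic50)
  rec <- molecule_records(smiles, ic50 = ic50, pic50 = pic50,
                          active_label = as.integer(ic50 < active_below_uM))
  list(records = rec, rule = rule_spec, counts = counts)
}
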