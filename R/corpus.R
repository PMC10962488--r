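#' Corpus filter criteria
#'
#' Rules a SMILES corpus must satisfy before pretraining: parseable, raw string
#' length capped, heavy-atom count in a closed range, all atomic numbers drawn
#' from an allowed set, and not a member of an exclusion set (the active
#' molecules held out of the pretraining corpus).
#'
#' @param max_smiles_length maximum raw SMILES string length (characters).
#' @param heavy_atom_range integer pair, closed interval for heavy-atom count.
#' @param allowed_atomic_numbers integer set of permitted atomic numbers;
#'   0 permits wildcard/dummy atoms.
#' @param exclude_set character vector of canonical SMILES to drop.
#' @param allow_dummy_atoms logical; drop 0 from the allowed set when `FALSE`.
#' @return object of class `filter_criteria`.
#' @export
filter_criteria <- function(max_smiles_length = 120L,
                            heavy_atom_range = c(5L, 70L),
                            allowed_atomic_numbers = c(0L, 6L, 7L, 8L, 9L, 16L, 17L, 35L),
                            exclude_set = character(0),
                            allow_dummy_atoms = TRUE) {
  stopifnot(max_smiles_length > 0,
            length(heavy_atom_range) == 2L,
            heavy_atom_range[1] <= heavy_atom_range[2])
  if (!allow_dummy_atoms) allowed_atomic_numbers <- setdiff(allowed_atomic_numbers, 0L)
  structure(list(max_smiles_length = as.integer(max_smiles_length),
                 heavy_atom_range = as.integer(heavy_atom_range),
                 allowed_atomic_numbers = as.integer(allowed_atomic_numbers),
                 exclude_set = unique(exclude_set)),
            class = "filter_criteria")
}

#' Filter a SMILES corpus
#'
#' Applies the criteria in order (parse, raw length, heavy-atom range, allowed
#' elements, exclusion set); every dropped input is counted under the first
#' rule it fails. Unparseable strings are counted, never raised.
#'
#' @param smiles_list nonempty character vector of raw SMILES.
#' @param criteria a [filter_criteria()] object.
#' @param compute_qed logical; attach QED to the retained records.
#' @return list with `records` (data.frame: raw_smiles, canonical_smiles,
#'   n_heavy, and qed when requested) and `rejections` (named counts by rule:
#'   parse, max_smiles_length, heavy_atom_range, allowed_atomic_numbers,
#'   exclude_set).
#' @export
filter_corpus <- function(smiles_list, criteria = filter_criteria(),
                          compute_qed = FALSE) {
  if (length(smiles_list) == 0L) stop("empty SMILES list")
  stopifnot(inherits(criteria, "filter_criteria"))
  tab <- chem_table(smiles_list)
  rule <- rep(NA_character_, nrow(tab))
  rule[!tab$valid] <- "parse"
  ok <- tab$valid
  too_long <- ok & nchar(smiles_list) > criteria$max_smiles_length
  rule[too_long] <- "max_smiles_length"
  ok <- ok & !too_long
  bad_heavy <- ok & (tab$n_heavy < criteria$heavy_atom_range[1] |
                     tab$n_heavy > criteria$heavy_atom_range[2])
  rule[bad_heavy] <- "heavy_atom_range"
  ok <- ok & !bad_heavy
  bad_elem <- ok & !vapply(tab$atomic_numbers, function(z)
    all(z %in% criteria$allowed_atomic_numbers), logical(1))
  rule[bad_elem] <- "allowed_atomic_numbers"
  ok <- ok & !bad_elem
  excluded <- ok & tab$canonical %in% criteria$exclude_set
  rule[excluded] <- "exclude_set"
  ok <- ok & !excluded

  records <- data.frame(raw_smiles = smiles_list[ok],
                        canonical_smiles = tab$canonical[ok],
                        n_heavy = tab$n_heavy[ok],
                        stringsAsFactors = FALSE)
  if (compute_qed && nrow(records) > 0L)
    records$qed <- compute_qed(records$canonical_smiles)
  rules <- c("parse", "max_smiles_length", "heavy_atom_range",
             "allowed_atomic_numbers", "exclude_set")
  rejections <- vapply(rules, function(r) sum(rule == r, na.rm = TRUE), integer(1))
  list(records = records, rejections = rejections)
}

#' Build molecule records with activity annotations
#'
#' @param smiles character vector of valid SMILES.
#' @param ic50 optional IC50 values in micromolar.
#' @param pic50 optional pIC50 (= -log10 of molar IC50); derived from `ic50`
#'   when absent.
#' @param active_label optional binary activity labels.
#' @param qed optional precomputed QED; computed when `NULL`.
#' @return data.frame with columns raw_smiles, canonical_smiles, qed, ic50,
#'   pic50, active_label.
#' @export
molecule_records <- function(smiles, ic50 = NULL, pic50 = NULL,
                             active_label = NULL, qed = NULL) {
  can <- canonicalize_smiles(smiles)
  if (anyNA(can)) stop("invalid SMILES: ",
                       paste(utils::head(smiles[is.na(can)], 5), collapse = ", "))
  if (is.null(ic50)) ic50 <- rep(NA_real_, length(smiles))
  if (is.null(pic50)) pic50 <- ic50_to_pic50(ic50)
  if (is.null(active_label)) active_label <- rep(NA_integer_, length(smiles))
  if (is.null(qed)) qed <- compute_qed(can)
  data.frame(raw_smiles = smiles, canonical_smiles = can, qed = qed,
             ic50 = ic50, pic50 = pic50,
             active_label = as.integer(active_label),
             stringsAsFactors = FALSE)
}

#' Convert between IC50 (micromolar) and pIC50
#'
#' pIC50 is the negative base-10 logarithm of the molar IC50, so an IC50 of
#' 1 uM corresponds to pIC50 = 6.
#'
#' @param ic50 IC50 in micromolar.
#' @return pIC50 values.
#' @export
ic50_to_pic50 <- function(ic50) -log10(ic50 * 1e-6)

#' @rdname ic50_to_pic50
#' @param pic50 pIC50 values.
#' @export
pic50_to_ic50 <- function(pic50) 10^(-pic50) * 1e6

#' Partition thresholds for the QED-by-activity sub-domains
#'
#' The activity dataset is split on drug-likeness (QED above/below a split
#' value) and potency (IC50 strictly below, or at/above, a split value up to a
#' maximum). Defaults mirror the colorectal-cancer setting (split 1 uM, max
#' 10 uM); the Alzheimer setting uses 50/100 uM.
#'
#' @param qed_split QED boundary in (0,1).
#' @param ic50_min exclusive lower IC50 bound (uM).
#' @param ic50_split IC50 boundary between high and low activity (uM).
#' @param ic50_max inclusive upper IC50 bound (uM).
#' @return object of class `partition_thresholds`.
#' @export
partition_thresholds <- function(qed_split = 0.6, ic50_min = 0,
                                 ic50_split = 1, ic50_max = 10) {
  stopifnot(ic50_min < ic50_split, ic50_split <= ic50_max,
            qed_split > 0, qed_split < 1)
  structure(list(qed_split = qed_split, ic50_min = ic50_min,
                 ic50_split = ic50_split, ic50_max = ic50_max),
            class = "partition_thresholds")
}

#' Partition an activity dataset into the four QED-by-IC50 sub-domains
#'
#' * A: drug-like, high activity (QED > split, ic50_min < IC50 < ic50_split)
#' * B: drug-like, low activity (QED > split, ic50_split <= IC50 <= ic50_max)
#' * C: non-drug-like, high activity (QED <= split, high-activity window)
#' * D: non-drug-like, low activity (QED <= split, low-activity window)
#'
#' Records whose IC50 falls outside (ic50_min, ic50_max] are returned under
#' `out_of_range`, never silently dropped.
#'
#' @param records data.frame with `qed` and `ic50` columns (see
#'   [molecule_records()]).
#' @param thresholds a [partition_thresholds()] object.
#' @return list with elements A, B, C, D and out_of_range (data.frames).
#' @export
partition_target_domain <- function(records, thresholds = partition_thresholds()) {
  stopifnot(inherits(thresholds, "partition_thresholds"))
  if (nrow(records) == 0L) {
    e <- records
    return(list(A = e, B = e, C = e, D = e, out_of_range = e))
  }
  if (anyNA(records$qed) || anyNA(records$ic50)) {
    bad <- which(is.na(records$qed) | is.na(records$ic50))
    stop("records missing qed/ic50 at rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  t <- thresholds
  druglike <- records$qed > t$qed_split
  high <- records$ic50 > t$ic50_min & records$ic50 < t$ic50_split
  low <- records$ic50 >= t$ic50_split & records$ic50 <= t$ic50_max
  list(A = records[druglike & high, , drop = FALSE],
       B = records[druglike & low, , drop = FALSE],
       C = records[!druglike & high, , drop = FALSE],
       D = records[!druglike & low, , drop = FALSE],
       out_of_range = records[!(high | low), , drop = FALSE])
}
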