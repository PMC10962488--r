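# Fast OpenBabel molecule handles. forEachMol parses a multi-line SMILES
# source once; the returned OBMol references can then be fed repeatedly to
# prop_OB / smartsSearch_OB / fingerprint_OB without re-parsing. All callers
# must pass SMILES that already passed the validity audit.
ob_mol_refs <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) > 0L)
  src <- paste0(smiles, " m", seq_along(smiles), "\n", collapse = "")
  refs <- tryCatch(
    ChemmineOB::forEachMol("SMI", src, identity),
    error = function(e) NULL)
  if (!is.null(refs) && length(refs) == length(smiles)) return(refs)
  # fallback: per-molecule parse so one bad record cannot void the batch
  lapply(smiles, function(s) {
    tryCatch(ChemmineOB::forEachMol("SMI", paste0(s, "\n"), identity)[[1]],
             error = function(e) NULL)
  })
}

# Count unique SMARTS matches for each molecule reference; pattern failures
# (OpenBabel rejects a handful of component-level SMARTS) count as zero.
ob_smarts_count <- function(refs, smarts, unique_matches = TRUE) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::smartsSearch_OB(refs, smarts,
                                                 uniqueMatches = unique_matches)),
    error = function(e) rep(0L, length(refs)))
  if (length(out) != length(refs)) out <- rep(0L, length(refs))
  as.integer(out)
}

ob_props <- function(refs) {
  do.call(rbind, lapply(refs, function(r) {
    if (is.null(r)) {
      data.frame(cansmi = NA, MW = NA_real_, logP = NA_real_, TPSA = NA_real_,
                 HBA1 = NA_real_, HBD = NA_real_)
    } else {
      p <- ChemmineOB::prop_OB(r)
      data.frame(cansmi = p$cansmi, MW = p$MW, logP = p$logP, TPSA = p$TPSA,
                 HBA1 = p$HBA1, HBD = p$HBD)
    }
  }))
}
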