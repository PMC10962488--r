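#' @importFrom stats setNames
NULL

# Elements with two-character SMILES symbols that the tokenizer must keep whole.
TWO_CHAR_ORGANIC <- c("Cl", "Br")

# MDL ctab charge codes (old-style atom-block field) -> formal charge.
MDL_CHARGE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L, `5` = -1L,
                `6` = -2L, `7` = -3L)

# Maximum allowed valence per element for the neutral atom. Charged atoms get
# charge-shifted maxima (N+ -> 4, O- -> 1, ...). Elements absent from the table
# are not audited.
MAX_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 5, S = 6,
                 Cl = 1, Br = 1, I = 1)

#' Split a SMILES string into tokens
#'
#' Character-level tokenization, except that the two-character element symbols
#' `Cl` and `Br` are kept as single tokens so that generated strings can never
#' contain half an element symbol.
#'
#' @param smiles a single SMILES string.
#' @return character vector of tokens (empty for the empty string).
#' @examples
#' split_smiles("Brc1ccccc1")
#' @export
split_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (is.na(smiles) || nchar(smiles) == 0L) return(character(0))
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- character(n)
  k <- 0L
  i <- 1L
  while (i <= n) {
    two <- if (i < n) paste0(chars[i], chars[i + 1L]) else ""
    if (two %in% TWO_CHAR_ORGANIC) {
      k <- k + 1L; out[k] <- two; i <- i + 2L
    } else {
      k <- k + 1L; out[k] <- chars[i]; i <- i + 1L
    }
  }
  out[seq_len(k)]
}

# Cheap structural syntax audit: balanced branches and brackets, matched ring
# bond labels (digits and %nn), no whitespace. OpenBabel alone is too lenient
# (it silently repairs unbalanced branches), so this runs first.
smiles_syntax_ok <- function(smiles) {
  if (is.na(smiles) || !nzchar(smiles)) return(FALSE)
  if (grepl("[[:space:]]", smiles)) return(FALSE)
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  depth <- 0L
  in_bracket <- FALSE
  open_rings <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (in_bracket) {
      if (ch == "[") return(FALSE)
      if (ch == "]") in_bracket <- FALSE
      i <- i + 1L
      next
    }
    if (ch == "[") {
      in_bracket <- TRUE
    } else if (ch == "]") {
      return(FALSE)
    } else if (ch == "(") {
      depth <- depth + 1L
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(FALSE)
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9][0-9]$", paste0(chars[i + 1L], chars[i + 2L])))
        return(FALSE)
      lab <- paste0("%", chars[i + 1L], chars[i + 2L])
      open_rings <- toggle_ring(open_rings, lab)
      i <- i + 3L
      next
    } else if (grepl("^[0-9]$", ch)) {
      open_rings <- toggle_ring(open_rings, ch)
    }
    i <- i + 1L
  }
  depth == 0L && !in_bracket && length(open_rings) == 0L
}

toggle_ring <- function(open, lab) {
  hit <- match(lab, open)
  if (is.na(hit)) c(open, lab) else open[-hit]
}

ob_options <- function(names, args = rep("", length(names))) {
  data.frame(names = names, args = args, stringsAsFactors = FALSE)
}

# Batched OpenBabel conversion keyed by synthetic titles, so records dropped by
# the parser can be mapped back to their inputs.
ob_convert_titled <- function(smiles, to, opts = "e") {
  titles <- paste0("m", seq_along(smiles))
  src <- paste0(smiles, " ", titles, "\n", collapse = "")
  out <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", to, source = src, options = ob_options(opts))
  )
  list(titles = titles, text = out)
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to the toolkit-default canonical aromatic form,
#' stereochemistry preserved. Strings failing the syntax audit or the parser
#' come back as `NA`.
#'
#' @param smiles character vector of SMILES.
#' @return character vector, same length, `NA` where invalid.
#' @export
canonicalize_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  out <- rep(NA_character_, length(smiles))
  ok <- vapply(smiles, smiles_syntax_ok, logical(1), USE.NAMES = FALSE)
  if (!any(ok)) return(out)
  conv <- ob_convert_titled(smiles[ok], "CAN")
  lines <- strsplit(conv$text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  got <- vapply(parts, function(p) p[length(p)], character(1))
  can <- vapply(parts, function(p) p[1L], character(1))
  idx <- match(got, conv$titles)
  res <- rep(NA_character_, sum(ok))
  res[idx[!is.na(idx)]] <- can[!is.na(idx)]
  out[ok] <- res
  out
}

# Parse SMILES into an SDFset (optionally with explicit hydrogens) and return
# the set plus the index of the input each record came from.
parse_smiles_sdf <- function(smiles, add_h = FALSE) {
  opts <- if (add_h) c("e", "h") else "e"
  conv <- ob_convert_titled(smiles, "SDF", opts = opts)
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(conv$text, tf)
  sset <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(tf)),
                   error = function(e) NULL)
  if (is.null(sset) || length(sset) == 0L)
    return(list(sdf = NULL, input_index = integer(0)))
  ids <- ChemmineR::sdfid(sset)
  list(sdf = sset, input_index = match(ids, conv$titles))
}

atom_symbols <- function(sdf_mol) {
  sub("_.*$", "", rownames(ChemmineR::atomblock(sdf_mol)))
}

atom_charges <- function(sdf_mol) {
  ab <- ChemmineR::atomblock(sdf_mol)
  if (!"C6" %in% colnames(ab)) return(rep(0L, nrow(ab)))
  unname(MDL_CHARGE[as.character(ab[, "C6"])])
}

# Valence audit on a hydrogen-added molecule: the sum of explicit bond orders
# at each audited atom must not exceed the (charge-shifted) element maximum.
# Undervalence (radicals) is allowed; overvalence is the failure the SMILES
# grammar cannot express correctly.
valence_ok <- function(sdf_mol) {
  ab <- ChemmineR::atomblock(sdf_mol)
  bb <- ChemmineR::bondblock(sdf_mol)
  sym <- atom_symbols(sdf_mol)
  chg <- atom_charges(sdf_mol)
  v <- numeric(nrow(ab))
  if (is.matrix(bb) && nrow(bb) > 0L) {
    for (j in seq_len(nrow(bb))) {
      o <- bb[j, 3L]
      v[bb[j, 1L]] <- v[bb[j, 1L]] + o
      v[bb[j, 2L]] <- v[bb[j, 2L]] + o
    }
  }
  audit <- sym %in% names(MAX_VALENCE)
  if (!any(audit)) return(TRUE)
  maxv <- MAX_VALENCE[sym[audit]] + ifelse(sym[audit] %in% c("N", "O", "P", "S", "C", "B"),
                                           chg[audit], 0L)
  all(v[audit] <= maxv)
}

#' Full per-SMILES chemistry table
#'
#' One batched pass over a SMILES vector returning, per input: syntax flag,
#' validity (syntax + parse + valence audit), canonical SMILES, heavy-atom
#' count, and the set of atomic numbers present.
#'
#' @param smiles character vector.
#' @return data.frame with columns `smiles`, `valid`, `canonical`, `n_heavy`,
#'   and a list-column `atomic_numbers`.
#' @export
chem_table <- function(smiles) {
  stopifnot(is.character(smiles))
  n <- length(smiles)
  uniq <- unique(smiles)
  res <- data.frame(smiles = uniq, valid = FALSE,
                    canonical = NA_character_, n_heavy = NA_integer_,
                    stringsAsFactors = FALSE)
  res$atomic_numbers <- vector("list", length(uniq))
  syn <- vapply(uniq, smiles_syntax_ok, logical(1), USE.NAMES = FALSE)
  if (any(syn)) {
    sub <- uniq[syn]
    parsed <- parse_smiles_sdf(sub, add_h = TRUE)
    can <- canonicalize_smiles(sub)
    keep <- rep(FALSE, length(sub))
    nh <- rep(NA_integer_, length(sub))
    an <- vector("list", length(sub))
    if (!is.null(parsed$sdf)) {
      for (k in seq_along(parsed$input_index)) {
        i <- parsed$input_index[k]
        if (is.na(i) || keep[i]) next
        mol <- parsed$sdf[[k]]
        sym <- atom_symbols(mol)
        heavy <- sym[sym != "H"]
        if (!valence_ok(mol)) next
        keep[i] <- TRUE
        nh[i] <- length(heavy)
        an[[i]] <- sort(unique(unname(symbol_to_z(heavy))))
      }
    }
    keep <- keep & !is.na(can)
    w <- which(syn)
    res$valid[w] <- keep
    res$canonical[w] <- ifelse(keep, can, NA_character_)
    res$n_heavy[w] <- ifelse(keep, nh, NA_integer_)
    res$atomic_numbers[w] <- an
  }
  res[match(smiles, uniq), , drop = FALSE]
}

# Minimal symbol -> atomic number map covering the filter's allowed set plus
# common organic chemistry; unknown symbols map to NA (and thus fail the
# element filter rather than erroring).
SYMBOL_Z <- c(`*` = 0L, H = 1L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L,
              Si = 14L, P = 15L, S = 16L, Cl = 17L, Br = 35L, I = 53L,
              Se = 34L, As = 33L, Na = 11L, K = 19L, Li = 3L, Mg = 12L,
              Ca = 20L, Fe = 26L, Zn = 30L)

symbol_to_z <- function(sym) {
  z <- SYMBOL_Z[sym]
  z[is.na(z)] <- -1L
  z
}

#' Validity of SMILES strings
#'
#' A string is valid when it passes the syntax audit (balanced branches and
#' brackets, matched ring bonds), parses, and survives the valence audit.
#'
#' @param smiles character vector.
#' @return logical vector.
#' @export
is_valid_smiles <- function(smiles) {
  chem_table(smiles)$valid
}
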