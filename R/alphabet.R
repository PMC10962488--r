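SPECIAL_TOKENS <- c(pad = "<pad>", start = "<start>", end = "<end>")

#' Build a token alphabet from SMILES corpora
#'
#' Collects every token occurring in the given corpora (character-level, with
#' `Cl`/`Br` kept whole) and prepends the pad/start/end specials. Token ids are
#' 0-based; pad is always id 0.
#'
#' @param corpora a character vector of SMILES, or a list of such vectors.
#' @return object of class `token_alphabet` with fields `tokens` (ordered
#'   character vector), `index_of` (named 0-based integer map) and `specials`.
#' @export
build_alphabet <- function(corpora) {
  if (!is.list(corpora)) corpora <- list(corpora)
  if (length(corpora) == 0L || all(lengths(corpora) == 0L))
    stop("empty corpora")
  smiles <- unlist(corpora, use.names = FALSE)
  toks <- sort(unique(unlist(lapply(unique(smiles), split_smiles), use.names = FALSE)))
  tokens <- c(unname(SPECIAL_TOKENS), toks)
  structure(list(tokens = tokens,
                 index_of = setNames(seq_along(tokens) - 1L, tokens),
                 specials = SPECIAL_TOKENS),
            class = "token_alphabet")
}

#' @export
print.token_alphabet <- function(x, ...) {
  cat("token_alphabet:", length(x$tokens), "tokens (3 specials)\n")
  cat(" ", paste(setdiff(x$tokens, x$specials), collapse = " "), "\n")
  invisible(x)
}

special_id <- function(alphabet, which) {
  unname(alphabet$index_of[alphabet$specials[[which]]])
}

#' Tokenize a SMILES string to id sequences
#'
#' Frames the token sequence with start/end ids; ids are 0-based positions in
#' the alphabet. `detokenize()` is the exact inverse on alphabet-covered
#' strings (specials and padding are stripped).
#'
#' @param smiles a single SMILES string.
#' @param alphabet a [build_alphabet()] object.
#' @param pad_to optional total length to right-pad to with the pad id.
#' @return integer vector of token ids.
#' @export
tokenize <- function(smiles, alphabet, pad_to = NULL) {
  stopifnot(inherits(alphabet, "token_alphabet"))
  toks <- split_smiles(smiles)
  unknown <- setdiff(toks, names(alphabet$index_of))
  if (length(unknown) > 0L)
    stop("unknown token(s): ", paste(unique(unknown), collapse = " "))
  ids <- c(special_id(alphabet, "start"),
           unname(alphabet$index_of[toks]),
           special_id(alphabet, "end"))
  if (!is.null(pad_to)) {
    if (pad_to < length(ids)) stop("pad_to shorter than token sequence")
    ids <- c(ids, rep(special_id(alphabet, "pad"), pad_to - length(ids)))
  }
  ids
}

#' @rdname tokenize
#' @param ids integer vector of token ids.
#' @export
detokenize <- function(ids, alphabet) {
  stopifnot(inherits(alphabet, "token_alphabet"))
  toks <- alphabet$tokens[ids + 1L]
  if (anyNA(toks)) stop("id out of alphabet range")
  paste(toks[!toks %in% alphabet$specials], collapse = "")
}

# Tokenize a corpus into a padded id matrix (rows = molecules), plus the
# unpadded framed lengths. Used by the generator's training loop.
tokenize_matrix <- function(smiles, alphabet) {
  seqs <- lapply(smiles, tokenize, alphabet = alphabet)
  lens <- lengths(seqs)
  maxlen <- max(lens)
  pad <- special_id(alphabet, "pad")
  mat <- matrix(pad, nrow = length(seqs), ncol = maxlen)
  for (i in seq_along(seqs)) mat[i, seq_len(lens[i])] <- seqs[[i]]
  list(ids = mat, lengths = lens)
}

#' Write / read an alphabet as JSON
#'
#' @param alphabet a `token_alphabet`.
#' @param path file path.
#' @export
write_alphabet <- function(alphabet, path) {
  jsonlite::write_json(list(tokens = alphabet$tokens,
                            specials = as.list(alphabet$specials)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_alphabet
#' @export
read_alphabet <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(tokens = x$tokens,
                 index_of = setNames(seq_along(x$tokens) - 1L, x$tokens),
                 specials = unlist(x$specials)),
            class = "token_alphabet")
}
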