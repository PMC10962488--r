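#' Fingerprint specification
#'
#' Fixed-parameter descriptor settings used by the activity models:
#' * `rdkit_topological`: path-based fingerprint, path lengths 1-7, 1024 bits
#'   (OpenBabel FP2 backend).
#' * `ecfp4`: circular Morgan fingerprint, radius 2, 1024 bits (own
#'   implementation on the molecular graph).
#' * `avalon`: substructure-feature fingerprint folded to 1024 bits (OpenBabel
#'   FP4 SMARTS-feature backend standing in for the Avalon enumerator).
#' * `morgan2048`: Morgan radius 2, 2048 bits (used for Tanimoto similarity
#'   and chemical-space embedding).
#'
#' @param kind one of `"rdkit_topological"`, `"ecfp4"`, `"avalon"`,
#'   `"morgan2048"`.
#' @return object of class `fingerprint_spec`.
#' @export
fingerprint_spec <- function(kind = c("ecfp4", "rdkit_topological", "avalon",
                                      "morgan2048")) {
  kind <- match.arg(kind)
  n_bits <- if (kind == "morgan2048") 2048L else 1024L
  structure(list(kind = kind, n_bits = n_bits, min_path = 1L, max_path = 7L,
                 radius = 2L, use_chirality = FALSE),
            class = "fingerprint_spec")
}

# ---- molecular graph ----

# Smallest standard valence >= bond-order sum, used to infer implicit H.
IMPLICIT_VALENCE <- list(B = 3, C = 4, N = 3, O = 2, F = 1, P = c(3, 5),
                         S = c(2, 4, 6), Cl = 1, Br = 1, I = 1)

# Parse canonical SMILES into light graph structures: element symbols,
# charges, bond list with orders, heavy degree, implicit H count and ring
# membership (edges not on any cycle are bridges; ring atoms touch a
# non-bridge edge).
mol_graphs <- function(smiles) {
  parsed <- parse_smiles_sdf(smiles, add_h = FALSE)
  out <- vector("list", length(smiles))
  if (is.null(parsed$sdf)) return(out)
  for (k in seq_along(parsed$input_index)) {
    i <- parsed$input_index[k]
    if (is.na(i) || !is.null(out[[i]])) next
    mol <- parsed$sdf[[k]]
    sym <- atom_symbols(mol)
    chg <- atom_charges(mol)
    bb <- ChemmineR::bondblock(mol)
    n <- length(sym)
    if (!is.matrix(bb)) bb <- matrix(bb, ncol = length(bb))
    edges <- if (nrow(bb) > 0L) cbind(bb[, 1L], bb[, 2L], bb[, 3L]) else
      matrix(0L, 0L, 3L)
    deg <- tabulate(c(edges[, 1L], edges[, 2L]), nbins = n)
    bsum <- numeric(n)
    for (j in seq_len(nrow(edges))) {
      bsum[edges[j, 1L]] <- bsum[edges[j, 1L]] + edges[j, 3L]
      bsum[edges[j, 2L]] <- bsum[edges[j, 2L]] + edges[j, 3L]
    }
    nh <- vapply(seq_len(n), function(a) {
      allowed <- IMPLICIT_VALENCE[[sym[a]]]
      if (is.null(allowed)) return(0)
      eff <- bsum[a] - chg[a] * (sym[a] %in% c("N", "O", "P", "S"))
      fits <- allowed[allowed >= eff]
      if (length(fits) == 0L) 0 else fits[1] - eff
    }, numeric(1))
    ring_edge <- ring_edges(n, edges)
    in_ring <- rep(FALSE, n)
    if (any(ring_edge)) {
      re <- edges[ring_edge, , drop = FALSE]
      in_ring[unique(c(re[, 1L], re[, 2L]))] <- TRUE
    }
    out[[i]] <- list(z = unname(symbol_to_z(sym)), charge = chg, deg = deg,
                     bond_sum = bsum, n_h = nh, in_ring = in_ring,
                     edges = edges)
  }
  # duplicated inputs share the first parse
  for (i in seq_along(smiles)) {
    if (is.null(out[[i]])) {
      j <- match(smiles[i], smiles)
      if (j < i) out[[i]] <- out[[j]]
    }
  }
  out
}

# Edges that lie on a cycle = edges that are not bridges (iterative DFS).
ring_edges <- function(n, edges) {
  m <- nrow(edges)
  if (m == 0L) return(logical(0))
  adj <- vector("list", n)
  for (j in seq_len(m)) {
    a <- edges[j, 1L]; b <- edges[j, 2L]
    adj[[a]] <- rbind(adj[[a]], c(b, j))
    adj[[b]] <- rbind(adj[[b]], c(a, j))
  }
  disc <- rep(0L, n); low <- rep(0L, n)
  bridge <- rep(FALSE, m)
  timer <- 0L
  for (root in seq_len(n)) {
    if (disc[root] > 0L) next
    stack <- list(c(root, 0L, 1L))  # node, incoming edge, next child pointer
    while (length(stack) > 0L) {
      top <- stack[[length(stack)]]
      v <- top[1L]; pe <- top[2L]; ptr <- top[3L]
      if (ptr == 1L) { timer <- timer + 1L; disc[v] <- low[v] <- timer }
      nb <- adj[[v]]
      if (is.null(nb) || ptr > nrow(nb)) {
        stack[[length(stack)]] <- NULL
        if (length(stack) > 0L) {
          par <- stack[[length(stack)]][1L]
          low[par] <- min(low[par], low[v])
          if (low[v] > disc[par]) bridge[pe] <- TRUE
        }
        next
      }
      stack[[length(stack)]][3L] <- ptr + 1L
      u <- nb[ptr, 1L]; ej <- nb[ptr, 2L]
      if (disc[u] == 0L) {
        stack[[length(stack) + 1L]] <- c(u, ej, 1L)
      } else if (ej != pe) {
        low[v] <- min(low[v], disc[u])
      }
    }
  }
  !bridge
}

# ---- Morgan (ECFP-style) fingerprint ----

HASH_MOD <- 2147483647

hash_ints <- function(ints) {
  h <- 5381
  for (x in ints) h <- (h * 33 + (x %% HASH_MOD) + 1) %% HASH_MOD
  h
}

morgan_bits <- function(graph, radius, n_bits) {
  n <- length(graph$z)
  if (n == 0L) return(integer(0))
  ids <- vapply(seq_len(n), function(a) {
    hash_ints(c(graph$z[a], graph$deg[a], graph$bond_sum[a], graph$charge[a],
                graph$n_h[a], as.integer(graph$in_ring[a])))
  }, numeric(1))
  feats <- ids
  if (nrow(graph$edges) > 0L && radius > 0L) {
    nbrs <- vector("list", n)
    for (j in seq_len(nrow(graph$edges))) {
      a <- graph$edges[j, 1L]; b <- graph$edges[j, 2L]; o <- graph$edges[j, 3L]
      nbrs[[a]] <- rbind(nbrs[[a]], c(b, o))
      nbrs[[b]] <- rbind(nbrs[[b]], c(a, o))
    }
    for (r in seq_len(radius)) {
      new_ids <- vapply(seq_len(n), function(a) {
        nb <- nbrs[[a]]
        if (is.null(nb)) return(hash_ints(c(r, ids[a])))
        pairs <- cbind(nb[, 2L], ids[nb[, 1L]])
        ord <- order(pairs[, 1L], pairs[, 2L])
        hash_ints(c(r, ids[a], t(pairs[ord, , drop = FALSE])))
      }, numeric(1))
      ids <- new_ids
      feats <- c(feats, ids)
    }
  }
  unique(as.integer(feats %% n_bits))
}

#' Compute a molecular fingerprint
#'
#' @param smiles character vector of valid SMILES (canonicalized internally so
#'   two spellings of one molecule give identical bits).
#' @param spec a [fingerprint_spec()].
#' @return 0/1 integer matrix, one row per molecule, `n_bits` columns.
#' @export
compute_fingerprint <- function(smiles, spec = fingerprint_spec("ecfp4")) {
  stopifnot(inherits(spec, "fingerprint_spec"))
  can <- canonicalize_smiles(smiles)
  if (anyNA(can)) stop("invalid molecule(s): ",
                       paste(utils::head(smiles[is.na(can)], 5), collapse = ", "))
  if (spec$kind %in% c("ecfp4", "morgan2048")) {
    graphs <- mol_graphs(can)
    mat <- matrix(0L, length(can), spec$n_bits)
    for (i in seq_along(graphs)) {
      if (is.null(graphs[[i]])) stop("failed to parse molecule: ", smiles[i])
      mat[i, morgan_bits(graphs[[i]], spec$radius, spec$n_bits) + 1L] <- 1L
    }
  } else {
    refs <- ob_mol_refs(can)
    name <- if (spec$kind == "rdkit_topological") "FP2" else "FP4"
    raw <- ChemmineOB::fingerprint_OB(refs, name)
    if (ncol(raw) == spec$n_bits) {
      mat <- raw
    } else if (ncol(raw) > spec$n_bits) {  # fold
      mat <- raw[, seq_len(spec$n_bits), drop = FALSE]
      for (b in seq(spec$n_bits + 1L, ncol(raw)))
        mat[, ((b - 1L) %% spec$n_bits) + 1L] <-
          pmax(mat[, ((b - 1L) %% spec$n_bits) + 1L], raw[, b])
    } else {  # pad
      mat <- cbind(raw, matrix(0L, nrow(raw), spec$n_bits - ncol(raw)))
    }
    mat <- matrix(as.integer(mat), nrow(mat), ncol(mat))
  }
  rownames(mat) <- NULL
  mat
}

#' Tanimoto similarity between two molecules
#'
#' Jaccard index of the on-bit sets of the Morgan radius-2, 2048-bit
#' fingerprints. Symmetric; 1 for identical bit patterns; defined as 0 when
#' both fingerprints are empty.
#'
#' @param a,b SMILES strings (single molecules).
#' @return similarity in `[0, 1]`.
#' @export
tanimoto_similarity <- function(a, b) {
  fp <- compute_fingerprint(c(a, b), fingerprint_spec("morgan2048"))
  tanimoto_bits(fp[1L, ], fp[2L, ])
}

tanimoto_bits <- function(x, y) {
  inter <- sum(x & y)
  uni <- sum(x | y)
  if (uni == 0) 0 else inter / uni
}

#' Pairwise Tanimoto similarity matrix
#'
#' @param smiles character vector of valid SMILES.
#' @param spec fingerprint specification (default morgan2048).
#' @return symmetric similarity matrix.
#' @export
tanimoto_matrix <- function(smiles, spec = fingerprint_spec("morgan2048")) {
  fp <- compute_fingerprint(smiles, spec)
  inter <- fp %*% t(fp)
  ones <- rowSums(fp)
  uni <- outer(ones, ones, "+") - inter
  out <- ifelse(uni == 0, 0, inter / uni)
  dimnames(out) <- NULL
  out
}
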