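# Extended-connectivity (Morgan) fingerprints over heavy-atom graphs, with
# generating-environment tracking so that per-atom contribution maps can
# remove exactly the bits an atom participates in. Identifiers are produced
# by an order-independent iterative hash, so two SMILES spellings of the
# same molecule give identical bit vectors.

HASH_MOD <- 33554393  # prime < 2^25: products with 2^25-bounded factors
                      # stay below 2^50, exact in double arithmetic

MAX_DEGREE <- 6L       # neighbor lists are padded to this fixed width
PAIR_BASE <- 67108864  # 2^26: encodes (bond order, neighbor id) pairs

hash_chain <- function(v) {
  h <- 17
  for (x in v) h <- (h * 33 + (x %% HASH_MOD)) %% HASH_MOD
  h
}

# Vectorized fixed-width polynomial hash over parallel columns; exactly
# equivalent to hash_chain applied row-wise.
hash_cols <- function(cols) {
  k <- length(cols)
  pw <- numeric(k + 1L)
  pw[k + 1L] <- 1
  for (j in k:1) pw[j] <- (pw[j + 1L] * 33) %% HASH_MOD
  acc <- rep((17 * pw[1L]) %% HASH_MOD, length(cols[[1L]]))
  for (j in seq_len(k)) {
    acc <- (acc + (cols[[j]] %% HASH_MOD) * pw[j + 1L]) %% HASH_MOD
  }
  acc
}

# Neighbor update input for one atom: the (bond order, neighbor id) pairs
# encoded as order * PAIR_BASE + id, sorted ascending, left-padded with
# zeros to MAX_DEGREE. Both the batch and the detailed path hash
# c(r, own id, padded sorted pairs), so their bits are identical.
pad_pairs <- function(encoded) {
  if (length(encoded) > MAX_DEGREE) encoded <- sort(encoded)[seq_len(MAX_DEGREE)]
  c(rep(0, MAX_DEGREE - length(encoded)), sort(encoded))
}

# Initial atom invariant: element, charge, attached H, heavy degree, ring flag.
atom_invariants <- function(mol) {
  ecode <- match(mol$elem, ELEMENTS, nomatch = 0L)
  vapply(seq_len(mol$n_atoms), function(a) {
    hash_chain(c(ecode[a], mol$charge[a] + 8, mol$nH[a], mol$degree[a],
                 as.integer(mol$in_ring[a])))
  }, 0)
}

# All (identifier, radius, center, environment-atom-set) features up to the
# given radius. Detailed single-molecule path used by the similarity maps;
# bit-identical to the batch path of morgan_matrix().
morgan_features <- function(mol, radius) {
  n <- mol$n_atoms
  ids <- atom_invariants(mol)
  nbrs <- vector("list", n)          # list of (neighbor, bond order)
  b <- mol$bonds
  for (i in seq_len(nrow(b))) {
    nbrs[[b[i, 1L]]] <- rbind(nbrs[[b[i, 1L]]], c(b[i, 2L], b[i, 3L]))
    nbrs[[b[i, 2L]]] <- rbind(nbrs[[b[i, 2L]]], c(b[i, 1L], b[i, 3L]))
  }
  env <- as.list(seq_len(n))         # atoms within radius r of each center
  feats <- list()
  k <- 0L
  for (a in seq_len(n)) {
    k <- k + 1L
    feats[[k]] <- list(id = ids[a], radius = 0L, center = a, atoms = a)
  }
  if (radius > 0L) {
    for (r in seq_len(radius)) {
      new_ids <- numeric(n)
      new_env <- vector("list", n)
      for (a in seq_len(n)) {
        nb <- nbrs[[a]]
        if (is.null(nb)) {
          new_ids[a] <- hash_chain(c(r, ids[a], rep(0, MAX_DEGREE)))
          new_env[[a]] <- env[[a]]
        } else {
          enc <- nb[, 2L] * PAIR_BASE + ids[nb[, 1L]]
          new_ids[a] <- hash_chain(c(r, ids[a], pad_pairs(enc)))
          new_env[[a]] <- sort(unique(c(env[[a]],
                                        unlist(env[nb[, 1L]]))))
        }
        k <- k + 1L
        feats[[k]] <- list(id = new_ids[a], radius = r, center = a,
                           atoms = new_env[[a]])
      }
      ids <- new_ids
      env <- new_env
    }
  }
  feats
}

# Batch Morgan fingerprints: all molecules are laid out as one
# block-diagonal graph, so every radius iteration is a handful of
# vectorized operations over the concatenated atom vector.
morgan_matrix <- function(mols, radius, nbits) {
  n_mol <- length(mols)
  natoms <- vapply(mols, function(m) m$n_atoms, 0L)
  offset <- cumsum(c(0L, natoms[-n_mol]))
  N <- sum(natoms)
  mol_of <- rep.int(seq_len(n_mol), natoms)
  ecode <- unlist(lapply(mols, function(m) match(m$elem, ELEMENTS,
                                                 nomatch = 0L)))
  charge <- unlist(lapply(mols, function(m) m$charge))
  nH <- unlist(lapply(mols, function(m) m$nH))
  degree <- unlist(lapply(mols, function(m) m$degree))
  inring <- unlist(lapply(mols, function(m) as.integer(m$in_ring)))
  ids <- hash_cols(list(ecode, charge + 8, nH, degree, inring))
  # global padded neighbor table: NB (atom index, 0 = none), BO (order)
  NB <- matrix(0L, N, MAX_DEGREE)
  BO <- matrix(0L, N, MAX_DEGREE)
  slot <- integer(N)
  for (i in seq_len(n_mol)) {
    b <- mols[[i]]$bonds
    if (nrow(b) == 0L) next
    a1 <- b[, 1L] + offset[i]; a2 <- b[, 2L] + offset[i]
    for (j in seq_len(nrow(b))) {
      if (slot[a1[j]] < MAX_DEGREE) {
        slot[a1[j]] <- slot[a1[j]] + 1L
        NB[a1[j], slot[a1[j]]] <- a2[j]; BO[a1[j], slot[a1[j]]] <- b[j, 3L]
      }
      if (slot[a2[j]] < MAX_DEGREE) {
        slot[a2[j]] <- slot[a2[j]] + 1L
        NB[a2[j], slot[a2[j]]] <- a1[j]; BO[a2[j], slot[a2[j]]] <- b[j, 3L]
      }
    }
  }
  has_nb <- NB != 0L
  bits <- matrix(0L, n_mol, nbits)
  set_bits <- function(idvec) {
    bits[cbind(mol_of, as.integer(idvec %% nbits + 1))] <<- 1L
  }
  set_bits(ids)
  for (r in seq_len(radius)) {
    P <- matrix(0, N, MAX_DEGREE)
    for (s in seq_len(MAX_DEGREE)) {
      idx <- which(has_nb[, s])
      P[idx, s] <- BO[idx, s] * PAIR_BASE + ids[NB[idx, s]]
    }
    # vectorized ascending sort of the MAX_DEGREE columns (zeros first)
    for (a in seq_len(MAX_DEGREE - 1L)) {
      for (b2 in seq_len(MAX_DEGREE - a)) {
        lo <- pmin(P[, b2], P[, b2 + 1L])
        hi <- pmax(P[, b2], P[, b2 + 1L])
        P[, b2] <- lo; P[, b2 + 1L] <- hi
      }
    }
    ids <- hash_cols(c(list(rep(r, N), ids),
                       lapply(seq_len(MAX_DEGREE), function(s) P[, s])))
    set_bits(ids)
  }
  bits
}

#' Morgan (extended-connectivity) fingerprint
#'
#' ECFP-style circular fingerprint hashed to a fixed number of bits. ECFP4
#' corresponds to `radius = 2`, ECFP6 to `radius = 3`. With
#' `detail = TRUE` the generating environments behind every set bit are
#' returned, which the atom-contribution similarity maps rely on.
#'
#' @param mol a molecular graph from [parse_molecules()].
#' @param radius neighborhood radius (ECFP diameter / 2).
#' @param nbits folded length of the bit vector.
#' @param detail if `TRUE`, also return the bit/environment table.
#' @return integer 0/1 vector of length `nbits`; with `detail = TRUE`, a
#'   list with elements `bits` and `env` (data.frame of bit, radius,
#'   center and the atom set generating it).
#' @export
morgan_fingerprint <- function(mol, radius = 2L, nbits = 1024L,
                               detail = FALSE) {
  stopifnot(!is.null(mol), radius >= 0L, nbits >= 2L)
  feats <- morgan_features(mol, radius)
  bit <- vapply(feats, function(f) f$id %% nbits + 1, 0)
  fp <- integer(nbits)
  fp[bit] <- 1L
  if (!detail) return(fp)
  env <- data.frame(
    bit = as.integer(bit),
    radius = vapply(feats, function(f) f$radius, 0L),
    center = vapply(feats, function(f) f$center, 0L)
  )
  env$atoms <- lapply(feats, function(f) f$atoms)
  list(bits = fp, env = env)
}

ECFP_RADIUS <- c(ECFP4 = 2L, ECFP6 = 3L)

#' Fingerprint matrix for a set of molecules
#'
#' @param smiles character vector of valid SMILES.
#' @param type one of `"ECFP4"`, `"ECFP6"` (1024-bit Morgan) or `"MACCS"`
#'   (166 structural keys, computed by OpenBabel).
#' @param nbits folded length for the ECFP types (default 1024).
#' @return integer 0/1 matrix, one row per molecule, with column names
#'   `<type>_<bit>`.
#' @export
fingerprint_matrix <- function(smiles, type = c("ECFP4", "ECFP6", "MACCS"),
                               nbits = 1024L) {
  type <- match.arg(type)
  if (type == "MACCS") {
    m <- maccs_matrix(smiles)
  } else {
    mols <- parse_molecules(smiles)
    bad <- vapply(mols, is.null, TRUE)
    if (any(bad)) {
      stop("unparsable SMILES at position(s): ",
           paste(which(bad), collapse = ", "))
    }
    m <- morgan_matrix(mols, radius = ECFP_RADIUS[[type]], nbits = nbits)
  }
  colnames(m) <- paste0(type, "_", seq_len(ncol(m)))
  rownames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

# MACCS 166 structural keys via OpenBabel (padded output sliced to 166).
maccs_matrix <- function(smiles) {
  ok <- is_valid_smiles(smiles)
  if (any(!ok)) {
    stop("unparsable SMILES at position(s): ",
         paste(which(!ok), collapse = ", "))
  }
  mols <- ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"),
                                 identity)
  stopifnot(length(mols) == length(smiles))
  m <- ChemmineOB::fingerprint_OB(mols, "MACCS")
  m[, seq_len(166L), drop = FALSE]
}

#' Tanimoto similarity between fingerprint bit vectors
#'
#' @param a,b 0/1 integer vectors of equal length. Two all-zero vectors
#'   have similarity 0 by convention.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  num <- sum(a & b)
  den <- sum(a | b)
  if (den == 0L) return(0)
  num / den
}

# Row-wise Tanimoto of each row of `M` against each row of `Q` (both 0/1
# matrices with identical column count). Returns |M| x |Q| matrix.
tanimoto_cross <- function(M, Q) {
  M <- as.matrix(M); Q <- as.matrix(Q)
  inter <- M %*% t(Q)
  ra <- rowSums(M); rb <- rowSums(Q)
  den <- outer(ra, rb, "+") - inter
  out <- ifelse(den == 0, 0, inter / den)
  out
}

#' Nearest neighbor in a reference library by ECFP4 Tanimoto
#'
#' Exhaustive maximum-similarity search; ties are broken by the first
#' occurrence in the library.
#'
#' @param query_smiles single SMILES string.
#' @param library_smiles character vector of reference SMILES.
#' @param library_ids optional identifiers aligned with `library_smiles`.
#' @param library_fp optional precomputed ECFP4 matrix for the library.
#' @return list with `id`, `smiles`, `similarity`, `index`.
#' @export
tanimoto_nearest <- function(query_smiles, library_smiles,
                             library_ids = NULL, library_fp = NULL) {
  if (length(library_smiles) == 0L && is.null(library_fp)) {
    stop("reference library is empty")
  }
  qfp <- fingerprint_matrix(query_smiles, "ECFP4")
  if (is.null(library_fp)) {
    library_fp <- fingerprint_matrix(library_smiles, "ECFP4")
  }
  sims <- as.numeric(tanimoto_cross(library_fp, qfp))
  best <- which.max(sims)
  list(
    id = if (!is.null(library_ids)) library_ids[best] else best,
    smiles = if (length(library_smiles)) library_smiles[best] else NA_character_,
    similarity = sims[best],
    index = best
  )
}
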