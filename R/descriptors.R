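# 2D descriptor panel. The engine combines OpenBabel bulk properties,
# graph-topological indices computed on the heavy-atom graph, and SMARTS
# functional-group counts. The panel is fixed-length with stable names;
# descriptors that cannot be computed for a molecule yield NaN rather than
# dropping the row.

GROUP_SMARTS <- c(
  nCarbonyl   = "[CX3]=[OX1]",
  nAmide      = "[CX3](=[OX1])[NX3]",
  nCarboxyl   = "[CX3](=O)[OX2H1]",
  nHydroxyl   = "[OX2H]",
  nEther      = "[OD2]([#6])[#6]",
  nPrimAmine  = "[NX3;H2;!$(NC=O)]",
  nNitro      = "[$([NX3](=O)=O)]",
  nSulfonyl   = "[$([SX4](=O)(=O))]",
  nHalogen    = "[F,Cl,Br,I]",
  nArOH       = "[OX2H][c]"
)

#' Names of the 2D descriptor panel, in column order
#' @return character vector of descriptor names.
#' @export
descriptor_names_2d <- function() {
  c("MW", "logP", "TPSA", "MR", "HBA", "HBApolar", "HBD", "nF",
    "nAtoms", "nHeavy", "nBonds", "nRings", "nRingAtoms", "ringAtomFrac",
    "nRotB", "nC", "nN", "nO", "nS", "nP", "nHal", "heteroFrac",
    "sumCharge", "sumAbsCharge", "nHtotal", "meanDegree", "maxDegree",
    "nTerminal", "zagrebM1", "zagrebM2", "randic", "wiener",
    "nDouble", "nTriple", "bondOrderSum",
    names(GROUP_SMARTS))
}

graph_descriptors <- function(mol) {
  if (is.null(mol)) return(rep(NaN, 27L))
  n <- mol$n_atoms
  b <- mol$bonds
  deg <- mol$degree
  nb <- nrow(b)
  nrings <- nb - n + 1L  # cyclomatic number (graphs here are connected)
  halo <- c("F", "Cl", "Br", "I")
  hetero <- !(mol$elem %in% c("C", "H"))
  zag2 <- if (nb) sum(deg[b[, 1L]] * deg[b[, 2L]]) else 0
  randic <- if (nb) sum(1 / sqrt(deg[b[, 1L]] * deg[b[, 2L]])) else 0
  c(
    nAtoms = n + sum(mol$nH), nHeavy = n, nBonds = nb,
    nRings = max(nrings, 0L), nRingAtoms = sum(mol$in_ring),
    ringAtomFrac = if (n) sum(mol$in_ring) / n else 0,
    nRotB = rotatable_bond_count(mol),
    nC = sum(mol$elem == "C"), nN = sum(mol$elem == "N"),
    nO = sum(mol$elem == "O"), nS = sum(mol$elem == "S"),
    nP = sum(mol$elem == "P"), nHal = sum(mol$elem %in% halo),
    heteroFrac = if (n) sum(hetero) / n else 0,
    sumCharge = sum(mol$charge), sumAbsCharge = sum(abs(mol$charge)),
    nHtotal = sum(mol$nH),
    meanDegree = if (n) mean(deg) else 0, maxDegree = if (n) max(deg) else 0,
    nTerminal = sum(deg == 1L),
    zagrebM1 = sum(deg^2), zagrebM2 = zag2, randic = randic,
    wiener = wiener_index(mol),
    nDouble = if (nb) sum(b[, "order"] == 2L) else 0,
    nTriple = if (nb) sum(b[, "order"] == 3L) else 0,
    bondOrderSum = if (nb) sum(b[, "order"]) else 0
  )
}

# Sum of all-pairs shortest-path lengths on the heavy-atom graph.
wiener_index <- function(mol) {
  n <- mol$n_atoms
  if (n < 2L) return(0)
  adj <- vector("list", n)
  b <- mol$bonds
  for (i in seq_len(nrow(b))) {
    adj[[b[i, 1L]]] <- c(adj[[b[i, 1L]]], b[i, 2L])
    adj[[b[i, 2L]]] <- c(adj[[b[i, 2L]]], b[i, 1L])
  }
  total <- 0
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n); dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      a <- queue[1L]; queue <- queue[-1L]
      for (nx in adj[[a]]) if (is.na(dist[nx])) {
        dist[nx] <- dist[a] + 1L; queue <- c(queue, nx)
      }
    }
    total <- total + sum(dist[dist > 0], na.rm = TRUE)
  }
  total / 2
}

#' Compute the 2D molecular descriptor panel
#'
#' Fixed-length panel combining bulk physicochemical properties
#' (OpenBabel: MW, logP, TPSA, molar refractivity, H-bond counts),
#' graph-topological indices (ring statistics, Zagreb/Randic/Wiener
#' indices, degree statistics) and SMARTS functional-group counts. The
#' panel length and names are constant across molecules; per-descriptor
#' failures yield `NaN`, never row loss.
#'
#' @param smiles character vector of SMILES.
#' @return numeric matrix, one row per molecule, columns named by
#'   [descriptor_names_2d()]. Unparsable rows error.
#' @export
descriptors_2d <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  ok <- is_valid_smiles(smiles)
  if (any(!ok)) {
    stop("unparsable SMILES at position(s): ",
         paste(which(!ok), collapse = ", "))
  }
  props <- ob_props(smiles)
  mols <- parse_molecules(smiles)
  gmat <- t(vapply(mols, graph_descriptors, numeric(27L)))
  obmols <- ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"),
                                   identity)
  smarts <- vapply(GROUP_SMARTS, function(pat) {
    as.numeric(ChemmineOB::smartsSearch_OB(obmols, pat,
                                           uniqueMatches = TRUE))
  }, numeric(length(smiles)))
  if (length(smiles) == 1L) smarts <- matrix(smarts, nrow = 1L,
                                             dimnames = list(NULL, names(GROUP_SMARTS)))
  out <- cbind(
    MW = props$MW, logP = props$logP, TPSA = props$TPSA, MR = props$MR,
    HBA = props$HBA1, HBApolar = props$HBA2, HBD = props$HBD, nF = props$nF,
    gmat, smarts
  )
  colnames(out) <- descriptor_names_2d()
  rownames(out) <- NULL
  out
}
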