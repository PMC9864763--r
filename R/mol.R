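#' @keywords internal
"_PACKAGE"

# OpenBabel conversion options are passed as a data.frame(names, args).
ob_opts <- function(...) {
  nm <- c(...)
  if (length(nm) == 0L) return(NULL)
  data.frame(names = nm, args = rep("", length(nm)), stringsAsFactors = FALSE)
}

ob_convert <- function(input, from = "SMI", to = "CAN", opts = NULL) {
  if (is.null(opts)) {
    ChemmineOB::convertFormat(from, to, input)
  } else {
    ChemmineOB::convertFormat(from, to, input, options = opts)
  }
}

# Split a multi-molecule OB text output (one molecule per line, "smiles\ttitle")
# into a data.frame of smiles + title.
parse_smi_lines <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    smiles = trimws(vapply(parts, `[`, "", 1L)),
    title  = trimws(vapply(parts, function(p) if (length(p) > 1L) p[2L] else "", "")),
    stringsAsFactors = FALSE
  )
}

# Batch conversion of SMILES with per-row failure tracking. OpenBabel stops a
# batch at the first unparsable entry, so conversion resumes after each
# failure until all rows are accounted for. Returns a character vector
# aligned with `smiles`, NA where the row failed to parse/convert.
ob_convert_rows <- function(smiles, to = "CAN", opts = NULL) {
  n <- length(smiles)
  out <- rep(NA_character_, n)
  todo_start <- 1L
  while (todo_start <= n) {
    idx <- todo_start:n
    inp <- paste0(smiles[idx], " i", idx, collapse = "\n")
    res <- suppressWarnings(ob_convert(inp, "SMI", to, opts))
    got <- if (nzchar(res)) parse_smi_lines(res) else
      data.frame(smiles = character(), title = character())
    ids <- suppressWarnings(as.integer(sub("^i", "", got$title)))
    ok <- !is.na(ids) & nzchar(got$smiles)
    out[ids[ok]] <- got$smiles[ok]
    done_max <- if (any(ok)) max(ids[ok]) else todo_start - 1L
    if (done_max >= n) break
    # the row after the last converted one failed to parse; skip past it
    todo_start <- done_max + 2L
  }
  out
}

#' Standardize SMILES to parent canonical form
#'
#' Keeps the largest contiguous fragment (salt stripping), neutralizes
#' charges where chemically valid, and returns the canonical SMILES. The
#' operation is idempotent: the output is its own fixed point. Rows that do
#' not parse yield `NA`.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of parent canonical SMILES, `NA` for rows that
#'   failed to parse.
#' @examples
#' standardize_smiles(c("CCO", "CC(=O)[O-].[Na+]"))
#' @export
standardize_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character())
  ob_convert_rows(smiles, to = "CAN", opts = ob_opts("r", "neutralize"))
}

#' Validate SMILES strings
#'
#' @param smiles character vector.
#' @return logical vector, `TRUE` where the string parses as a molecule.
#' @export
is_valid_smiles <- function(smiles) {
  !is.na(standardize_smiles(smiles))
}

# ---- molecular graph parsing -------------------------------------------

ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe"
)

# Parse one V2000 molblock (with explicit hydrogens) into a heavy-atom
# graph. Single-molecule reference path; the batch path below is the one
# used in production and is checked against this in the tests.
parse_molblock <- function(block) {
  lines <- strsplit(block, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) return(NULL)
  counts <- lines[4L]
  na <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nb <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(na) || is.na(nb)) return(NULL)
  atom_lines <- lines[5L:(4L + na)]
  elem <- trimws(substr(atom_lines, 32L, 34L))
  chg_code <- suppressWarnings(as.integer(substr(atom_lines, 37L, 39L)))
  chg_code[is.na(chg_code)] <- 0L
  code_map <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                `5` = -1L, `6` = -2L, `7` = -3L)
  charge <- unname(code_map[as.character(chg_code)])
  charge[is.na(charge)] <- 0L
  if (nb > 0L) {
    bond_lines <- lines[(5L + na):(4L + na + nb)]
    b1 <- as.integer(substr(bond_lines, 1L, 3L))
    b2 <- as.integer(substr(bond_lines, 4L, 6L))
    bo <- as.integer(substr(bond_lines, 7L, 9L))
  } else {
    b1 <- b2 <- bo <- integer()
  }
  # "M  CHG" property lines supersede atom-block charge codes entirely
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg_lines)) {
    charge <- rep(0L, na)
    for (ln in chg_lines) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
      k <- f[1L]
      charge[f[2L * seq_len(k)]] <- f[2L * seq_len(k) + 1L]
    }
  }
  heavy <- which(elem != "H")
  remap <- integer(na); remap[heavy] <- seq_along(heavy)
  nH <- integer(length(heavy))
  keep <- logical(length(b1))
  for (i in seq_along(b1)) {
    h1 <- elem[b1[i]] == "H"; h2 <- elem[b2[i]] == "H"
    if (h1 && h2) next
    if (h1) { nH[remap[b2[i]]] <- nH[remap[b2[i]]] + 1L; next }
    if (h2) { nH[remap[b1[i]]] <- nH[remap[b1[i]]] + 1L; next }
    keep[i] <- TRUE
  }
  bonds <- cbind(a1 = remap[b1[keep]], a2 = remap[b2[keep]],
                 order = bo[keep])
  nheavy <- length(heavy)
  deg <- tabulate(c(bonds[, 1L], bonds[, 2L]), nbins = nheavy)
  ring_bond <- ring_bonds(nheavy, bonds)
  in_ring <- logical(nheavy)
  if (any(ring_bond)) {
    in_ring[unique(c(bonds[ring_bond, 1L], bonds[ring_bond, 2L]))] <- TRUE
  }
  list(
    elem = elem[heavy], charge = charge[heavy], nH = nH, degree = deg,
    in_ring = in_ring, bonds = bonds, ring_bond = ring_bond,
    n_atoms = nheavy
  )
}

# A bond lies on a ring iff its endpoints stay connected when it is removed.
ring_bonds <- function(n_atoms, bonds) {
  nb <- nrow(bonds)
  if (nb == 0L) return(logical())
  adj <- vector("list", n_atoms)
  for (i in seq_len(nb)) {
    adj[[bonds[i, 1L]]] <- c(adj[[bonds[i, 1L]]], i)
    adj[[bonds[i, 2L]]] <- c(adj[[bonds[i, 2L]]], i)
  }
  out <- logical(nb)
  for (i in seq_len(nb)) {
    src <- bonds[i, 1L]; dst <- bonds[i, 2L]
    seen <- logical(n_atoms); seen[src] <- TRUE
    queue <- src
    while (length(queue) && !seen[dst]) {
      a <- queue[1L]; queue <- queue[-1L]
      for (j in adj[[a]]) {
        if (j == i) next
        nxt <- if (bonds[j, 1L] == a) bonds[j, 2L] else bonds[j, 1L]
        if (!seen[nxt]) { seen[nxt] <- TRUE; queue <- c(queue, nxt) }
      }
    }
    out[i] <- seen[dst]
  }
  out
}

#' Parse SMILES into heavy-atom molecular graphs
#'
#' Each SMILES is first brought to its canonical form (which fixes both
#' atom order and the Kekule assignment, so different spellings of one
#' molecule give one graph), then converted through OpenBabel with explicit
#' hydrogens so hydrogen counts are exact. Returns, per molecule, the
#' heavy-atom element list, formal charges, hydrogen counts, degrees, ring
#' membership and the bond table. Unparsable rows yield `NULL`.
#'
#' @param smiles character vector of SMILES.
#' @return list of molecular graphs (or `NULL` per failed row).
#' @export
parse_molecules <- function(smiles) {
  stopifnot(is.character(smiles))
  n <- length(smiles)
  out <- vector("list", n)
  if (n == 0L) return(out)
  can <- ob_convert_rows(smiles, to = "CAN")
  keep <- which(!is.na(can))
  if (length(keep) == 0L) return(out)
  sub <- parse_molecule_graphs(can[keep])
  out[keep] <- sub
  out
}

# canonical SMILES -> graphs, batch with halt-resume like ob_convert_rows
parse_molecule_graphs <- function(smiles) {
  n <- length(smiles)
  out <- vector("list", n)
  todo_start <- 1L
  while (todo_start <= n) {
    idx <- todo_start:n
    inp <- paste0(smiles[idx], " i", idx, collapse = "\n")
    sdf <- suppressWarnings(ob_convert(inp, "SMI", "SDF", ob_opts("h")))
    parsed <- parse_sdf_batch(sdf)
    done_max <- todo_start - 1L
    for (j in seq_along(parsed$ids)) {
      id <- parsed$ids[j]
      if (is.na(id)) next
      out[[id]] <- parsed$mols[[j]]
      done_max <- max(done_max, id)
    }
    if (done_max >= n) break
    todo_start <- done_max + 2L
  }
  out
}

# Vectorized parse of a multi-molecule V2000 SDF (explicit hydrogens):
# all atom and bond lines across all molecules are sliced in one pass,
# ring bonds are found with a single bridge computation on the
# block-diagonal heavy-atom graph.
parse_sdf_batch <- function(sdf) {
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
  ends <- which(lines == "$$$$")
  if (length(ends) == 0L) return(list(ids = integer(), mols = list()))
  starts <- c(1L, ends[-length(ends)] + 1L)
  ids <- suppressWarnings(as.integer(sub("^i", "", trimws(lines[starts]))))
  counts <- lines[starts + 3L]
  na <- as.integer(substr(counts, 1L, 3L))
  nb <- as.integer(substr(counts, 4L, 6L))
  n_mol <- length(starts)
  # global atom table
  at_idx <- sequence(na, from = starts + 4L)
  atom_mol <- rep.int(seq_len(n_mol), na)
  elem <- trimws(substr(lines[at_idx], 32L, 34L))
  chg_code <- suppressWarnings(as.integer(substr(lines[at_idx], 37L, 39L)))
  chg_code[is.na(chg_code)] <- 0L
  code_map <- c(0L, 3L, 2L, 1L, 0L, -1L, -2L, -3L)
  charge <- code_map[chg_code + 1L]
  # "M  CHG" overrides (per molecule, rare)
  chg_lines <- grep("^M  CHG", lines)
  atom_off <- cumsum(c(0L, na[-n_mol]))
  if (length(chg_lines)) {
    mol_of_line <- findInterval(chg_lines, starts)
    reset <- unique(mol_of_line)
    charge[atom_mol %in% reset] <- 0L
    for (j in seq_along(chg_lines)) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "",
                                          lines[chg_lines[j]])),
                               "\\s+")[[1]])
      k <- f[1L]
      charge[atom_off[mol_of_line[j]] + f[2L * seq_len(k)]] <-
        f[2L * seq_len(k) + 1L]
    }
  }
  # global bond table (indices shifted to the global atom numbering)
  bd_idx <- sequence(nb, from = starts + 4L + na)
  bond_mol <- rep.int(seq_len(n_mol), nb)
  b1 <- as.integer(substr(lines[bd_idx], 1L, 3L)) + atom_off[bond_mol]
  b2 <- as.integer(substr(lines[bd_idx], 4L, 6L)) + atom_off[bond_mol]
  bo <- as.integer(substr(lines[bd_idx], 7L, 9L))
  # hydrogen bookkeeping, then restrict to the heavy-atom graph
  is_h <- elem == "H"
  heavy_id <- cumsum(!is_h)          # global heavy index (valid where !is_h)
  h1 <- is_h[b1]; h2 <- is_h[b2]
  nH <- tabulate(c(heavy_id[b1[h2 & !h1]], heavy_id[b2[h1 & !h2]]),
                 nbins = sum(!is_h))
  keep <- !h1 & !h2
  g1 <- heavy_id[b1[keep]]; g2 <- heavy_id[b2[keep]]; go <- bo[keep]
  gmol <- bond_mol[keep]
  n_heavy_tot <- sum(!is_h)
  degree <- tabulate(c(g1, g2), nbins = n_heavy_tot)
  ring_bond <- rep(FALSE, length(g1))
  if (length(g1)) {
    g <- igraph::make_graph(rbind(g1, g2), n = n_heavy_tot,
                            directed = FALSE)
    br <- igraph::bridges(g)
    ring_bond[-as.integer(br)] <- TRUE
    if (length(br) == 0L) ring_bond[] <- TRUE
  }
  in_ring <- rep(FALSE, n_heavy_tot)
  if (any(ring_bond)) in_ring[unique(c(g1[ring_bond], g2[ring_bond]))] <- TRUE
  # split back into per-molecule graphs
  na_heavy <- tabulate(atom_mol[!is_h], nbins = n_mol)
  hoff <- cumsum(c(0L, na_heavy[-n_mol]))
  elem_h <- elem[!is_h]; charge_h <- charge[!is_h]
  bsplit <- split(seq_along(g1), factor(gmol, levels = seq_len(n_mol)))
  mols <- vector("list", n_mol)
  for (i in seq_len(n_mol)) {
    rng <- hoff[i] + seq_len(na_heavy[i])
    bi <- bsplit[[i]]
    bonds <- cbind(a1 = g1[bi] - hoff[i], a2 = g2[bi] - hoff[i],
                   order = go[bi])
    mols[[i]] <- list(
      elem = elem_h[rng], charge = charge_h[rng], nH = nH[rng],
      degree = degree[rng], in_ring = in_ring[rng], bonds = bonds,
      ring_bond = ring_bond[bi], n_atoms = na_heavy[i]
    )
  }
  list(ids = ids, mols = mols)
}

# ---- physicochemical profiles ------------------------------------------

#' Bulk physicochemical properties
#'
#' Computes, per molecule, the property set used for decoy matching and
#' rule-of-5 filtering: molecular weight, calculated logP, hydrogen-bond
#' donors and acceptors, topological polar surface area, rotatable-bond
#' count and net formal charge.
#'
#' @param smiles character vector of valid SMILES.
#' @return data.frame with one row per molecule (`NA` rows where parsing
#'   failed): `MW`, `logP`, `HBD`, `HBA`, `TPSA`, `MR`, `rotB`, `charge`.
#' @export
physchem_profile <- function(smiles) {
  stopifnot(is.character(smiles))
  n <- length(smiles)
  out <- data.frame(MW = rep(NA_real_, n), logP = NA_real_, HBD = NA_real_,
                    HBA = NA_real_, TPSA = NA_real_, MR = NA_real_,
                    rotB = NA_real_, charge = NA_real_)
  if (n == 0L) return(out)
  ok <- is_valid_smiles(smiles)
  if (!any(ok)) return(out)
  mols <- ChemmineOB::forEachMol("SMILES",
                                 paste(smiles[ok], collapse = "\n"),
                                 identity)
  stopifnot(length(mols) == sum(ok))
  props <- ob_props(smiles[ok])
  smarts_n <- function(pat) {
    as.numeric(ChemmineOB::smartsSearch_OB(mols, pat,
                                           uniqueMatches = TRUE))
  }
  out$MW[ok] <- props$MW
  out$logP[ok] <- props$logP
  out$HBD[ok] <- props$HBD
  out$HBA[ok] <- props$HBA1
  out$TPSA[ok] <- props$TPSA
  out$MR[ok] <- props$MR
  # single acyclic bond between two non-terminal heavy atoms
  out$rotB[ok] <- smarts_n("[!D1]-!@[!D1]")
  out$charge[ok] <- smarts_n("[*+]") + 2 * smarts_n("[*+2]") -
    smarts_n("[*-]") - 2 * smarts_n("[*-2]")
  out
}

# OpenBabel bulk property table for a batch of valid SMILES. Uses the
# descriptor-append conversion path, which skips the InChI generation of
# the generic property API and is orders of magnitude faster in bulk.
OB_PROP_NAMES <- c("MW", "logP", "HBD", "HBA1", "HBA2", "TPSA", "MR", "nF")

ob_props <- function(smiles) {
  inp <- paste0(smiles, " i", seq_along(smiles), collapse = "\n")
  out <- suppressWarnings(ob_convert(
    inp, "SMI", "SMI",
    ob_opts_args("append", paste(OB_PROP_NAMES, collapse = " "))))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  stopifnot(length(lines) == length(smiles))
  title <- vapply(strsplit(lines, "\t", fixed = TRUE),
                  function(p) p[length(p)], "")
  fields <- strsplit(trimws(title), "\\s+")
  ord <- as.integer(sub("^i", "", vapply(fields, `[`, "", 1L)))
  vals <- t(vapply(fields, function(f)
    suppressWarnings(as.numeric(f[-1L])), numeric(length(OB_PROP_NAMES))))
  vals <- vals[order(ord), , drop = FALSE]
  colnames(vals) <- OB_PROP_NAMES
  as.data.frame(vals)
}

ob_opts_args <- function(names, args) {
  data.frame(names = names, args = args, stringsAsFactors = FALSE)
}

# Rotatable bond: single, acyclic, both endpoints of heavy degree >= 2.
rotatable_bond_count <- function(mol) {
  b <- mol$bonds
  if (nrow(b) == 0L) return(0)
  sum(b[, "order"] == 1L & !mol$ring_bond &
        mol$degree[b[, "a1"]] >= 2L & mol$degree[b[, "a2"]] >= 2L)
}

#' Count Lipinski rule-of-5 violations
#'
#' Violations of MW <= 500, logP <= 5, H-bond donors <= 5 and H-bond
#' acceptors <= 10.
#'
#' @param smiles character vector of SMILES.
#' @return integer vector in 0..4; errors if any SMILES fails to parse.
#' @export
lipinski_violations <- function(smiles) {
  p <- physchem_profile(smiles)
  if (anyNA(p$MW)) {
    stop("unparsable SMILES at position(s): ",
         paste(which(is.na(p$MW)), collapse = ", "))
  }
  as.integer((p$MW > 500) + (p$logP > 5) + (p$HBD > 5) + (p$HBA > 10))
}
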