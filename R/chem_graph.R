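# Internal molecular-graph layer.
#
# Molecules are handled as plain connection tables ("delmol"): a character
# vector of element symbols plus an integer bond matrix (from, to, order),
# obtained from ChemmineR/Open Babel SMILES parsing. The reaction transforms
# (amide coupling, Fmoc removal) are graph edits on this table; Open Babel is
# used again to emit canonical SMILES from the edited table. Hydrogens are
# implicit and derived from standard valences, which restricts the layer to
# neutral organic molecules (C, H, N, O, S, P, halogens) - the chemistry this
# library design uses.

DEFAULT_VALENCE <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4,
                     P = 3, S = 2, Cl = 1, Br = 1, I = 1)

smiles_syntax_ok <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles) ||
      !nzchar(smiles)) return(FALSE)
  if (grepl("[^A-Za-z0-9@+\\-\\[\\]()=#$:/\\\\%.*]", smiles)) return(FALSE)
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  for (pair in list(c("(", ")"), c("[", "]"))) {
    depth <- cumsum((chars == pair[1]) - (chars == pair[2]))
    if (any(depth < 0) || depth[length(depth)] != 0) return(FALSE)
  }
  TRUE
}

# Parse one SMILES string into a delmol. Open Babel is lenient with broken
# SMILES, so a syntax pre-check guards the common malformations.
parse_smiles <- function(smiles, what = "SMILES") {
  if (!smiles_syntax_ok(smiles)) stop("malformed ", what, ": ", sQuote(smiles))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  ab <- ChemmineR::atomblock(sdf[[1]])
  if (nrow(ab) == 0) stop("unparsable ", what, ": ", sQuote(smiles))
  atoms <- sub("_[0-9]+$", "", rownames(ab))
  unknown <- setdiff(unique(atoms), names(DEFAULT_VALENCE))
  if (length(unknown)) stop("unsupported element(s) ", paste(unknown, collapse = ", "),
                            " in ", sQuote(smiles))
  bb <- ChemmineR::bondblock(sdf[[1]])
  bonds <- if (nrow(bb) == 0) matrix(integer(), 0, 3)
           else unname(cbind(as.integer(bb[, 1]), as.integer(bb[, 2]), as.integer(bb[, 3])))
  structure(list(atoms = atoms, bonds = bonds), class = "delmol")
}

# Sum of bond orders per atom.
bond_order_sum <- function(mol) {
  n <- length(mol$atoms)
  s <- integer(n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      s[mol$bonds[k, 1]] <- s[mol$bonds[k, 1]] + mol$bonds[k, 3]
      s[mol$bonds[k, 2]] <- s[mol$bonds[k, 2]] + mol$bonds[k, 3]
    }
  }
  s
}

implicit_h <- function(mol) {
  pmax(0L, DEFAULT_VALENCE[mol$atoms] - bond_order_sum(mol))
}

heavy_degree <- function(mol) {
  n <- length(mol$atoms)
  tabulate(c(mol$bonds[, 1], mol$bonds[, 2]), nbins = n)
}

neighbours_of <- function(mol, i) {
  b <- mol$bonds
  c(b[b[, 1] == i, 2], b[b[, 2] == i, 1])
}

bond_between <- function(mol, i, j) {
  b <- mol$bonds
  which((b[, 1] == i & b[, 2] == j) | (b[, 1] == j & b[, 2] == i))
}

mol_graph <- function(mol) {
  g <- igraph::make_empty_graph(n = length(mol$atoms), directed = FALSE)
  if (nrow(mol$bonds)) g <- igraph::add_edges(g, as.vector(t(mol$bonds[, 1:2, drop = FALSE])))
  g
}

# TRUE for atoms lying on a cycle (incident to at least one non-bridge edge).
ring_atoms <- function(mol) {
  n <- length(mol$atoms)
  if (!nrow(mol$bonds)) return(logical(n))
  g <- mol_graph(mol)
  br <- igraph::bridges(g)
  in_ring <- logical(n)
  keep <- setdiff(seq_len(nrow(mol$bonds)), as.integer(br))
  in_ring[unique(c(mol$bonds[keep, 1], mol$bonds[keep, 2]))] <- TRUE
  in_ring
}

# Carboxylic acid carbons: C(=O)(OH) with a terminal hydroxyl oxygen.
# Returns a matrix with columns c_acid, o_carbonyl, o_hydroxyl.
find_carboxyl <- function(mol) {
  deg <- heavy_degree(mol)
  hits <- NULL
  for (i in which(mol$atoms == "C")) {
    nb <- neighbours_of(mol, i)
    dbl_o <- nb[mol$atoms[nb] == "O" & deg[nb] == 1 &
                  vapply(nb, function(j) mol$bonds[bond_between(mol, i, j), 3] == 2, logical(1))]
    sgl_o <- nb[mol$atoms[nb] == "O" & deg[nb] == 1 &
                  vapply(nb, function(j) mol$bonds[bond_between(mol, i, j), 3] == 1, logical(1))]
    if (length(dbl_o) >= 1 && length(sgl_o) >= 1)
      hits <- rbind(hits, c(i, dbl_o[1], sgl_o[1]))
  }
  if (is.null(hits)) hits <- matrix(integer(), 0, 3)
  colnames(hits) <- c("c_acid", "o_carbonyl", "o_hydroxyl")
  hits
}

# Free primary/secondary amine nitrogens eligible for acylation: N-H present,
# acyclic, all single bonds, not an amide/carbamate/sulfonamide nitrogen.
# Ordered alpha-amino-acid pattern first (N-C-C(=O)), then by atom index.
find_amines <- function(mol) {
  hcount <- implicit_h(mol)
  in_ring <- ring_atoms(mol)
  deg <- heavy_degree(mol)
  cand <- integer(0)
  for (i in which(mol$atoms == "N")) {
    if (hcount[i] < 1 || in_ring[i]) next
    nb <- neighbours_of(mol, i)
    orders <- vapply(nb, function(j) mol$bonds[bond_between(mol, i, j), 3], integer(1))
    if (any(orders != 1)) next
    acylated <- FALSE
    for (j in nb) {
      if (mol$atoms[j] %in% c("C", "S")) {
        jn <- setdiff(neighbours_of(mol, j), i)
        dbl <- vapply(jn, function(k)
          mol$atoms[k] == "O" && mol$bonds[bond_between(mol, j, k), 3] == 2, logical(1))
        if (any(dbl)) { acylated <- TRUE; break }
      }
    }
    if (!acylated) cand <- c(cand, i)
  }
  if (length(cand) < 2) return(cand)
  alpha <- vapply(cand, function(i) {
    nb <- neighbours_of(mol, i)
    any(vapply(nb, function(j) {
      if (mol$atoms[j] != "C") return(FALSE)
      jn <- setdiff(neighbours_of(mol, j), i)
      any(vapply(jn, function(k) {
        if (mol$atoms[k] != "C") return(FALSE)
        kn <- setdiff(neighbours_of(mol, k), j)
        any(mol$atoms[kn] == "O" &
              vapply(kn, function(m) mol$bonds[bond_between(mol, k, m), 3] == 2, logical(1)))
      }, logical(1)))
    }, logical(1)))
  }, logical(1))
  cand[order(!alpha, cand)]
}

# Fmoc carbamate matches: N-C(=O)-O-CH2-C(ring). Returns matrix with columns
# n, c_carbamate (the fluorenyl system hangs off the CH2).
find_fmoc <- function(mol) {
  deg <- heavy_degree(mol)
  hcount <- implicit_h(mol)
  in_ring <- ring_atoms(mol)
  hits <- NULL
  for (i in which(mol$atoms == "C")) {
    nb <- neighbours_of(mol, i)
    if (length(nb) != 3) next
    orders <- vapply(nb, function(j) mol$bonds[bond_between(mol, i, j), 3], integer(1))
    o_dbl <- nb[mol$atoms[nb] == "O" & orders == 2 & deg[nb] == 1]
    o_est <- nb[mol$atoms[nb] == "O" & orders == 1 & deg[nb] == 2]
    n_sgl <- nb[mol$atoms[nb] == "N" & orders == 1]
    if (!length(o_dbl) || !length(o_est) || !length(n_sgl)) next
    ch2 <- setdiff(neighbours_of(mol, o_est[1]), i)
    if (length(ch2) != 1 || mol$atoms[ch2] != "C" || hcount[ch2] != 2) next
    ring_c <- setdiff(neighbours_of(mol, ch2), o_est[1])
    if (length(ring_c) != 1 || !in_ring[ring_c]) next
    hits <- rbind(hits, c(n_sgl[1], i))
  }
  if (is.null(hits)) hits <- matrix(integer(), 0, 2)
  colnames(hits) <- c("n", "c_carbamate")
  hits
}

delete_atoms <- function(mol, idx) {
  keep <- setdiff(seq_along(mol$atoms), idx)
  map <- integer(length(mol$atoms))
  map[keep] <- seq_along(keep)
  b <- mol$bonds
  b <- b[!(b[, 1] %in% idx | b[, 2] %in% idx), , drop = FALSE]
  b[, 1] <- map[b[, 1]]; b[, 2] <- map[b[, 2]]
  structure(list(atoms = mol$atoms[keep], bonds = b), class = "delmol")
}

merge_mols <- function(a, b) {
  off <- length(a$atoms)
  bb <- b$bonds
  if (nrow(bb)) { bb[, 1] <- bb[, 1] + off; bb[, 2] <- bb[, 2] + off }
  structure(list(atoms = c(a$atoms, b$atoms), bonds = rbind(a$bonds, bb)),
            class = "delmol")
}

add_bond <- function(mol, i, j, order = 1L) {
  mol$bonds <- rbind(mol$bonds, c(as.integer(i), as.integer(j), as.integer(order)))
  mol
}

remove_bond <- function(mol, i, j) {
  k <- bond_between(mol, i, j)
  if (!length(k)) stop("no bond between atoms ", i, " and ", j)
  mol$bonds <- mol$bonds[-k, , drop = FALSE]
  mol
}

# Atom indices of the connected component containing `start`.
component_of <- function(mol, start) {
  g <- mol_graph(mol)
  comp <- igraph::components(g)$membership
  which(comp == comp[start])
}

mol_to_molblock <- function(mol) {
  n <- length(mol$atoms); m <- nrow(mol$bonds)
  header <- c("", " delforge", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m))
  atoms <- sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   mol$atoms)
  bonds <- if (m) sprintf("%3d%3d%3d  0  0  0  0",
                          mol$bonds[, 1], mol$bonds[, 2], mol$bonds[, 3]) else character(0)
  paste(c(header, atoms, bonds, "M  END", "$$$$", ""), collapse = "\n")
}

# Canonical SMILES for a delmol, via Open Babel.
mol_to_smiles <- function(mol) {
  out <- ChemmineOB::convertFormat("SDF", "CAN", mol_to_molblock(mol))
  sub("[\t\n].*$", "", out)
}

#' Canonicalise SMILES strings
#'
#' Returns the Open Babel canonical SMILES for each input, erroring on
#' malformed input. Canonical forms make structure equality a string
#' comparison.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical SMILES.
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (!smiles_syntax_ok(s)) stop("malformed SMILES: ", sQuote(s))
    out <- ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n"))
    out <- sub("[\t\n].*$", "", out)
    if (!nzchar(out)) stop("unparsable SMILES: ", sQuote(s))
    out
  }, character(1), USE.NAMES = FALSE)
}
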