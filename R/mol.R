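#' @title Molecular graph container
#' @description
#' A light molecular graph used throughout the package: atoms are rows of a
#' data frame (element, formal charge, implicit hydrogen count, atom-map
#' number, aromatic flag, abstraction-marker class/multiplicity, stereo tag)
#' and bonds are rows of a second data frame (endpoint indices and order,
#' where order 4 denotes an aromatic bond). Abstraction markers are
#' attachment-point pseudo-atoms with element \code{"*"} and an integer class
#' label (1 = HET, 2 = C(+), 3 = C(-), 4 = C-neutral); equal-class markers on
#' one core atom carry a multiplicity instead of duplicate pseudo-atoms.
#' @name mol
NULL

MARKER_HET <- 1L
MARKER_C_PLUS <- 2L
MARKER_C_MINUS <- 3L
MARKER_C_NEUTRAL <- 4L

#' Marker class labels
#'
#' Closed enumeration of abstraction-marker classes: heteroatom core (HET),
#' electrophilic carbon (C_PLUS), nucleophilic carbon (C_MINUS), and the
#' neutral carbon class used when the leaving atom's electronegativity is
#' within the threshold band around carbon.
#'
#' @return Named integer vector mapping class names to serialization labels.
#' @export
marker_classes <- function() {
  c(HET = MARKER_HET, C_PLUS = MARKER_C_PLUS,
    C_MINUS = MARKER_C_MINUS, C_NEUTRAL = MARKER_C_NEUTRAL)
}

new_atoms <- function(n = 0L) {
  data.frame(
    elem = character(n), chg = integer(n), nH = integer(n),
    map = integer(n), arom = logical(n), marker = integer(n),
    mult = integer(n), stereo = character(n), uid = rep(NA_integer_, n),
    stringsAsFactors = FALSE
  )
}

new_bonds <- function(n = 0L) {
  data.frame(a1 = integer(n), a2 = integer(n), order = integer(n))
}

new_mol <- function(atoms = new_atoms(), bonds = new_bonds()) {
  structure(list(atoms = atoms, bonds = bonds), class = "rmol")
}

is_mol <- function(x) inherits(x, "rmol")

n_atoms <- function(mol) nrow(mol$atoms)

#' Count heavy (non-pseudo) atoms
#' @param mol A molecule object.
#' @return Integer count of atoms excluding marker pseudo-atoms.
#' @export
heavy_atom_count <- function(mol) sum(mol$atoms$elem != "*")

#' @export
print.rmol <- function(x, ...) {
  cat("<mol> ", n_atoms(x), " atoms, ", nrow(x$bonds), " bonds: ",
      write_smiles(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.rmol <- function(x, ...) write_smiles(x)

# adjacency as list of integer vectors (neighbor atom indices)
mol_adjacency <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  adj
}

# order of bond between atoms i and j, or 0L if absent
bond_order_between <- function(mol, i, j) {
  hit <- (mol$bonds$a1 == i & mol$bonds$a2 == j) |
    (mol$bonds$a1 == j & mol$bonds$a2 == i)
  if (any(hit)) mol$bonds$order[which(hit)[1]] else 0L
}

mol_set_bond <- function(mol, i, j, order) {
  hit <- which((mol$bonds$a1 == i & mol$bonds$a2 == j) |
                 (mol$bonds$a1 == j & mol$bonds$a2 == i))
  if (length(hit)) {
    if (order == 0L) mol$bonds <- mol$bonds[-hit, , drop = FALSE]
    else mol$bonds$order[hit[1]] <- as.integer(order)
  } else if (order > 0L) {
    mol$bonds <- rbind(mol$bonds,
                       data.frame(a1 = as.integer(i), a2 = as.integer(j),
                                  order = as.integer(order)))
  }
  rownames(mol$bonds) <- NULL
  mol
}

mol_add_atom <- function(mol, elem, chg = 0L, nH = 0L, map = 0L,
                         arom = FALSE, marker = 0L, mult = 1L,
                         stereo = "", uid = NA_integer_) {
  mol$atoms <- rbind(mol$atoms, data.frame(
    elem = elem, chg = as.integer(chg), nH = as.integer(nH),
    map = as.integer(map), arom = arom, marker = as.integer(marker),
    mult = as.integer(mult), stereo = stereo, uid = as.integer(uid),
    stringsAsFactors = FALSE))
  rownames(mol$atoms) <- NULL
  mol
}

# Remove atoms (by index), dropping incident bonds and reindexing.
mol_delete_atoms <- function(mol, idx) {
  if (!length(idx)) return(mol)
  idx <- sort(unique(as.integer(idx)))
  keep <- setdiff(seq_len(n_atoms(mol)), idx)
  remap <- integer(n_atoms(mol))
  remap[keep] <- seq_along(keep)
  b <- mol$bonds
  b <- b[!(b$a1 %in% idx | b$a2 %in% idx), , drop = FALSE]
  b$a1 <- remap[b$a1]; b$a2 <- remap[b$a2]
  out <- new_mol(mol$atoms[keep, , drop = FALSE], b)
  rownames(out$atoms) <- NULL; rownames(out$bonds) <- NULL
  out
}

# Induced subgraph on atom indices `idx` (order preserved).
mol_subgraph <- function(mol, idx) {
  idx <- as.integer(idx)
  remap <- integer(n_atoms(mol))
  remap[idx] <- seq_along(idx)
  b <- mol$bonds
  b <- b[b$a1 %in% idx & b$a2 %in% idx, , drop = FALSE]
  b$a1 <- remap[b$a1]; b$a2 <- remap[b$a2]
  out <- new_mol(mol$atoms[idx, , drop = FALSE], b)
  rownames(out$atoms) <- NULL; rownames(out$bonds) <- NULL
  out
}

# Disjoint union; returns list(mol, offset of second fragment's indices).
mol_union <- function(a, b) {
  off <- n_atoms(a)
  atoms <- rbind(a$atoms, b$atoms)
  bb <- b$bonds
  if (nrow(bb)) { bb$a1 <- bb$a1 + off; bb$a2 <- bb$a2 + off }
  m <- new_mol(atoms, rbind(a$bonds, bb))
  rownames(m$atoms) <- NULL; rownames(m$bonds) <- NULL
  list(mol = m, offset = off)
}

# Connected components over atoms; returns integer membership vector.
mol_components <- function(mol) {
  n <- n_atoms(mol)
  comp <- integer(n)
  adj <- mol_adjacency(mol)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
    }
  }
  comp
}

# Split into a list of connected molecules (atom order preserved per part).
mol_split <- function(mol) {
  comp <- mol_components(mol)
  lapply(seq_len(max(comp, 0L)), function(k) mol_subgraph(mol, which(comp == k)))
}

# Attach fragment `frag` (its atom `fat`) to `mol` atom `at` by a bond.
mol_attach <- function(mol, at, frag, fat, order = 1L) {
  u <- mol_union(mol, frag)
  mol_set_bond(u$mol, at, fat + u$offset, order)
}

# Map numbers present on non-marker atoms.
mol_maps <- function(mol) {
  m <- mol$atoms$map[mol$atoms$elem != "*"]
  m[m > 0L]
}

# index of the atom carrying map number `m` (0 if absent)
atom_by_map <- function(mol, m) {
  i <- which(mol$atoms$map == m & mol$atoms$elem != "*")
  if (length(i)) i[1] else 0L
}
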