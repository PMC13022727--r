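#' @title Leaving-group abstraction
#' @description
#' Converts concrete molecules into synthon-like higher-level forms: every
#' maximal connected leaving substructure is removed and replaced by one
#' marker per core-attachment bond. Markers on heteroatom cores are a single
#' HET class; markers on carbon cores are classed by the Pauling
#' electronegativity of the attached leaving atom relative to carbon
#' (above the threshold: C(+), an electrophilic carbon; below: C(-), a
#' nucleophilic carbon; within the band: C-neutral). Implicit hydrogens that
#' do not survive to the route target are treated as leaving attachments so
#' that N-acylations and protecting-group chemistry abstract consistently.
#' @name abstraction
NULL

#' Pauling electronegativity table
#'
#' Electronegativities for the elements handled by the abstraction
#' heuristics. The carbon reference value is 2.55.
#'
#' @return Named numeric vector (element symbol to Pauling value).
#' @export
pauling_en <- function() {
  c(H = 2.20, Li = 0.98, Be = 1.57, B = 2.04, C = 2.55, N = 3.04, O = 3.44,
    F = 3.98, Na = 0.93, Mg = 1.31, Al = 1.61, Si = 1.90, P = 2.19, S = 2.58,
    Cl = 3.16, K = 0.82, Ca = 1.00, Ti = 1.54, Cr = 1.66, Mn = 1.55,
    Fe = 1.83, Ni = 1.91, Cu = 1.90, Zn = 1.65, As = 2.18, Se = 2.55,
    Br = 2.96, Pd = 2.20, Ag = 1.93, Cd = 1.69, Sn = 1.96, Sb = 2.05,
    Te = 2.10, I = 2.66, Pt = 2.28, Au = 2.54, Hg = 2.00, Pb = 2.33)
}

#' Classify the marker for one core-leaving attachment
#'
#' A heteroatom core always yields HET. A carbon core is classed by the
#' electronegativity difference between the attached leaving atom and
#' carbon: C(+) (electrophilic) when the leaving atom is more
#' electronegative than carbon by more than \code{threshold}, C(-)
#' (nucleophilic) when less by more than \code{threshold}, C-neutral
#' otherwise. The sign convention follows charge-affinity formalism: a
#' halide- or triflate-bearing carbon is the C(+) partner of a coupling, a
#' boron- or metal-bearing carbon the C(-) partner.
#'
#' @param core_elem Element symbol of the core (retained) atom.
#' @param leaving_elem Element symbol of the leaving atom attached to it.
#' @param table Named electronegativity vector (default \code{pauling_en()}).
#' @param threshold Electronegativity band half-width around carbon
#'   (default 0.1).
#' @return Marker class integer (see \code{\link{marker_classes}}).
#' @export
classify_marker <- function(core_elem, leaving_elem, table = pauling_en(),
                            threshold = 0.1) {
  if (core_elem != "C") return(MARKER_HET)
  if (!(leaving_elem %in% names(table)))
    stop("configuration error: element '", leaving_elem,
         "' missing from electronegativity table")
  d <- table[[leaving_elem]] - table[["C"]]
  if (d > threshold) MARKER_C_PLUS
  else if (d < -threshold) MARKER_C_MINUS
  else MARKER_C_NEUTRAL
}

# Add one marker unit of class `cls` to atom `at`, merging multiplicity with
# an existing equal-class marker pseudo-atom.
add_marker <- function(mol, at, cls) {
  adj <- mol_adjacency(mol)
  for (w in adj[[at]]) {
    if (mol$atoms$elem[w] == "*" && mol$atoms$marker[w] == cls) {
      mol$atoms$mult[w] <- mol$atoms$mult[w] + 1L
      return(mol)
    }
  }
  mol <- mol_add_atom(mol, "*", marker = cls, mult = 1L)
  mol_set_bond(mol, at, n_atoms(mol), 1L)
}

#' Abstract a molecule given its leaving atoms
#'
#' Removes every maximal connected leaving substructure and installs one
#' marker per core-attachment bond, classed by
#' \code{\link{classify_marker}}. Leaving implicit hydrogens (per-atom
#' counts in \code{leaving_h}) become marker units on their core atom and
#' are subtracted from its hydrogen count. Stereo tags on core atoms that
#' lose a leaving neighbour are dropped with a warning, since their parity
#' reference is gone. A molecule whose atoms are all leaving is a spectator:
#' \code{NULL} is returned with attribute-free semantics handled by callers.
#'
#' @param mol Molecule object.
#' @param leaving Integer vector of leaving atom indices.
#' @param leaving_h Integer vector (length = atom count) of leaving implicit
#'   hydrogen counts per atom; default none.
#' @param table,threshold Passed to \code{\link{classify_marker}}.
#' @return Abstracted molecule, or \code{NULL} for a spectator.
#' @export
abstract_molecule <- function(mol, leaving, leaving_h = NULL,
                              table = pauling_en(), threshold = 0.1) {
  leaving <- sort(unique(as.integer(leaving)))
  n <- n_atoms(mol)
  if (is.null(leaving_h)) leaving_h <- integer(n)
  core <- setdiff(which(mol$atoms$elem != "*"), leaving)
  if (!length(core)) return(NULL)
  # collect crossing bonds (core atom, leaving atom)
  cross <- list()
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    i <- b$a1[k]; j <- b$a2[k]
    if (i %in% leaving && !(j %in% leaving)) cross[[length(cross) + 1L]] <- c(j, i)
    if (j %in% leaving && !(i %in% leaving)) cross[[length(cross) + 1L]] <- c(i, j)
  }
  # markers classed before removal; record per (core atom, class)
  marks <- lapply(cross, function(cl) {
    c(core = cl[1],
      cls = classify_marker(mol$atoms$elem[cl[1]], mol$atoms$elem[cl[2]],
                            table, threshold))
  })
  # leaving hydrogens: treated as a leaving attachment of element H
  for (i in core) {
    if (leaving_h[i] > 0L) {
      cls <- classify_marker(mol$atoms$elem[i], "H", table, threshold)
      for (r in seq_len(leaving_h[i]))
        marks[[length(marks) + 1L]] <- c(core = i, cls = cls)
    }
  }
  # stereo tags referencing removed neighbours are dropped
  if (length(marks)) {
    touched <- unique(vapply(marks, function(x) x[["core"]], 0))
    dropped <- touched[nzchar(mol$atoms$stereo[touched])]
    if (length(dropped)) {
      warning("dropping stereo tag(s) on ", length(dropped),
              " atom(s) whose leaving neighbour was abstracted")
      mol$atoms$stereo[dropped] <- ""
    }
  }
  out <- mol_delete_atoms(mol, leaving)
  # reindex core positions after deletion
  remap <- integer(n)
  remap[setdiff(seq_len(n), leaving)] <- seq_len(n - length(leaving))
  for (mk in marks) out <- add_marker(out, remap[mk[["core"]]], mk[["cls"]])
  # subtract leaving hydrogens from the core atoms that carried them
  for (i in core) {
    if (leaving_h[i] > 0L) {
      j <- remap[i]
      out$atoms$nH[j] <- max(0L, out$atoms$nH[j] - leaving_h[i])
    }
  }
  out
}
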