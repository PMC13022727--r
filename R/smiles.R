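#' @title SMILES dialect: parsing, implicit hydrogens, canonical writing
#' @description
#' The package reads and writes a SMILES dialect covering the organic subset,
#' bracket atoms with isotope/stereo/H-count/charge/atom-map fields, branches,
#' ring closures (including \code{\%nn}), dot-separated fragments and aromatic
#' lower-case atoms. Abstraction markers are serialized as isotope-labelled
#' attachment pseudo-atoms: \code{[1*]} HET, \code{[2*]} C(+), \code{[3*]}
#' C(-), \code{[4*]} C-neutral; a multiplicity m > 1 is encoded as isotope
#' 10*m + class (e.g. \code{[21*]} is a doubled HET marker). This keeps
#' abstracted molecules round-trippable through standard SMILES machinery.
#' @name smiles
NULL

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

# Default valence lists used for implicit-H assignment.
DEFAULT_VALENCE <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

# sum of bond orders at each atom; aromatic bonds count 1.5, then ceiling
atom_bond_degree <- function(mol) {
  n <- n_atoms(mol)
  s <- numeric(n)
  b <- mol$bonds
  if (nrow(b)) {
    ord <- ifelse(b$order == 4L, 1.5, as.numeric(b$order))
    for (k in seq_len(nrow(b))) {
      s[b$a1[k]] <- s[b$a1[k]] + ord[k]
      s[b$a2[k]] <- s[b$a2[k]] + ord[k]
    }
  }
  as.integer(ceiling(s - 1e-9))
}

# implied implicit-H count for a bare (non-bracket) organic-subset atom
implied_h <- function(elem, arom, bonddeg) {
  vals <- DEFAULT_VALENCE[[elem]]
  if (is.null(vals)) return(0L)
  # aromatic O/S in a ring carry no implicit H
  if (arom && elem %in% c("O", "S")) return(0L)
  for (v in vals) if (bonddeg <= v) return(as.integer(v - bonddeg))
  0L
}

marker_isotope <- function(class, mult) {
  if (mult <= 1L) as.integer(class) else as.integer(10L * mult + class)
}

decode_marker_isotope <- function(iso) {
  if (iso < 10L) list(class = as.integer(iso), mult = 1L)
  else list(class = as.integer(iso %% 10L), mult = as.integer(iso %/% 10L))
}

#' Parse a SMILES string into a molecular graph
#'
#' Supports the organic subset, aromatic lower-case atoms, bracket atoms
#' (isotope, element, \code{@}/\code{@@} stereo tags, H count, charge, atom
#' map), branches, ring closures and dot-separated fragments. Marker
#' pseudo-atoms are recognised via isotope-labelled \code{*} atoms (see
#' \link{smiles}).
#'
#' @param s A SMILES string.
#' @return A molecule object.
#' @export
parse_smiles <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s))
    stop("parse error: empty or non-string SMILES input")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  atoms <- list()
  bonds <- list()
  bare <- logical(0)      # bare organic-subset atoms get implicit H later
  prev <- NA_integer_
  pending <- NA_integer_  # explicit bond order awaiting the next atom
  stack <- integer(0)
  rings <- list()         # ring-closure id -> list(atom, order)

  add_atom <- function(elem, chg = 0L, nH = 0L, map = 0L, arom = FALSE,
                       marker = 0L, mult = 1L, stereo = "", is_bare = FALSE) {
    atoms[[length(atoms) + 1L]] <<- list(
      elem = elem, chg = chg, nH = nH, map = map, arom = arom,
      marker = marker, mult = mult, stereo = stereo)
    bare[length(atoms)] <<- is_bare
    idx <- length(atoms)
    if (!is.na(prev)) {
      ord <- pending
      if (is.na(ord)) {
        ord <- if (atoms[[prev]]$arom && arom) 4L else 1L
      }
      bonds[[length(bonds) + 1L]] <<- c(prev, idx, ord)
    }
    pending <<- NA_integer_
    prev <<- idx
    invisible(idx)
  }

  close_ring <- function(id) {
    if (is.na(prev)) stop("parse error: ring bond before any atom in '", s, "'")
    key <- as.character(id)
    if (!is.null(rings[[key]])) {
      open <- rings[[key]]
      ord <- pending
      if (is.na(ord)) ord <- open$order
      if (is.na(ord)) {
        ord <- if (atoms[[open$atom]]$arom && atoms[[prev]]$arom) 4L else 1L
      }
      bonds[[length(bonds) + 1L]] <<- c(open$atom, prev, ord)
      rings[[key]] <<- NULL
    } else {
      rings[[key]] <<- list(atom = prev, order = pending)
    }
    pending <<- NA_integer_
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") { stack <- c(stack, prev); i <- i + 1L; next }
    if (ch == ")") {
      if (!length(stack)) stop("parse error: unbalanced ')' in '", s, "'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L; next
    }
    if (ch == ".") { prev <- NA_integer_; pending <- NA_integer_; i <- i + 1L; next }
    if (ch %in% c("-", "/", "\\")) { pending <- 1L; i <- i + 1L; next }
    if (ch == "=") { pending <- 2L; i <- i + 1L; next }
    if (ch == "#") { pending <- 3L; i <- i + 1L; next }
    if (ch == ":") { pending <- 4L; i <- i + 1L; next }
    if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9][0-9]$", paste0(chars[i + 1L], chars[i + 2L])))
        stop("parse error: bad %% ring closure in '", s, "'")
      close_ring(as.integer(paste0(chars[i + 1L], chars[i + 2L])))
      i <- i + 3L; next
    }
    if (grepl("^[0-9]$", ch)) { close_ring(as.integer(ch)); i <- i + 1L; next }
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("parse error: unterminated bracket atom in '", s, "'")
      body <- paste0(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]+)?([A-Z][a-z]?|[a-z]|\\*)(@@|@)?(H[0-9]*)?(\\+[0-9]+|-[0-9]+|\\++|-+)?(:[0-9]+)?$",
        body))[[1]]
      if (!length(m)) stop("parse error: bad bracket atom '[", body, "]' in '", s, "'")
      iso <- if (nzchar(m[2])) as.integer(m[2]) else 0L
      sym <- m[3]
      stereo <- m[4]
      hfield <- m[5]
      chfield <- m[6]
      mapfield <- m[7]
      nH <- if (!nzchar(hfield)) 0L
            else if (hfield == "H") 1L else as.integer(sub("H", "", hfield))
      chg <- 0L
      if (nzchar(chfield)) {
        if (grepl("^\\++$", chfield)) chg <- nchar(chfield)
        else if (grepl("^-+$", chfield)) chg <- -nchar(chfield)
        else chg <- as.integer(chfield)
      }
      map <- if (nzchar(mapfield)) as.integer(sub(":", "", mapfield)) else 0L
      if (sym == "*") {
        mk <- decode_marker_isotope(iso)
        if (!(mk$class %in% 1:4))
          stop("parse error: marker atom with unknown class isotope ", iso,
               " in '", s, "'")
        add_atom("*", chg = 0L, nH = 0L, map = 0L, arom = FALSE,
                 marker = mk$class, mult = mk$mult)
      } else {
        arom <- grepl("^[a-z]", sym)
        elem <- if (arom) paste0(toupper(substr(sym, 1, 1)), substring(sym, 2)) else sym
        add_atom(elem, chg = chg, nH = nH, map = map, arom = arom,
                 stereo = stereo)
      }
      i <- j + 1L; next
    }
    # two-character organic-subset elements
    if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r")) {
      two <- paste0(ch, chars[i + 1L])
      if (two %in% c("Cl", "Br")) {
        add_atom(two, is_bare = TRUE)
        i <- i + 2L; next
      }
    }
    if (ch %in% ORGANIC_SUBSET) { add_atom(ch, is_bare = TRUE); i <- i + 1L; next }
    if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      add_atom(toupper(ch), arom = TRUE, is_bare = TRUE)
      i <- i + 1L; next
    }
    stop("parse error: unexpected character '", ch, "' in '", s, "'")
  }
  if (length(stack)) stop("parse error: unbalanced '(' in '", s, "'")
  if (length(rings)) stop("parse error: unclosed ring bond in '", s, "'")

  at <- new_atoms(length(atoms))
  for (k in seq_along(atoms)) {
    a <- atoms[[k]]
    at$elem[k] <- a$elem; at$chg[k] <- a$chg; at$nH[k] <- a$nH
    at$map[k] <- a$map; at$arom[k] <- a$arom; at$marker[k] <- a$marker
    at$mult[k] <- a$mult; at$stereo[k] <- a$stereo
  }
  bd <- new_bonds(length(bonds))
  for (k in seq_along(bonds)) {
    bd$a1[k] <- bonds[[k]][1]; bd$a2[k] <- bonds[[k]][2]
    bd$order[k] <- bonds[[k]][3]
  }
  mol <- new_mol(at, bd)
  deg <- atom_bond_degree(mol)
  for (k in seq_len(n_atoms(mol))) {
    if (bare[k]) mol$atoms$nH[k] <- implied_h(mol$atoms$elem[k],
                                              mol$atoms$arom[k], deg[k])
  }
  mol
}

# ---- canonical ranks ------------------------------------------------------

# Canonical atom ranks via bliss canonical labeling on a colored auxiliary
# graph in which every bond is subdivided by a vertex colored by bond order.
# Atom map numbers never influence the ranks.
mol_canonical_ranks <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  a <- mol$atoms
  key <- paste(a$elem, a$chg, a$nH, a$arom, a$marker, a$mult, a$stereo,
               sep = "|")
  ucolor <- match(key, sort(unique(key)))
  nb <- nrow(mol$bonds)
  edges <- integer(0)
  colors <- c(ucolor, integer(nb))
  if (nb) {
    for (k in seq_len(nb)) {
      bv <- n + k
      edges <- c(edges, mol$bonds$a1[k], bv, bv, mol$bonds$a2[k])
      colors[bv] <- 1000L + mol$bonds$order[k]
    }
  }
  g <- igraph::make_graph(edges = edges, n = n + nb, directed = FALSE)
  lab <- igraph::canonical_permutation(g, colors = colors)$labeling
  rank(lab[seq_len(n)])
}

# ---- writer ---------------------------------------------------------------

atom_token2 <- function(elem, chg, nH, map, arom, marker, mult, stereo,
                        bonddeg, keep_maps) {
  if (elem == "*") {
    return(paste0("[", marker_isotope(marker, mult), "*]"))
  }
  if (!keep_maps) map <- 0L
  sym <- if (arom) tolower(elem) else elem
  bare_ok <- chg == 0L && map == 0L && !nzchar(stereo) &&
    elem %in% ORGANIC_SUBSET && nH == implied_h(elem, arom, bonddeg)
  if (bare_ok) return(sym)
  h <- if (nH == 0L) "" else if (nH == 1L) "H" else paste0("H", nH)
  chgs <- if (chg == 0L) ""
          else if (chg > 0L) paste0("+", if (chg > 1L) chg else "")
          else paste0("-", if (chg < -1L) -chg else "")
  mp <- if (map > 0L) paste0(":", map) else ""
  paste0("[", sym, stereo, h, chgs, mp, "]")
}

bond_token <- function(order, arom1, arom2) {
  if (order == 1L) { if (arom1 && arom2) "-" else "" }
  else if (order == 2L) "="
  else if (order == 3L) "#"
  else if (order == 4L) ""  # aromatic bond between aromatic atoms
  else stop("unknown bond order ", order)
}

#' Serialize a molecule as (canonical) SMILES
#'
#' With \code{canonical = TRUE} (default) the output is invariant to input
#' atom order: atoms are ranked by a colored canonical labeling (element,
#' charge, H count, aromaticity, marker class/multiplicity and bond orders
#' all contribute) and emitted in rank order. Disconnected fragments are
#' serialized independently and joined sorted with \code{.}.
#'
#' @param mol Molecule object.
#' @param keep_maps Keep atom-map numbers in the output (default FALSE).
#' @param canonical Use canonical atom ordering (default TRUE).
#' @return A SMILES string.
#' @export
write_smiles <- function(mol, keep_maps = FALSE, canonical = TRUE) {
  n <- n_atoms(mol)
  if (n == 0L) return("")
  ranks <- if (canonical) mol_canonical_ranks(mol) else seq_len(n)
  deg <- atom_bond_degree(mol)
  comp <- mol_components(mol)
  adj <- mol_adjacency(mol)
  # plain-vector atom fields and a dense bond-order lookup (hot path)
  v_elem <- mol$atoms$elem; v_chg <- mol$atoms$chg; v_nH <- mol$atoms$nH
  v_map <- mol$atoms$map; v_arom <- mol$atoms$arom
  v_marker <- mol$atoms$marker; v_mult <- mol$atoms$mult
  v_stereo <- mol$atoms$stereo
  BO <- matrix(0L, n, n)
  if (nrow(mol$bonds)) {
    BO[cbind(mol$bonds$a1, mol$bonds$a2)] <- mol$bonds$order
    BO[cbind(mol$bonds$a2, mol$bonds$a1)] <- mol$bonds$order
  }

  ring_counter <- 0L
  out_parts <- character(0)
  for (ci in sort(unique(comp))) {
    atoms_c <- which(comp == ci)
    start <- atoms_c[which.min(ranks[atoms_c])]
    visited <- logical(n)
    ring_bonds <- list()   # per atom: list of c(other, order, number)
    ring_open <- new.env(parent = emptyenv())

    # first pass: identify DFS tree + ring-closure bonds
    parent <- rep(NA_integer_, n)
    order_visit <- integer(0)
    stack2 <- start
    visited2 <- logical(n)
    tree_children <- vector("list", n)
    closures <- list()
    dfs <- function(v, from) {
      visited2[v] <<- TRUE
      order_visit <<- c(order_visit, v)
      nbrs <- adj[[v]]
      nbrs <- nbrs[order(ranks[nbrs])]
      for (w in nbrs) {
        if (!is.na(from) && w == from) next
        if (visited2[w]) {
          key <- paste(min(v, w), max(v, w))
          if (is.null(closures[[key]])) {
            closures[[key]] <<- TRUE
            ring_counter <<- ring_counter + 1L
            num <- ring_counter
            ring_bonds[[as.character(v)]] <<-
              c(ring_bonds[[as.character(v)]], list(c(w, BO[v, w], num)))
            ring_bonds[[as.character(w)]] <<-
              c(ring_bonds[[as.character(w)]], list(c(v, BO[v, w], num)))
          }
        } else {
          parent[w] <<- v
          tree_children[[v]] <<- c(tree_children[[v]], w)
          dfs(w, v)
        }
      }
    }
    dfs(start, NA_integer_)

    ring_num_token <- function(num) {
      if (num < 10L) as.character(num) else paste0("%", sprintf("%02d", num))
    }

    emit <- function(v) {
      str <- atom_token2(v_elem[v], v_chg[v], v_nH[v], v_map[v], v_arom[v],
                         v_marker[v], v_mult[v], v_stereo[v], deg[v],
                         keep_maps)
      rb <- ring_bonds[[as.character(v)]]
      if (!is.null(rb)) {
        # deterministic: ring closures ordered by ring number
        rb <- rb[order(vapply(rb, function(x) x[3], numeric(1)))]
        for (x in rb) {
          w <- x[1]; ordx <- x[2]; num <- x[3]
          opened <- exists(as.character(num), envir = ring_open)
          sym <- if (!opened) bond_token(ordx, v_arom[v], v_arom[w]) else ""
          if (!opened) assign(as.character(num), TRUE, envir = ring_open)
          str <- paste0(str, sym, ring_num_token(num))
        }
      }
      kids <- tree_children[[v]]
      if (length(kids)) {
        kids <- kids[order(ranks[kids])]
        for (ki in seq_along(kids)) {
          w <- kids[ki]
          bt <- bond_token(BO[v, w], v_arom[v], v_arom[w])
          sub <- paste0(bt, emit(w))
          if (ki < length(kids)) str <- paste0(str, "(", sub, ")")
          else str <- paste0(str, sub)
        }
      }
      str
    }
    out_parts <- c(out_parts, emit(start))
  }
  if (canonical) out_parts <- sort_c(out_parts)
  paste(out_parts, collapse = ".")
}

#' Canonical serialization of a molecule
#'
#' Deterministic string identity for molecular graphs including marker
#' classes; equal graphs give equal strings regardless of input atom order.
#' Atom-map numbers are excluded so that serialization is stable across
#' differently mapped records of one molecule.
#'
#' @param mol Molecule object.
#' @return Canonical SMILES string.
#' @export
canonical_serialize <- function(mol) write_smiles(mol, keep_maps = FALSE,
                                                  canonical = TRUE)

# Alignment between two isomorphic molecules via canonical ranks:
# returns idx vector m with m[i in a] = corresponding atom in b, or NULL.
mol_align <- function(a, b) {
  if (n_atoms(a) != n_atoms(b)) return(NULL)
  ra <- mol_canonical_ranks(a)
  rb <- mol_canonical_ranks(b)
  m <- order(rb)[ra]
  # verify element agreement as a cheap sanity check
  if (!all(a$atoms$elem == b$atoms$elem[m])) return(NULL)
  m
}
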