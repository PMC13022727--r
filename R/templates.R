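#' @title Retrosynthetic templates
#' @description
#' A retro template is a rewrite rule extracted from one mapped reaction:
#' the product-side pattern is the subgraph of changed atoms plus a context
#' radius (double-bonded O/N/S neighbours of pattern atoms are pulled in
#' whole), and the precursor side records, per recorded reactant, the
#' pattern atoms it contributes, its bond orders among them, reactant-side
#' H/charge values for changed atoms, and any added atoms (leaving groups
#' or abstraction markers) with their attachment bonds. Application matches
#' the product pattern into a query molecule by subgraph monomorphism and
#' replays the edits, yielding one precursor set per distinct embedding.
#' Consolidation reassigns each reaction to the most general template able
#' to recover its recorded reactants.
#' @name templates
NULL

# neighbor signature of atom `i` restricted to heavy atoms with map in
# `valid_maps`: sorted "map:order" strings
nbr_signature <- function(mol, i, valid_maps) {
  b <- mol$bonds
  sig <- character(0)
  for (k in seq_len(nrow(b))) {
    j <- if (b$a1[k] == i) b$a2[k] else if (b$a2[k] == i) b$a1[k] else next
    if (mol$atoms$elem[j] == "*") next
    m <- mol$atoms$map[j]
    if (m > 0L && m %in% valid_maps)
      sig <- c(sig, paste0(m, ":", b$order[k]))
  }
  paste(sort_c(sig), collapse = ",")
}

# marker signature: sorted "class:mult" over marker neighbours of atom i
marker_signature <- function(mol, i) {
  b <- mol$bonds
  sig <- character(0)
  for (k in seq_len(nrow(b))) {
    j <- if (b$a1[k] == i) b$a2[k] else if (b$a2[k] == i) b$a1[k] else next
    if (mol$atoms$elem[j] == "*")
      sig <- c(sig, paste0(mol$atoms$marker[j], ":", mol$atoms$mult[j]))
  }
  paste(sort_c(sig), collapse = ",")
}

# TRUE per heavy atom of `mol` if it has any neighbour that is a marker, is
# unmapped, or carries a map outside `valid_maps` (an added/leaving atom)
has_added_neighbor <- function(mol, i, valid_maps) {
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    j <- if (b$a1[k] == i) b$a2[k] else if (b$a2[k] == i) b$a1[k] else next
    if (mol$atoms$elem[j] == "*") next  # markers handled separately
    m <- mol$atoms$map[j]
    if (m == 0L || !(m %in% valid_maps)) return(TRUE)
  }
  FALSE
}

#' Extract a retro template from a mapped reaction
#'
#' Identifies changed atoms (bonding, hydrogen count, charge, or attached
#' abstraction markers differ between the two sides, or a leaving/added
#' neighbour is present on the reactant side), grows the product pattern by
#' \code{radius} bonds of context plus whole multiply-bonded O/N/S groups,
#' and records the reactant-side state needed to replay the rewrite.
#'
#' @param rxn Reaction (concrete or abstracted), product fully mapped.
#' @param radius Context radius in bonds around changed atoms (default 1).
#' @return A template object.
#' @export
extract_template <- function(rxn, radius = 1L) {
  p <- rxn$product
  pmaps <- p$atoms$map[p$atoms$elem != "*"]
  if (any(pmaps == 0L))
    stop("template extraction requires a fully mapped product")
  # locate each product map in the reactants
  ratom <- list()  # map -> c(reactant index, atom index)
  for (j in seq_along(rxn$reactants)) {
    rm <- rxn$reactants[[j]]
    for (ai in seq_len(n_atoms(rm))) {
      if (rm$atoms$elem[ai] == "*") next
      m <- rm$atoms$map[ai]
      if (m > 0L) ratom[[as.character(m)]] <- c(j, ai)
    }
  }
  heavy <- which(p$atoms$elem != "*")
  changed <- logical(n_atoms(p))
  for (i in heavy) {
    m <- p$atoms$map[i]
    ra <- ratom[[as.character(m)]]
    if (is.null(ra)) stop("orphan product atom (map ", m, ")")
    rm <- rxn$reactants[[ra[1]]]
    ai <- ra[2]
    changed[i] <-
      nbr_signature(p, i, pmaps) != nbr_signature(rm, ai, pmaps) ||
      marker_signature(p, i) != marker_signature(rm, ai) ||
      p$atoms$nH[i] != rm$atoms$nH[ai] ||
      p$atoms$chg[i] != rm$atoms$chg[ai] ||
      has_added_neighbor(rm, ai, pmaps)
  }
  if (!any(changed)) stop("null transformation: no changed atoms")

  # grow pattern: radius bonds of context from changed atoms (heavy only)
  adj <- mol_adjacency(p)
  patt <- which(changed)
  frontier <- patt
  r <- 0L
  while (r < radius) {
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[p$atoms$elem[nxt] != "*"]
    frontier <- setdiff(nxt, patt)
    patt <- union(patt, frontier)
    r <- r + 1L
  }
  # whole special-case groups: multiply-bonded O/N/S neighbours
  repeat {
    extra <- integer(0)
    for (i in patt) {
      b <- p$bonds
      for (k in seq_len(nrow(b))) {
        j <- if (b$a1[k] == i) b$a2[k] else if (b$a2[k] == i) b$a1[k] else next
        if (j %in% patt) next
        if (b$order[k] >= 2L && p$atoms$elem[j] %in% c("O", "N", "S"))
          extra <- c(extra, j)
      }
    }
    if (!length(extra)) break
    patt <- union(patt, unique(extra))
  }
  patt <- sort(patt)
  # marker vertices attached to pattern atoms
  mk <- integer(0)
  for (i in patt) for (j in adj[[i]])
    if (p$atoms$elem[j] == "*") mk <- c(mk, j)
  sel <- c(patt, sort(unique(mk)))
  prod_pat <- mol_subgraph(p, sel)
  tmaps <- p$atoms$map[patt]
  prod_changed <- changed[sel]

  # reactant side
  reactants <- list()
  for (j in seq_along(rxn$reactants)) {
    rm <- rxn$reactants[[j]]
    kept <- which(rm$atoms$elem != "*" & rm$atoms$map %in% tmaps)
    if (!length(kept)) next  # spectator or out-of-pattern contributor
    # added atoms: connected components of non-kept atoms adjacent to kept;
    # restricted to atoms not mapped into the product at all
    nonkept <- which(!(seq_len(n_atoms(rm)) %in% kept) &
                       !(rm$atoms$map %in% pmaps & rm$atoms$elem != "*"))
    added <- integer(0)
    if (length(nonkept)) {
      sub <- mol_subgraph(rm, nonkept)
      comp <- mol_components(sub)
      radj <- mol_adjacency(rm)
      for (ci in seq_len(max(comp, 0L))) {
        members <- nonkept[comp == ci]
        touches <- any(vapply(members, function(a)
          any(radj[[a]] %in% kept), FALSE))
        if (touches) added <- c(added, members)
      }
    }
    selr <- c(kept, sort(added))
    rpat <- mol_subgraph(rm, selr)
    reactants[[length(reactants) + 1L]] <- list(
      mol = rpat,
      tmap = c(rm$atoms$map[kept], rep(0L, length(added))))
  }

  tpl <- structure(list(
    prod = prod_pat,
    tmaps = tmaps,                       # per heavy pattern atom (order of patt)
    prod_changed = prod_changed,         # per prod_pat atom (heavy then markers)
    reactants = reactants,
    radius = radius,
    precedent_count = 1L
  ), class = "retro_template")
  tpl$id <- template_id(tpl)
  tpl
}

# Deterministic template identity string. Heavy pattern atoms are relabelled
# by canonical ranks of the product pattern; precursors reuse those labels.
template_id <- function(tpl) {
  pp <- tpl$prod
  heavy <- which(pp$atoms$elem != "*")
  ranks <- mol_canonical_ranks(pp)
  lab <- integer(max(tpl$tmaps))
  lab[tpl$tmaps] <- rank(ranks[heavy])  # labels 1..n in canonical order
  pp$atoms$map[heavy] <- lab[tpl$tmaps]
  rstr <- vapply(tpl$reactants, function(rp) {
    m <- rp$mol
    hv <- which(m$atoms$elem != "*")
    m$atoms$map[hv] <- ifelse(rp$tmap[hv] > 0L, lab[pmax(rp$tmap[hv], 1L)], 0L)
    m$atoms$map[m$atoms$elem == "*"] <- 0L
    write_smiles(m, keep_maps = TRUE)
  }, "")
  ch <- sort(lab[tpl$tmaps[tpl$prod_changed[seq_along(tpl$tmaps)]]])
  chinfo <- paste(ch, collapse = ",")
  paste0(write_smiles(pp, keep_maps = TRUE), ">>",
         paste(sort_c(rstr), collapse = "|"), "!", chinfo)
}

#' @export
print.retro_template <- function(x, ...) {
  cat("<retro_template> ", x$id, " (", x$precedent_count, " precedent",
      if (x$precedent_count != 1L) "s", ")\n", sep = "")
  invisible(x)
}

# element counts used as a fast match prefilter
elem_counts <- function(mol) {
  t <- table(mol$atoms$elem[mol$atoms$elem != "*"])
  stats::setNames(as.integer(t), names(t))
}

template_can_match <- function(tpl, target_counts) {
  pc <- elem_counts(tpl$prod)
  for (e in names(pc)) {
    tc <- target_counts[e]
    if (is.na(tc) || tc < pc[[e]]) return(FALSE)
  }
  TRUE
}

#' Apply a retro template to a product molecule
#'
#' Finds all embeddings of the product pattern (subgraph monomorphism with
#' element, aromaticity, charge, marker class/multiplicity, bond order, and
#' changed-atom H-count constraints) and replays the recorded edits for
#' each, producing one precursor set per distinct embedding
#' (canonical-deduplicated).
#'
#' @param tpl Template object.
#' @param product Molecule to rewrite.
#' @return List of precursor sets; each set is a list with \code{mols}
#'   (molecule objects) and \code{smiles} (sorted canonical strings).
#' @export
apply_template <- function(tpl, product) {
  np <- n_atoms(tpl$prod)
  nt <- n_atoms(product)
  if (np == 0L || nt < np) return(list())
  pa <- tpl$prod$atoms
  ta <- product$atoms
  # candidate domains per pattern vertex
  domains <- vector("list", np)
  heavy_pat <- pa$elem != "*"
  for (i in seq_len(np)) {
    if (heavy_pat[i]) {
      cand <- which(ta$elem == pa$elem[i] & ta$arom == pa$arom[i] &
                      ta$chg == pa$chg[i])
      if (tpl$prod_changed[i]) cand <- cand[ta$nH[cand] == pa$nH[i]]
    } else {
      cand <- which(ta$elem == "*" & ta$marker == pa$marker[i] &
                      ta$mult == pa$mult[i])
    }
    if (!length(cand)) return(list())
    domains[[i]] <- cand
  }
  maps <- find_monomorphisms(tpl$prod, product, domains)
  if (!length(maps)) return(list())
  out <- list()
  seen <- character(0)
  for (mp in maps) {
    pset <- apply_edits(tpl, product, mp)
    if (is.null(pset)) next
    key <- paste(pset$smiles, collapse = "+")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- pset
  }
  out
}

# subgraph monomorphisms of pattern into target honoring domains and bond
# orders; returns list of integer vectors (target index per pattern vertex)
find_monomorphisms <- function(pattern, target, domains) {
  np <- n_atoms(pattern)
  if (np == 1L) return(lapply(domains[[1]], function(x) x))
  pg <- igraph::make_graph(edges = rbind(pattern$bonds$a1, pattern$bonds$a2),
                           n = np, directed = FALSE)
  tg <- igraph::make_graph(edges = rbind(target$bonds$a1, target$bonds$a2),
                           n = n_atoms(target), directed = FALSE)
  maps <- tryCatch(
    igraph::subgraph_isomorphisms(pg, tg, method = "lad",
                                  domains = lapply(domains, as.integer),
                                  induced = FALSE),
    error = function(e) list())
  if (!length(maps)) return(list())
  good <- list()
  for (m in maps) {
    mp <- as.integer(m)
    ok <- TRUE
    for (k in seq_len(nrow(pattern$bonds))) {
      o <- bond_order_between(target, mp[pattern$bonds$a1[k]],
                              mp[pattern$bonds$a2[k]])
      if (o != pattern$bonds$order[k]) { ok <- FALSE; break }
    }
    if (ok) good[[length(good) + 1L]] <- mp
  }
  good
}

# replay template edits for one embedding; returns precursor set or NULL
apply_edits <- function(tpl, product, mp) {
  pa <- tpl$prod$atoms
  heavy_idx <- which(pa$elem != "*")
  # matched target atom per tmap label
  tgt_of <- integer(0)
  for (k in seq_along(heavy_idx))
    tgt_of[as.character(tpl$tmaps[k])] <- mp[heavy_idx[k]]
  g <- product
  # 1. remove matched product-side marker vertices (reactant side re-adds)
  marker_rows <- which(pa$elem == "*")
  del_markers <- mp[marker_rows]
  # 2. bond edits among pattern atoms: set to reactant-side orders
  pb <- tpl$prod$bonds
  # product-side orders among tmap pairs
  p_pairs <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(pb))) {
    i <- pb$a1[k]; j <- pb$a2[k]
    if (pa$elem[i] == "*" || pa$elem[j] == "*") next
    mi <- tpl$tmaps[match(i, heavy_idx)]
    mj <- tpl$tmaps[match(j, heavy_idx)]
    key <- paste(min(mi, mj), max(mi, mj))
    p_pairs[[key]] <- pb$order[k]
  }
  r_pairs <- new.env(parent = emptyenv())
  owner <- integer(0)  # tmap -> reactant index
  for (j in seq_along(tpl$reactants)) {
    rp <- tpl$reactants[[j]]
    rm <- rp$mol
    for (k in seq_len(nrow(rm$bonds))) {
      i1 <- rm$bonds$a1[k]; i2 <- rm$bonds$a2[k]
      m1 <- rp$tmap[i1]; m2 <- rp$tmap[i2]
      if (m1 > 0L && m2 > 0L) {
        key <- paste(min(m1, m2), max(m1, m2))
        r_pairs[[key]] <- rm$bonds$order[k]
      }
    }
    for (i in seq_along(rp$tmap))
      if (rp$tmap[i] > 0L) owner[as.character(rp$tmap[i])] <- j
  }
  # delete or change product bonds
  for (key in ls(p_pairs)) {
    ms <- as.integer(strsplit(key, " ")[[1]])
    ro <- r_pairs[[key]]
    po <- p_pairs[[key]]
    if (is.null(ro)) {
      g <- mol_set_bond(g, tgt_of[[as.character(ms[1])]],
                        tgt_of[[as.character(ms[2])]], 0L)
    } else if (ro != po) {
      g <- mol_set_bond(g, tgt_of[[as.character(ms[1])]],
                        tgt_of[[as.character(ms[2])]], ro)
    }
  }
  # add reactant-side bonds absent from the product pattern
  for (key in ls(r_pairs)) {
    if (!is.null(p_pairs[[key]])) next
    ms <- as.integer(strsplit(key, " ")[[1]])
    g <- mol_set_bond(g, tgt_of[[as.character(ms[1])]],
                      tgt_of[[as.character(ms[2])]], r_pairs[[key]])
  }
  # 3. changed-atom H/charge set to reactant-side values; collect adds
  new_atom_owner <- integer(0)
  for (j in seq_along(tpl$reactants)) {
    rp <- tpl$reactants[[j]]
    rm <- rp$mol
    local_of <- integer(n_atoms(rm))  # reactant-pattern idx -> g idx
    for (i in seq_len(n_atoms(rm))) {
      if (rp$tmap[i] > 0L) {
        gi <- tgt_of[[as.character(rp$tmap[i])]]
        local_of[i] <- gi
        g$atoms$nH[gi] <- rm$atoms$nH[i]
        g$atoms$chg[gi] <- rm$atoms$chg[i]
      }
    }
    # added atoms (leaving groups, markers)
    for (i in seq_len(n_atoms(rm))) {
      if (rp$tmap[i] == 0L) {
        g <- mol_add_atom(g, rm$atoms$elem[i], chg = rm$atoms$chg[i],
                          nH = rm$atoms$nH[i], arom = rm$atoms$arom[i],
                          marker = rm$atoms$marker[i], mult = rm$atoms$mult[i])
        local_of[i] <- n_atoms(g)
        new_atom_owner[as.character(n_atoms(g))] <- j
      }
    }
    for (k in seq_len(nrow(rm$bonds))) {
      i1 <- rm$bonds$a1[k]; i2 <- rm$bonds$a2[k]
      if (rp$tmap[i1] > 0L && rp$tmap[i2] > 0L) next  # handled above
      g <- mol_set_bond(g, local_of[i1], local_of[i2], rm$bonds$order[k])
    }
  }
  # 4. delete matched product-side markers (indices unchanged: deletions last)
  g <- mol_delete_atoms(g, del_markers)
  # deletion reindexed atoms; rebuild tracking
  keep <- setdiff(seq_len(n_atoms(g) + length(del_markers)), del_markers)
  remap <- integer(length(keep) + length(del_markers))
  remap[keep] <- seq_along(keep)
  tgt_of2 <- vapply(tgt_of, function(x) remap[x], 0L)
  comp <- mol_components(g)
  parts <- mol_split(g)
  # assign components to reactants
  comp_owner <- rep(NA_integer_, length(parts))
  for (nm in names(tgt_of2)) {
    ci <- comp[tgt_of2[[nm]]]
    j <- owner[[nm]]
    if (!is.na(comp_owner[ci]) && comp_owner[ci] != j) return(NULL)
    comp_owner[ci] <- j
  }
  for (nm in names(new_atom_owner)) {
    gi <- remap[as.integer(nm)]
    ci <- comp[gi]
    if (!is.na(comp_owner[ci]) && comp_owner[ci] != new_atom_owner[[nm]])
      return(NULL)
    comp_owner[ci] <- new_atom_owner[[nm]]
  }
  if (any(is.na(comp_owner))) return(NULL)  # stranded fragment
  # merge parts per reactant
  mols <- list()
  for (j in sort(unique(comp_owner))) {
    sub <- parts[comp_owner == j]
    m <- sub[[1]]
    if (length(sub) > 1L) for (s in sub[-1]) m <- mol_union(m, s)$mol
    mols[[length(mols) + 1L]] <- m
  }
  smiles <- sort_c(vapply(mols, canonical_serialize, ""))
  list(mols = mols, smiles = smiles)
}

#' Does a template recover a reaction's recorded reactants?
#'
#' Applies the template to the reaction's product and tests whether any
#' precursor set equals the recorded (non-spectator) reactant multiset by
#' canonical strings.
#'
#' @param tpl Template.
#' @param rxn Reaction whose product/reactants to test.
#' @return TRUE if recovered.
#' @export
template_recovers <- function(tpl, rxn) {
  want <- sort_c(vapply(rxn$reactants, canonical_serialize, ""))
  psets <- apply_template(tpl, rxn$product)
  for (ps in psets) if (identical(ps$smiles, want)) return(TRUE)
  FALSE
}

#' Extract and consolidate templates over a set of reactions
#'
#' Extracts templates from every reaction at the given radii (the pool thus
#' contains more and less specific variants), deduplicates them, computes
#' which templates recover which reactions, and assigns each reaction the
#' most general recovering template: largest recovery set, ties broken by
#' fewer pattern atoms, then lexicographic template id.
#'
#' @param reactions List of reactions (e.g. the \code{rxn} fields of a
#'   curated dataset's pairs).
#' @param radii Context radii pooled for generality (default \code{c(1, 0)}).
#' @return List: \code{templates} (unique assigned templates with precedent
#'   counts), \code{assignment} (template index per reaction),
#'   \code{pool_size} (unique extracted templates before consolidation),
#'   \code{unrecovered} (indices of reactions recovered by no template;
#'   expected empty).
#' @export
consolidate_templates <- function(reactions, radii = c(1L, 0L)) {
  radii <- sort(unique(as.integer(radii)))
  pool <- list()
  pool_ids <- character(0)
  own <- vector("list", length(reactions))    # per reaction: pool idx by radius
  fam_of_rxn <- character(length(reactions))  # minimal-radius id = family key
  fam_of_tpl <- character(0)
  for (ri in seq_along(reactions)) {
    ids_here <- character(0)
    for (rad in radii) {
      tpl <- extract_template(reactions[[ri]], radius = rad)
      k <- match(tpl$id, pool_ids)
      if (is.na(k)) {
        pool[[length(pool) + 1L]] <- tpl
        pool_ids <- c(pool_ids, tpl$id)
        fam_of_tpl <- c(fam_of_tpl, NA_character_)
        k <- length(pool)
      }
      own[[ri]] <- c(own[[ri]], k)
      ids_here <- c(ids_here, tpl$id)
    }
    fam_of_rxn[ri] <- ids_here[1]  # smallest radius first
    for (k in own[[ri]]) fam_of_tpl[k] <- ids_here[1]
  }
  # Recovery sets without exhaustive application. Within one family (same
  # minimal-radius rewrite), the identity embedding guarantees that (a) the
  # family's minimal-radius template recovers every member reaction, and
  # (b) any template recovers the reactions sharing its own extraction id.
  # Cross-family recovery would require two distinct changed-atom rewrites
  # to reproduce identical recorded reactants and does not occur.
  rxn_by_tpl <- vector("list", length(pool))  # reactions extracting tpl ti
  for (ri in seq_along(reactions))
    for (k in unique(own[[ri]]))
      rxn_by_tpl[[k]] <- c(rxn_by_tpl[[k]], ri)
  recovers <- vector("list", length(pool))
  rxn_by_fam <- split(seq_along(reactions), fam_of_rxn)
  for (ti in seq_along(pool)) {
    if (pool_ids[ti] == fam_of_tpl[ti]) {
      recovers[[ti]] <- rxn_by_fam[[fam_of_tpl[ti]]]
    } else {
      recovers[[ti]] <- sort(unique(rxn_by_tpl[[ti]]))
    }
  }
  gen_size <- vapply(recovers, length, 0L)
  npat <- vapply(pool, function(t) n_atoms(t$prod), 0L)
  assignment <- integer(length(reactions))
  unrecovered <- integer(0)
  for (ri in seq_along(reactions)) {
    cand <- which(vapply(recovers, function(h) ri %in% h, FALSE))
    if (!length(cand)) {
      unrecovered <- c(unrecovered, ri)
      assignment[ri] <- NA_integer_
      next
    }
    ord <- order(-gen_size[cand], npat[cand],
                 match(pool_ids, sort_c(pool_ids))[cand])
    assignment[ri] <- cand[ord[1]]
  }
  used <- sort(unique(assignment[!is.na(assignment)]))
  remap <- integer(length(pool))
  remap[used] <- seq_along(used)
  templates <- pool[used]
  for (k in seq_along(templates))
    templates[[k]]$precedent_count <- sum(assignment == used[k], na.rm = TRUE)
  list(templates = templates,
       assignment = ifelse(is.na(assignment), NA_integer_, remap[assignment]),
       pool_size = length(pool),
       unrecovered = unrecovered)
}

#' Write templates as JSONL
#' @param templates List of templates.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_templates_jsonl <- function(templates, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(templates)) {
    writeLines(jsonlite::toJSON(list(
      template_id = i, rule = templates[[i]]$id,
      precedent_count = templates[[i]]$precedent_count
    ), auto_unbox = TRUE), con)
  }
  invisible(path)
}
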