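#' @title Synthetic patent-like reaction corpus
#' @description
#' Generates per-document multistep routes assembled forward from enumerated
#' aryl scaffolds via a fixed library of reaction families (biaryl coupling,
#' amide/ester formation, Buchwald amination, Sonogashira coupling,
#' etherification, N-alkylation, sulfonamide formation, benzyl/Boc
#' deprotections), with tactical detours (hydroxyl-to-triflate and
#' acid-to-acyl-chloride interconversions, Boc protection/deprotection
#' pairs) planted at known positions. Every atom carries a persistent
#' identity through the forward assembly, so leaving-atom ground truth is
#' known exactly by construction and is independent of the map-following
#' provenance tracer it is used to test.
#' @name synthetic_corpus
NULL

#' Corpus generation specification
#'
#' @param n_documents Number of documents (one route each).
#' @param p_tactical Probability of planting a leaving-group FGI detour in a
#'   route (hydroxyl-to-triflate before a biaryl coupling, or
#'   acid-to-acyl-chloride before an acylation).
#' @param p_protection Probability a route takes the Boc
#'   protection/deprotection shape (two planted tactical steps).
#' @param p_obn Probability the target carries a benzyl-protected phenol
#'   removed in a final (non-tactical) deprotection step.
#' @param p_convergent Probability the final step's partner is itself
#'   assembled by a prefab coupling (convergent route).
#' @param min_steps,max_steps Scaffold-building steps per route.
#' @param families Allowed scaffold-building families.
#' @param seed Integer seed; same spec and seed give a byte-identical corpus.
#' @return A corpus specification list.
#' @export
corpus_spec <- function(n_documents = 50L, p_tactical = 0.35,
                        p_protection = 0.1, p_obn = 0.1,
                        p_convergent = 0.2, min_steps = 2L, max_steps = 3L,
                        families = c("suzuki", "amide", "ester", "buchwald",
                                     "sonogashira", "ether", "n_alkylation",
                                     "amide_on_amine", "sulfonamide"),
                        seed = 1L) {
  if (!length(families)) stop("empty family list")
  list(n_documents = as.integer(n_documents), p_tactical = p_tactical,
       p_protection = p_protection, p_obn = p_obn,
       p_convergent = p_convergent, min_steps = as.integer(min_steps),
       max_steps = as.integer(max_steps), families = families,
       seed = as.integer(seed))
}

# ---- piece construction ---------------------------------------------------

# W-side handle prefix per family (the group consumed by that family's step)
family_w_handle <- function(fam) {
  switch(fam,
         suzuki = "Br", buchwald = "Br", sonogashira = "Br",
         amide = "acyl", ester = "acyl",
         ether = "OH",
         n_alkylation = "NH2", amide_on_amine = "NH2",
         sulfonamide = "SO2Cl",
         stop("unknown family ", fam))
}

HANDLE_PREFIX <- list(
  Br = "Br", OH = "O", NH2 = "N", SO2Cl = "ClS(=O)(=O)",
  acyl_OH = "OC(=O)", acyl_Cl = "ClC(=O)", acyl_OMe = "COC(=O)")

# handle group written attachment-atom-first, for ring substituent slots
HANDLE_SUFFIX <- list(
  Br = "(Br)", OH = "(O)", NH2 = "(N)", SO2Cl = "(S(=O)(=O)Cl)",
  acyl_OH = "(C(=O)O)", acyl_Cl = "(C(=O)Cl)", acyl_OMe = "(C(=O)OC)")

VARIANT_PREFIX <- list(
  Br = "I", OH = "CC(=O)O", NH2 = "CC(C)(C)OC(=O)N", SO2Cl = "FS(=O)(=O)",
  acyl_OH = "ClC(=O)", acyl_Cl = "COC(=O)", acyl_OMe = "OC(=O)",
  B = "C[Sn](C)(C)", CC = "C[Sn](C)(C)", BrC = "IC")

RING_SUBS <- c("", "(F)", "(Cl)", "(C)", "(CC)", "(OC)", "(C#N)")

ring_smiles <- function(prefix, nxt = "", extra = "", allow_ome = TRUE) {
  subs <- RING_SUBS
  if (!allow_ome) subs <- setdiff(subs, "(OC)")
  s <- sample(subs, 2L, replace = TRUE)
  slots <- c(s[1], if (nzchar(nxt)) nxt else s[2], extra)
  paste0(prefix, "c1c", slots[1], "c", slots[2], "c", slots[3], "cc1")
}

# atoms occupied by each handle prefix in a piece SMILES (attachment-bearing
# group written first), used to disambiguate a piece's own handle from a
# carried next-step handle of the same kind
PREFIX_NATOMS <- list(
  Br = 1L, OH = 1L, NH2 = 1L, SO2Cl = 4L, acyl_OH = 3L, acyl_Cl = 3L,
  acyl_OMe = 4L, B = 3L, CC = 2L, BrC = 2L)

# locate a handle of `type` in a parsed piece; returns list(attach, lv,
# hloss) with atom indices. `region` restricts the handle's anchor atom.
locate_handle <- function(mol, type, region = NULL) {
  adj <- mol_adjacency(mol)
  a <- mol$atoms
  one <- function(x, what) {
    if (!is.null(region)) x <- intersect(x, region)
    if (length(x) != 1L) stop("handle location failed (", what, ")")
    x
  }
  if (type == "Br" || type == "BrC") {
    brs <- which(a$elem == "Br")
    want_arom <- type == "Br"
    br <- one(brs[vapply(brs, function(i) a$arom[adj[[i]][1]] == want_arom,
                         FALSE)], type)
    list(attach = adj[[br]][1], lv = br, hloss = 0L)
  } else if (type == "I") {
    i <- one(which(a$elem == "I"), "I")
    list(attach = adj[[i]][1], lv = i, hloss = 0L)
  } else if (type == "B") {
    b <- one(which(a$elem == "B"), "B")
    os <- adj[[b]][a$elem[adj[[b]]] == "O"]
    att <- adj[[b]][a$arom[adj[[b]]]]
    if (length(att) != 1L) stop("handle location failed (B attach)")
    list(attach = att, lv = c(b, os), hloss = 0L)
  } else if (type == "OH") {
    cand <- which(a$elem == "O" & a$nH == 1L &
                    vapply(seq_len(n_atoms(mol)), function(i) {
                      if (a$elem[i] != "O" || length(adj[[i]]) != 1L)
                        return(FALSE)
                      nb <- adj[[i]][1]
                      if (a$elem[nb] == "B") return(FALSE)
                      # not a carboxyl OH: neighbour has no double-bonded O
                      !any(vapply(adj[[nb]], function(j)
                        a$elem[j] == "O" &&
                          bond_order_between(mol, nb, j) == 2L, FALSE))
                    }, FALSE))
    o <- one(cand, "OH")
    list(attach = o, lv = integer(0), hloss = 1L)
  } else if (type == "NH2") {
    n <- one(which(a$elem == "N" & a$nH == 2L), "NH2")
    list(attach = n, lv = integer(0), hloss = 1L)
  } else if (type == "SO2Cl") {
    s <- one(which(a$elem == "S"), "S")
    cl <- adj[[s]][a$elem[adj[[s]]] == "Cl"]
    list(attach = s, lv = one(cl, "SO2Cl Cl"), hloss = 0L)
  } else if (type %in% c("acyl_OH", "acyl_Cl", "acyl_OMe")) {
    cac <- which(a$elem == "C" & !a$arom &
                   vapply(seq_len(n_atoms(mol)), function(i)
                     any(a$elem[adj[[i]]] == "O" &
                           vapply(adj[[i]], function(j)
                             bond_order_between(mol, i, j) == 2L, FALSE)),
                     FALSE))
    if (!is.null(region)) cac <- intersect(cac, region)
    # the acyl carbon also carries the X group
    lv <- NULL; att <- NULL
    for (cc in cac) {
      nb <- adj[[cc]]
      if (type == "acyl_Cl") {
        x <- nb[a$elem[nb] == "Cl"]
        if (length(x) == 1L) { att <- cc; lv <- x; break }
      } else if (type == "acyl_OH") {
        x <- nb[a$elem[nb] == "O" & a$nH[nb] == 1L]
        if (length(x) == 1L) { att <- cc; lv <- x; break }
      } else {
        x <- nb[a$elem[nb] == "O" & a$nH[nb] == 0L &
                  vapply(nb, function(j)
                    bond_order_between(mol, cc, j) == 1L, FALSE)]
        if (length(x) == 1L) {
          me <- setdiff(adj[[x]], cc)
          if (length(me) == 1L && a$elem[me] == "C" && a$nH[me] == 3L) {
            att <- cc; lv <- c(x, me); break
          }
        }
      }
    }
    if (is.null(att)) stop("handle location failed (", type, ")")
    list(attach = att, lv = lv, hloss = 0L)
  } else if (type == "CC") {
    cc <- one(which(a$elem == "C" & a$nH == 1L &
                      vapply(seq_len(n_atoms(mol)), function(i)
                        any(vapply(adj[[i]], function(j)
                          bond_order_between(mol, i, j) == 3L, FALSE)),
                        FALSE)), "terminal alkyne")
    list(attach = cc, lv = integer(0), hloss = 1L)
  } else stop("unknown handle type ", type)
}

# generator state: environment with uid counter
new_gen_state <- function() {
  e <- new.env(parent = emptyenv())
  e$uid <- 0L
  e
}

assign_uids <- function(mol, st) {
  n <- n_atoms(mol)
  mol$atoms$uid <- st$uid + seq_len(n)
  st$uid <- st$uid + n
  mol
}

uid_idx <- function(mol, uids) match(uids, mol$atoms$uid)

# make a piece: parse, assign uids, locate handles (stored as uids)
make_piece <- function(st, smiles, handle_type, nxt_type = NULL,
                       variant = NA_character_) {
  mol <- assign_uids(parse_smiles(smiles), st)
  np <- PREFIX_NATOMS[[handle_type]]
  own_region <- if (!is.null(np)) seq_len(np) else NULL
  h <- locate_handle(mol, handle_type, region = own_region)
  piece <- list(mol = mol, smiles = canonical_serialize(mol),
                variant = variant,
                handle = list(type = handle_type,
                              attach = mol$atoms$uid[h$attach],
                              lv = mol$atoms$uid[h$lv], hloss = h$hloss))
  if (!is.null(nxt_type)) {
    h2 <- locate_handle(mol, nxt_type,
                        region = if (!is.null(np))
                          setdiff(seq_len(n_atoms(mol)), seq_len(np)))
    piece$nxt <- list(type = nxt_type, attach = mol$atoms$uid[h2$attach],
                      lv = mol$atoms$uid[h2$lv], hloss = h2$hloss)
  }
  piece
}

# partner piece for a family; carries the next W handle when nxt_type given
make_partner <- function(st, fam, nxt_type = NULL) {
  nxt_prefix <- if (!is.null(nxt_type)) HANDLE_SUFFIX[[nxt_type]] else ""
  if (fam == "suzuki") {
    smi <- ring_smiles("OB(O)", nxt_prefix)
    make_piece(st, smi, "B", nxt_type,
               variant = sub("^OB\\(O\\)", VARIANT_PREFIX$B, smi))
  } else if (fam %in% c("amide", "buchwald", "sulfonamide")) {
    if (is.null(nxt_type) && stats::runif(1) < 0.5) {
      smi <- sample(c("NCC", "NCCC", "NCC(C)C", "NCc1ccccc1"), 1L)
    } else {
      smi <- ring_smiles("N", nxt_prefix)
    }
    make_piece(st, smi, "NH2", nxt_type,
               variant = sub("^N", VARIANT_PREFIX$NH2, smi))
  } else if (fam == "sonogashira") {
    smi <- if (is.null(nxt_type) && stats::runif(1) < 0.5)
      sample(c("C#CC", "C#CCC", "C#CCCC"), 1L)
    else ring_smiles("C#C", nxt_prefix)
    make_piece(st, smi, "CC", nxt_type,
               variant = paste0(VARIANT_PREFIX$CC, smi))
  } else if (fam == "ester") {
    smi <- if (is.null(nxt_type) && stats::runif(1) < 0.5)
      sample(c("OCC", "OCCC", "OCC(C)C"), 1L)
    else ring_smiles("O", nxt_prefix)
    make_piece(st, smi, "OH", nxt_type,
               variant = sub("^O", VARIANT_PREFIX$OH, smi))
  } else if (fam %in% c("ether", "n_alkylation")) {
    smi <- if (is.null(nxt_type) && stats::runif(1) < 0.5)
      sample(c("BrCC", "BrCCC", "BrCCc1ccccc1"), 1L)
    else ring_smiles("BrC", nxt_prefix)
    make_piece(st, smi, "BrC", nxt_type,
               variant = sub("^Br", "I", smi))
  } else if (fam == "amide_on_amine") {
    x <- sample(c("acyl_OH", "acyl_Cl", "acyl_OMe"), 1L)
    smi <- ring_smiles(HANDLE_PREFIX[[x]], nxt_prefix)
    make_piece(st, smi, x, nxt_type,
               variant = sub(paste0("^", gsub("([()])", "\\\\\\1",
                                              HANDLE_PREFIX[[x]])),
                             VARIANT_PREFIX[[x]], smi))
  } else stop("unknown family ", fam)
}

DONOR_SMILES <- list(
  tf2o = "O=S(=O)(OS(=O)(=O)C(F)(F)F)C(F)(F)F",
  boc2o = "O=C(OC(C)(C)C)OC(=O)OC(C)(C)C",
  oxalyl = "ClC(=O)C(=O)Cl")

# ---- forward reaction surgery --------------------------------------------

# couple W and partner: drop both leaving sets, adjust H, bond attach atoms
do_couple <- function(W, P, order = 1L) {
  u <- mol_union(W$mol, P$mol)
  g <- u$mol
  ia <- uid_idx(g, W$handle$attach)
  ib <- uid_idx(g, P$handle$attach)
  g$atoms$nH[ia] <- g$atoms$nH[ia] - W$handle$hloss
  g$atoms$nH[ib] <- g$atoms$nH[ib] - P$handle$hloss
  g <- mol_set_bond(g, ia, ib, order)
  g <- mol_delete_atoms(g, uid_idx(g, c(W$handle$lv, P$handle$lv)))
  g
}

# FGI: phenol W -> triflate W (Tf2O donor); handle becomes OTf-like
do_fgi_otf <- function(st, W) {
  donor <- assign_uids(parse_smiles(DONOR_SMILES$tf2o), st)
  transfer <- c(2L, 1L, 3L, 12L, 13L, 14L, 15L)  # S(=O)(=O)CF3 of one half
  u <- mol_union(W$mol, donor)
  g <- u$mol
  io <- uid_idx(g, W$handle$attach)
  is <- u$offset + 2L
  g$atoms$nH[io] <- g$atoms$nH[io] - 1L
  g <- mol_set_bond(g, io, is, 1L)
  drop <- u$offset + setdiff(seq_len(15L), transfer)
  g <- mol_delete_atoms(g, drop)
  ring_c <- W$ring_attach
  newW <- W
  newW$mol <- g
  newW$handle <- list(type = "OTf", attach = ring_c,
                      lv = c(W$handle$attach, donor$atoms$uid[transfer]),
                      hloss = 0L)
  list(W = newW, donor = donor)
}

# FGI: carboxylic acid W -> acyl chloride W (oxalyl chloride donor)
do_fgi_acyl_cl <- function(st, W) {
  donor <- assign_uids(parse_smiles(DONOR_SMILES$oxalyl), st)
  u <- mol_union(W$mol, donor)
  g <- u$mol
  icl <- u$offset + 1L
  iac <- uid_idx(g, W$handle$attach)
  g <- mol_set_bond(g, iac, icl, 1L)
  g <- mol_delete_atoms(g, c(uid_idx(g, W$handle$lv),
                             u$offset + 2:6))
  newW <- W
  newW$mol <- g
  newW$handle <- list(type = "acyl_Cl", attach = W$handle$attach,
                      lv = donor$atoms$uid[1L], hloss = 0L)
  list(W = newW, donor = donor)
}

# Boc protection of an amine handle (Boc2O donor)
do_protect_n <- function(st, W, nh) {
  donor <- assign_uids(parse_smiles(DONOR_SMILES$boc2o), st)
  transfer <- c(2L, 1L, 3L, 4L, 5L, 6L, 7L)
  u <- mol_union(W$mol, donor)
  g <- u$mol
  iN <- uid_idx(g, nh$attach)
  iC <- u$offset + 2L
  g$atoms$nH[iN] <- g$atoms$nH[iN] - 1L
  g <- mol_set_bond(g, iN, iC, 1L)
  g <- mol_delete_atoms(g, u$offset + setdiff(seq_len(15L), transfer))
  list(mol = g, donor = donor,
       nh = list(type = "NHBoc", attach = nh$attach,
                 boc = donor$atoms$uid[transfer], hloss = 0L))
}

do_deprotect_n <- function(g, nh) {
  iN <- uid_idx(g, nh$attach)
  g$atoms$nH[iN] <- g$atoms$nH[iN] + 1L
  mol_delete_atoms(g, uid_idx(g, nh$boc))
}

# remove an O-benzyl group (atom uids in `obn`), restoring the phenol
do_deprotect_obn <- function(g, obn) {
  io <- uid_idx(g, obn$o)
  g$atoms$nH[io] <- g$atoms$nH[io] + 1L
  mol_delete_atoms(g, uid_idx(g, obn$bn))
}

# ---- record emission ------------------------------------------------------

emit_record <- function(doc_id, rid, reactant_mols, product_mol) {
  ctr <- 0L
  for (j in seq_along(reactant_mols)) {
    m <- reactant_mols[[j]]
    for (i in seq_len(n_atoms(m))) {
      if (m$atoms$elem[i] == "*") next
      ctr <- ctr + 1L
      m$atoms$map[i] <- ctr
    }
    reactant_mols[[j]] <- m
  }
  alluid <- unlist(lapply(reactant_mols, function(m) m$atoms$uid))
  allmap <- unlist(lapply(reactant_mols, function(m) m$atoms$map))
  pm <- product_mol
  pm$atoms$map <- allmap[match(pm$atoms$uid, alluid)]
  if (any(is.na(pm$atoms$map)))
    stop("internal corpus error: product atom without reactant origin")
  new_reaction(reactant_mols, pm, doc_id, rid)
}

# ---- route/document generation -------------------------------------------

generate_document <- function(spec, doc_id) {
  st <- new_gen_state()
  records <- list()
  fam_by_record <- character(0)
  tactical_ids <- character(0)
  leaves <- list()
  rid_ctr <- 0L
  next_rid <- function() { rid_ctr <<- rid_ctr + 1L; sprintf("r%03d", rid_ctr) }
  add_record <- function(rxn, fam, tactical = FALSE) {
    records[[length(records) + 1L]] <<- rxn
    fam_by_record[rxn$record_id] <<- fam
    if (tactical) tactical_ids <<- c(tactical_ids, rxn$record_id)
  }
  add_leaf <- function(piece) {
    leaves[[length(leaves) + 1L]] <<-
      list(smiles = piece$smiles,
           variant = if (is.na(piece$variant)) piece$smiles
                     else canonical_serialize(parse_smiles(piece$variant)))
  }
  add_donor_leaf <- function(donor) {
    cs <- canonical_serialize(donor)
    leaves[[length(leaves) + 1L]] <<- list(smiles = cs, variant = cs)
  }

  protection_plan <- stats::runif(1) < spec$p_protection
  if (protection_plan) {
    # protect -> one scaffold step -> deprotect -> final N-acylation
    mid_fams <- intersect(spec$families,
                          c("suzuki", "buchwald", "sonogashira", "amide",
                            "ester", "ether"))
    if (!length(mid_fams)) mid_fams <- "suzuki"
    fam1 <- sample(mid_fams, 1L)
    h1 <- family_w_handle(fam1)
    h1key <- if (h1 == "acyl") sample(c("acyl_Cl", "acyl_OMe"), 1L) else h1
    smi <- ring_smiles(HANDLE_PREFIX[[h1key]], "(N)")
    W <- make_piece(st, smi, h1key, nxt_type = "NH2",
                    variant = sub(paste0("^", gsub("([()])", "\\\\\\1",
                                                   HANDLE_PREFIX[[h1key]])),
                                  VARIANT_PREFIX[[h1key]], smi))
    add_leaf(W)
    nh <- W$nxt
    # protect
    pr <- do_protect_n(st, W, nh)
    donor_mol <- pr$donor
    add_donor_leaf(donor_mol)
    prod1 <- pr$mol
    add_record(emit_record(doc_id, next_rid(), list(W$mol, donor_mol), prod1),
               "boc_protection", tactical = TRUE)
    Wm <- list(mol = prod1, handle = W$handle)
    # scaffold step
    P <- make_partner(st, fam1, NULL)
    add_leaf(P)
    prod2 <- do_couple(Wm, P)
    add_record(emit_record(doc_id, next_rid(), list(Wm$mol, P$mol), prod2),
               fam1)
    # deprotect
    prod3 <- do_deprotect_n(prod2, pr$nh)
    add_record(emit_record(doc_id, next_rid(), list(prod2), prod3),
               "boc_deprotection", tactical = TRUE)
    # final N-acylation on the freed amine
    Wf <- list(mol = prod3,
               handle = list(type = "NH2", attach = nh$attach,
                             lv = integer(0), hloss = 1L))
    Pf <- make_partner(st, "amide_on_amine", NULL)
    add_leaf(Pf)
    prod4 <- do_couple(Pf, Wf)  # acyl partner's attach bonds to W's N
    add_record(emit_record(doc_id, next_rid(), list(prod3, Pf$mol), prod4),
               "amide_on_amine")
    target <- prod4
  } else {
    n_steps <- spec$min_steps +
      sample.int(spec$max_steps - spec$min_steps + 1L, 1L) - 1L
    fams <- sample(spec$families, n_steps, replace = TRUE)
    want_fgi <- stats::runif(1) < spec$p_tactical
    detour_step <- 0L
    if (want_fgi) {
      cand <- which(fams %in% c("suzuki", "amide", "ester"))
      if (!length(cand)) { fams[1] <- "suzuki"; cand <- 1L }
      detour_step <- cand[1]
    }
    use_obn <- stats::runif(1) < spec$p_obn
    # start piece
    h1 <- family_w_handle(fams[1])
    h1key <- if (h1 == "acyl") {
      if (detour_step == 1L) "acyl_OH" else sample(c("acyl_Cl", "acyl_OMe"), 1L)
    } else if (h1 == "Br" && detour_step == 1L && fams[1] == "suzuki") {
      "OH"
    } else h1
    extra <- if (use_obn) "(OCc2ccccc2)" else ""
    smi <- ring_smiles(HANDLE_PREFIX[[h1key]], "", extra = extra,
                       allow_ome = !use_obn)
    W <- make_piece(st, smi, h1key,
                    variant = sub(paste0("^", gsub("([()])", "\\\\\\1",
                                                   HANDLE_PREFIX[[h1key]])),
                                  VARIANT_PREFIX[[h1key]], smi))
    W$ring_attach <- {
      h <- locate_handle(W$mol, h1key,
                         region = seq_len(PREFIX_NATOMS[[h1key]]))
      adjW <- mol_adjacency(W$mol)
      nb <- adjW[[h$attach]]
      ar <- nb[W$mol$atoms$arom[nb]]
      if (length(ar)) W$mol$atoms$uid[ar[1]] else W$mol$atoms$uid[h$attach]
    }
    obn <- NULL
    if (use_obn) {
      # locate the benzyl-protected oxygen: O with a CH2 neighbour that has
      # an aromatic neighbour in a second ring
      a <- W$mol$atoms; adjW <- mol_adjacency(W$mol)
      o <- which(a$elem == "O" & a$nH == 0L &
                   vapply(seq_len(n_atoms(W$mol)), function(i) {
                     nb <- adjW[[i]]
                     any(a$elem[nb] == "C" & !a$arom[nb] & a$nH[nb] == 2L)
                   }, FALSE))
      o <- o[1]
      ch2 <- adjW[[o]][a$elem[adjW[[o]]] == "C" & !a$arom[adjW[[o]]]][1]
      ring2 <- setdiff(adjW[[ch2]], o)
      # collect the benzyl: CH2 + its aromatic ring
      bn <- ch2
      queue <- ring2
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        if (v %in% bn || v == o) next
        bn <- c(bn, v)
        queue <- c(queue, setdiff(adjW[[v]], bn))
      }
      obn <- list(o = W$mol$atoms$uid[o], bn = W$mol$atoms$uid[bn])
    }
    add_leaf(W)
    for (s in seq_len(n_steps)) {
      fam <- fams[s]
      if (s == detour_step) {
        if (fam == "suzuki") {
          fgi <- do_fgi_otf(st, W)
          add_donor_leaf(fgi$donor)
          add_record(emit_record(doc_id, next_rid(),
                                 list(W$mol, fgi$donor), fgi$W$mol),
                     "fgi_oh_otf", tactical = TRUE)
          W <- fgi$W
        } else {
          fgi <- do_fgi_acyl_cl(st, W)
          add_donor_leaf(fgi$donor)
          add_record(emit_record(doc_id, next_rid(),
                                 list(W$mol, fgi$donor), fgi$W$mol),
                     "fgi_acid_chloride", tactical = TRUE)
          W <- fgi$W
        }
      }
      nxt_type <- if (s < n_steps) {
        h <- family_w_handle(fams[s + 1])
        if (h == "acyl") {
          if (detour_step == s + 1L) "acyl_OH"
          else sample(c("acyl_Cl", "acyl_OMe"), 1L)
        } else if (h == "Br" && detour_step == s + 1L &&
                   fams[s + 1] == "suzuki") "OH"
        else h
      } else NULL
      convergent <- s == n_steps && stats::runif(1) < spec$p_convergent &&
        fam %in% c("amide", "ester", "buchwald", "sulfonamide",
                   "amide_on_amine")
      if (convergent) {
        # partner assembled by a prefab biaryl coupling
        pfam <- fam
        ph <- family_w_handle(pfam)
        phkey <- if (ph == "acyl") sample(c("acyl_Cl", "acyl_OMe"), 1L) else ph
        # partner-side handles differ from W-side for these families:
        pkey <- switch(pfam, amide = "NH2", buchwald = "NH2",
                       sulfonamide = "NH2", ester = "OH",
                       amide_on_amine = phkey)
        smi2 <- ring_smiles("Br", HANDLE_SUFFIX[[pkey]])
        base <- make_piece(st, smi2, "Br", nxt_type = pkey,
                           variant = sub("^Br", "I", smi2))
        add_leaf(base)
        boro <- make_partner(st, "suzuki", NULL)
        add_leaf(boro)
        prefab <- do_couple(base, boro)
        add_record(emit_record(doc_id, next_rid(),
                               list(base$mol, boro$mol), prefab),
                   "suzuki")
        P <- list(mol = prefab, handle = base$nxt)
      } else {
        P <- make_partner(st, fam, nxt_type)
        add_leaf(P)
      }
      if (fam == "amide_on_amine") {
        prod <- do_couple(P, W)  # acyl partner attacks W's amine
      } else {
        prod <- do_couple(W, P)
      }
      add_record(emit_record(doc_id, next_rid(), list(W$mol, P$mol), prod),
                 fam)
      newW <- list(mol = prod, handle = P$nxt)
      if (!is.null(P$nxt) && P$nxt$type %in% c("Br", "OH")) {
        # ring attach for a possible OTf detour next step
        idx <- uid_idx(prod, P$nxt$attach)
        adjP <- mol_adjacency(prod)
        nb <- adjP[[idx]]
        ar <- nb[prod$atoms$arom[nb]]
        newW$ring_attach <- if (length(ar)) prod$atoms$uid[ar[1]]
                            else P$nxt$attach
      }
      W <- newW
    }
    target <- W$mol
    if (use_obn) {
      prod <- do_deprotect_obn(target, obn)
      add_record(emit_record(doc_id, next_rid(), list(target), prod),
                 "obn_deprotection")
      target <- prod
    }
  }

  # ground truth from persistent atom identities
  tgt_uids <- target$atoms$uid
  tgt_nH <- stats::setNames(target$atoms$nH, target$atoms$uid)
  gt_mol <- function(m) {
    uid <- m$atoms$uid
    core <- uid %in% tgt_uids
    lv_maps <- m$atoms$map[!core]
    lh <- integer(0)
    for (i in which(core)) {
      d <- m$atoms$nH[i] - tgt_nH[[as.character(uid[i])]]
      if (d > 0L) lh[as.character(m$atoms$map[i])] <- d
    }
    list(leaving_maps = sort(lv_maps), leaving_h = lh)
  }
  gt <- lapply(records, function(r) {
    list(record_id = r$record_id,
         product = gt_mol(r$product),
         reactants = lapply(r$reactants, gt_mol))
  })
  names(gt) <- vapply(records, function(r) r$record_id, "")

  list(doc_id = doc_id, records = records,
       target = canonical_serialize(target),
       tactical_ids = tactical_ids, family = fam_by_record,
       leaves = leaves, ground_truth = gt)
}

#' Generate a synthetic reaction corpus
#'
#' Runs the forward route assembler for every document under one seeded
#' random stream. The returned ground truth (leaving atom maps, leaving
#' hydrogen counts, tactical record ids, family labels) is derived from the
#' persistent atom identities used during assembly.
#'
#' @param spec Specification from \code{\link{corpus_spec}}.
#' @return Corpus object: \code{documents} (per-document record lists with
#'   ground truth), \code{spec}.
#' @export
generate_corpus <- function(spec) {
  if (!length(spec$families)) stop("empty family list")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  docs <- lapply(seq_len(spec$n_documents), function(d)
    generate_document(spec, sprintf("D%04d", d)))
  structure(list(documents = docs, spec = spec), class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat("<synthetic_corpus> ", length(x$documents), " documents, ",
      sum(vapply(x$documents, function(d) length(d$records), 0L)),
      " reactions\n", sep = "")
  invisible(x)
}

#' Write corpus records to a reaction record file
#' @param corpus Corpus object.
#' @param path Output path (tab-separated records).
#' @return Invisibly, the path.
#' @export
write_corpus_records <- function(corpus, path) {
  recs <- unlist(lapply(corpus$documents, function(d) d$records),
                 recursive = FALSE)
  write_reaction_records(recs, path)
}

#' Build a buyables catalog from corpus leaves
#'
#' The catalog holds the starting materials (route leaves, including
#' reagent donors). With \code{variant_expansion}, every leaf is replaced
#' by a different functional-group variant of the same abstracted form
#' (bromide to iodide, boronic acid to stannane, acid to ester, amine to
#' Boc-carbamate, ...), producing an adversarial stock that defeats exact
#' matching while remaining reachable by substructure matching.
#'
#' @param corpus Corpus object.
#' @param variant_expansion Replace leaves by variants (default FALSE).
#' @return A buyables catalog (see \code{\link{load_buyables}}).
#' @export
make_buyables <- function(corpus, variant_expansion = FALSE) {
  smi <- unlist(lapply(corpus$documents, function(d)
    vapply(d$leaves, function(l)
      if (variant_expansion) l$variant else l$smiles, "")))
  buyables_from_smiles(unique(smi))
}
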