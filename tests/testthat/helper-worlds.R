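# Shared fixtures. Worlds are generated in code under fixed seeds and
# memoised so expensive corpora are built once per test run.

.worlds <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.worlds[[key]])) .worlds[[key]] <- builder()
  .worlds[[key]]
}

# pipeline: corpus -> mined routes -> higher-level/concrete datasets
curate_corpus <- function(corp) {
  recs <- unlist(lapply(corp$documents, function(d) d$records),
                 recursive = FALSE)
  mined <- mine_routes(recs)
  hl <- mapply(function(r, p) build_higher_level_route(r, p),
               mined$routes, mined$provenances, SIMPLIFY = FALSE)
  cc <- lapply(mined$routes, concrete_route)
  list(corpus = corp, mined = mined, hl_routes = hl, cc_routes = cc,
       ds_hl = curate_dataset(hl), ds_cc = curate_dataset(cc))
}

# main study corpus: 100 multistep routes with planted detours
world_main <- function() memo("main", function() {
  spec <- corpus_spec(n_documents = 100L, p_tactical = 0.5,
                      p_protection = 0.15, p_obn = 0.15,
                      p_convergent = 0.25, min_steps = 2L, max_steps = 3L,
                      seed = 11L)
  w <- curate_corpus(generate_corpus(spec))
  w$cons_hl <- consolidate_templates(lapply(w$ds_hl$pairs, function(p) p$rxn))
  w$cons_cc <- consolidate_templates(lapply(w$ds_cc$pairs, function(p) p$rxn))
  w
})

# micro world for exhaustive planner oracles and fast pipeline tests
world_micro <- function() memo("micro", function() {
  spec <- corpus_spec(n_documents = 12L, p_tactical = 0.4,
                      p_protection = 0, p_obn = 0.2, p_convergent = 0,
                      min_steps = 1L, max_steps = 2L, seed = 5L)
  w <- curate_corpus(generate_corpus(spec))
  w$cons_hl <- consolidate_templates(lapply(w$ds_hl$pairs, function(p) p$rxn))
  w$cons_cc <- consolidate_templates(lapply(w$ds_cc$pairs, function(p) p$rxn))
  w$stock_exact <- make_buyables(w$corpus, FALSE)
  w$stock_var <- make_buyables(w$corpus, TRUE)
  w
})

# single-step family-classification corpus (10 families, >= 2000 pairs)
world_model <- function() memo("model", function() {
  spec <- corpus_spec(n_documents = 1700L, p_tactical = 0.3,
                      p_protection = 0, p_obn = 0.3, p_convergent = 0,
                      min_steps = 1L, max_steps = 1L, seed = 101L)
  w <- curate_corpus(generate_corpus(spec))
  stopifnot(length(w$ds_hl$pairs) >= 2000L)
  w$ds_hl$pairs <- w$ds_hl$pairs[seq_len(2000L)]
  w$ds_hl$keys <- w$ds_hl$keys[seq_len(2000L)]
  w$cons_hl <- consolidate_templates(lapply(w$ds_hl$pairs, function(p) p$rxn))
  w$split <- split_dataset(w$ds_hl, seed = 101L)
  w$model <- train_classifier(
    w$ds_hl, w$cons_hl, w$split$train, w$split$valid,
    config = list(bits = 1024L, radius = 2L, hidden = 128L, epochs = 30L,
                  lr = 0.05, batch = 64L, momentum = 0.9, patience = 5L,
                  seed = 101L))
  w
})

# reorder atoms of a molecule by permutation (new row k = old row perm[k])
mol_permute <- function(mol, perm) {
  pos <- integer(length(perm))
  pos[perm] <- seq_along(perm)
  b <- mol$bonds
  b$a1 <- pos[b$a1]
  b$a2 <- pos[b$a2]
  m <- mol
  m$atoms <- mol$atoms[perm, , drop = FALSE]
  rownames(m$atoms) <- NULL
  m$bonds <- b
  m
}

# exhaustive breadth-limited solvability oracle: a molecule is solvable at
# depth d when it matches the stock, or some template application yields a
# precursor set entirely solvable at depth d - 1
bfs_oracle <- function(mol, templates, cat, depth, mode = "substructure") {
  memo_env <- new.env(parent = emptyenv())
  solv <- function(m, d) {
    key <- paste0(canonical_serialize(m), "@", d)
    v <- memo_env[[key]]
    if (!is.null(v)) return(v)
    if (length(match_buyables(m, cat, mode = mode))) {
      memo_env[[key]] <- TRUE
      return(TRUE)
    }
    if (d <= 0L) { memo_env[[key]] <- FALSE; return(FALSE) }
    counts <- retrosynthon:::elem_counts(m)
    for (tpl in templates) {
      if (!retrosynthon:::template_can_match(tpl, counts)) next
      for (ps in apply_template(tpl, m)) {
        if (all(vapply(ps$mols, function(x) solv(x, d - 1L), FALSE))) {
          memo_env[[key]] <- TRUE
          return(TRUE)
        }
      }
    }
    memo_env[[key]] <- FALSE
    FALSE
  }
  solv(mol, depth)
}

add_marker_twice <- function(mol, at, classes) {
  for (cl in classes) mol <- retrosynthon:::add_marker(mol, at, cl)
  mol
}

# simple hand-mapped reactions reused across chem/template tests
amide_coupling_rxn <- function() {
  parse_mapped_reaction(paste0(
    "[Cl:1][C:2](=[O:3])[c:4]1[cH:5][cH:6][cH:7][cH:8][cH:9]1.",
    "[NH2:10][CH2:11][CH3:12]",
    ">>[O:3]=[C:2]([NH:10][CH2:11][CH3:12])",
    "[c:4]1[cH:5][cH:6][cH:7][cH:8][cH:9]1"), "doc", "r1")
}

abstract_amide_rxn <- function() {
  rx <- amide_coupling_rxn()
  new_rxn <- rx
  new_rxn$reactants <- list(
    abstract_molecule(rx$reactants[[1]], 1L),
    abstract_molecule(rx$reactants[[2]], integer(0),
                      leaving_h = c(1L, 0L, 0L)))
  new_rxn
}

# deprotection-style template: ArOH -> ArO-[HET]
deprotection_template <- function(radius = 0L) {
  rx <- parse_mapped_reaction(paste0(
    "[1*][O:1][c:2]1[cH:3][cH:4][cH:5][cH:6][cH:7]1",
    ">>[OH:1][c:2]1[cH:3][cH:4][cH:5][cH:6][cH:7]1"), "doc", "rdep")
  extract_template(rx, radius = radius)
}
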