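test_that("extracted templates replay their own reaction (concrete and abstracted)", {
  rx <- amide_coupling_rxn()
  arx <- abstract_amide_rxn()
  for (r in list(rx, arx)) for (rad in c(0L, 1L)) {
    tpl <- extract_template(r, radius = rad)
    expect_true(template_recovers(tpl, r))
  }
})

test_that("context radius grows the pattern monotonically", {
  rx <- abstract_amide_rxn()
  t0 <- extract_template(rx, radius = 0L)
  t1 <- extract_template(rx, radius = 1L)
  expect_lt(n_atoms(t0$prod), n_atoms(t1$prod))
  # radius-1 pattern contains the radius-0 pattern as a subgraph: every
  # changed atom map of t0 appears among t1's pattern maps
  expect_true(all(t0$tmaps %in% t1$tmaps))
})

test_that("null transformations are rejected", {
  rx <- parse_mapped_reaction("[CH3:1][OH:2]>>[CH3:1][OH:2]", "d", "null")
  expect_error(extract_template(rx), "null transformation")
})

test_that("template application proposes marker-bearing precursors", {
  at0 <- extract_template(abstract_amide_rxn(), radius = 0L)
  tgt <- parse_smiles("O=C(NCc1ccccc1)c1ccc(F)cc1")
  ps <- apply_template(at0, tgt)
  expect_length(ps, 1L)
  expect_true(any(grepl("\\[1\\*\\]", ps[[1]]$smiles)))
  expect_true(any(grepl("\\[2\\*\\]", ps[[1]]$smiles)))
  # no embedding: empty list
  expect_length(apply_template(at0, parse_smiles("c1ccccc1")), 0L)
})

test_that("equivalent embeddings in a symmetric product are deduplicated", {
  tpl <- deprotection_template(radius = 0L)
  hq <- parse_smiles("Oc1ccc(O)cc1")
  ps <- apply_template(tpl, hq)
  # two hydroxyls, one canonical precursor after dedup
  expect_length(ps, 1L)
  # three inequivalent hydroxyls give three distinct proposals
  triol <- parse_smiles("Oc1ccc(O)c(O)c1")
  expect_length(apply_template(tpl, triol), 3L)
})

test_that("consolidation assigns the most general recovering template", {
  # benzylamine vs aniline amides share a rewrite but differ at radius 1;
  # the radius-0 template recovers both, so both are assigned to it
  mk <- function(amine_part, product_part) {
    rx <- parse_mapped_reaction(paste0(
      "[Cl:1][C:2](=[O:3])[CH3:4].", amine_part, ">>", product_part),
      "d", amine_part)
    rx$reactants <- list(abstract_molecule(rx$reactants[[1]], 1L),
                         abstract_molecule(rx$reactants[[2]], integer(0),
                                           leaving_h = c(1L, rep(0L, 20L))[
                                             seq_len(n_atoms(rx$reactants[[2]]))]))
    rx
  }
  r_alkyl <- mk("[NH2:10][CH2:11][CH3:12]",
                "[CH3:4][C:2](=[O:3])[NH:10][CH2:11][CH3:12]")
  r_aryl <- mk("[NH2:10][c:11]1[cH:12][cH:13][cH:14][cH:15][cH:16]1",
               "[CH3:4][C:2](=[O:3])[NH:10][c:11]1[cH:12][cH:13][cH:14][cH:15][cH:16]1")
  cons <- consolidate_templates(list(r_alkyl, r_aryl))
  expect_equal(cons$assignment[1], cons$assignment[2])
  expect_lt(length(cons$templates), cons$pool_size)
  expect_length(cons$unrecovered, 0L)
  # the shared template still recovers both reactions when applied
  tpl <- cons$templates[[cons$assignment[1]]]
  expect_true(template_recovers(tpl, r_alkyl))
  expect_true(template_recovers(tpl, r_aryl))
})

test_that("consolidation never increases the unique-template count", {
  w <- world_micro()
  expect_lte(length(w$cons_hl$templates), w$cons_hl$pool_size)
  expect_lte(length(w$cons_cc$templates), w$cons_cc$pool_size)
  # a reaction recoverable only by its own template keeps it
  single <- consolidate_templates(list(abstract_amide_rxn()))
  expect_equal(single$assignment, 1L)
})
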