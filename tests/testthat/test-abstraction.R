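test_that("marker classes follow the electronegativity rule", {
  expect_equal(classify_marker("C", "Br"), marker_classes()[["C_PLUS"]])
  expect_equal(classify_marker("C", "Cl"), marker_classes()[["C_PLUS"]])
  expect_equal(classify_marker("C", "O"), marker_classes()[["C_PLUS"]])
  expect_equal(classify_marker("C", "B"), marker_classes()[["C_MINUS"]])
  expect_equal(classify_marker("C", "Sn"), marker_classes()[["C_MINUS"]])
  # an enolate-type C-H nucleophile: hydrogen is below the carbon band
  expect_equal(classify_marker("C", "H"), marker_classes()[["C_MINUS"]])
  expect_equal(classify_marker("C", "C"), marker_classes()[["C_NEUTRAL"]])
  expect_equal(classify_marker("O", "C"), marker_classes()[["HET"]])
  expect_equal(classify_marker("N", "C"), marker_classes()[["HET"]])
  expect_error(classify_marker("C", "Xx"), "electronegativity table")
})

test_that("acid, ester and acyl chloride abstract to one acyl equivalent", {
  ab <- function(s, lv) canonical_serialize(
    abstract_molecule(parse_smiles(s), lv))
  acid <- ab("CC(=O)O", 4L)
  ester <- ab("CC(=O)OC", c(4L, 5L))
  chloride <- ab("CC(=O)Cl", 4L)
  expect_identical(acid, ester)
  expect_identical(acid, chloride)
  expect_match(acid, "\\[2\\*\\]", all = FALSE)
})

test_that("halide and triflate give one aryl electrophile form", {
  br <- parse_smiles("Brc1ccccc1")
  a1 <- canonical_serialize(abstract_molecule(br, which(br$atoms$elem == "Br")))
  tf <- parse_smiles("c1ccccc1OS(=O)(=O)C(F)(F)F")
  a2 <- canonical_serialize(abstract_molecule(tf, which(!tf$atoms$arom)))
  expect_identical(a1, a2)
  # the boronic acid abstracts to the nucleophilic class instead
  bo <- parse_smiles("OB(O)c1ccccc1")
  a3 <- canonical_serialize(abstract_molecule(bo, which(!bo$atoms$arom)))
  expect_false(identical(a1, a3))
})

test_that("abstraction is the identity for empty leaving sets", {
  m <- parse_smiles("CC(=O)Nc1ccccc1")
  out <- abstract_molecule(m, integer(0))
  expect_identical(canonical_serialize(out), canonical_serialize(m))
  # and idempotent on an already-abstracted molecule
  am <- parse_smiles("[2*]c1ccccc1")
  expect_identical(canonical_serialize(abstract_molecule(am, integer(0))),
                   canonical_serialize(am))
})

test_that("spectator molecules are dropped with a NULL signal", {
  m <- parse_smiles("CCO")
  expect_null(abstract_molecule(m, 1:3))
})

test_that("tactical steps are exactly the leaving-group interconversions", {
  # R-OH -> R-OTf with the O leaving downstream: both sides one aryl C(+)
  phen <- parse_smiles("Oc1ccccc1")
  otf <- parse_smiles("c1ccccc1OS(=O)(=O)C(F)(F)F")
  step <- list(
    reactants = list(abstract_molecule(phen, which(!phen$atoms$arom))),
    product = abstract_molecule(otf, which(!otf$atoms$arom)))
  expect_true(is_tactical(step))
  # a biaryl coupling builds a core bond: not tactical
  br <- parse_smiles("Brc1ccccc1")
  bo <- parse_smiles("OB(O)c1ccccc1")
  bi <- parse_smiles("c1ccc(cc1)-c1ccccc1")
  step2 <- list(
    reactants = list(abstract_molecule(br, 1L),
                     abstract_molecule(bo, which(!bo$atoms$arom))),
    product = bi)
  expect_false(is_tactical(step2))
  # ester hydrolysis where the acid oxygen is retained: the retained O-H is
  # concrete in the product, so the two sides differ
  est <- parse_smiles("CC(=O)OC")
  acid <- parse_smiles("CC(=O)O")
  step3 <- list(reactants = list(abstract_molecule(est, 5L)),
                product = acid)
  expect_false(is_tactical(step3))
})

test_that("an FGI-enabled coupling collapses three reactions to two steps", {
  phenol <- "[OH:1][c:2]1[cH:3][cH:4][c:5]([CH3:6])[cH:7][cH:8]1"
  tf2o <- paste0("[S:9](=[O:10])(=[O:11])([C:12]([F:13])([F:14])[F:15])",
                 "[O:16][S:17](=[O:18])(=[O:19])[C:20]([F:21])([F:22])[F:23]")
  otf <- paste0("[O:1]([c:2]1[cH:3][cH:4][c:5]([CH3:6])[cH:7][cH:8]1)",
                "[S:9](=[O:10])(=[O:11])[C:12]([F:13])([F:14])[F:15]")
  bor <- "[B:30]([OH:31])([OH:32])[c:33]1[cH:34][cH:35][cH:36][cH:37][cH:38]1"
  biaryl <- paste0("[CH3:6][c:5]1[cH:4][cH:3][c:2]([c:33]2[cH:34][cH:35]",
                   "[cH:36][cH:37][cH:38]2)[cH:8][cH:7]1")
  # the boronate carries an amine used in a third scaffold step, so only
  # the triflation is tactical
  bor2 <- sub("\\[cH:37\\]", "[c:37]([NH2:40])", bor)
  arno2 <- sub("\\[cH:37\\]", "[c:37]([NH2:40])", biaryl)
  final <- paste0("[CH3:6][c:5]1[cH:4][cH:3][c:2]([c:33]2[cH:34][cH:35]",
                  "[cH:36][c:37]([NH:40][CH3:41])[cH:38]2)[cH:8][cH:7]1")
  rec3 <- paste0(arno2, ".[CH3:41][Br:42]>>", final)
  recs <- list(
    parse_mapped_reaction(paste0(phenol, ".", tf2o, ">>", otf), "d", "r1"),
    parse_mapped_reaction(paste0(otf, ".", bor2, ">>", arno2), "d", "r2"),
    parse_mapped_reaction(rec3, "d", "r3"))
  rt <- extract_routes(build_network(recs))[[1]]
  expect_equal(rt$n_reactions, 3L)
  hl <- build_higher_level_route(rt, trace_provenance(rt))
  expect_equal(hl$n_reactions, 2L)
  expect_equal(hl$removed, "r1")
})

test_that("higher-level routes never exceed concrete depth or size", {
  w <- world_micro()
  for (i in seq_along(w$hl_routes)) {
    expect_lte(w$hl_routes[[i]]$depth, w$mined$routes[[i]]$depth)
    expect_lte(w$hl_routes[[i]]$n_reactions, w$mined$routes[[i]]$n_reactions)
  }
})

test_that("curation deduplicates pairs and honours exclusions", {
  w <- world_micro()
  ds <- w$ds_hl
  expect_equal(length(unique(ds$keys)), length(ds$keys))
  expect_true(all(vapply(ds$pairs, function(p)
    p$count == length(p$precedents), FALSE)))
  # excluding the first two pairs removes exactly those
  ds2 <- curate_dataset(w$hl_routes, exclusions = ds$keys[1:2])
  expect_length(ds2$pairs, length(ds$pairs) - 2L)
  expect_false(any(ds$keys[1:2] %in% ds2$keys))
})
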