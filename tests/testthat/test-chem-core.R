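test_that("well-formed mapped reactions parse and round-trip", {
  rx <- parse_mapped_reaction(
    "[CH3:1][C:2](=[O:3])Cl.[NH2:4][CH3:5]>>[CH3:1][C:2](=[O:3])[NH:4][CH3:5]",
    "d", "r1")
  expect_length(rx$reactants, 2L)
  expect_equal(heavy_atom_count(rx$product), 5L)
  expect_true(all(retrosynthon:::mol_maps(rx$product) > 0L))
  # serialize-parse-serialize is identity
  s <- reaction_smiles(rx)
  rx2 <- parse_mapped_reaction(s, "d", "r1")
  expect_identical(reaction_smiles(rx2), s)
})

test_that("malformed and degenerate records are rejected with clear signals", {
  expect_error(parse_mapped_reaction("not-a-smiles>>C", "d", "bad"),
               "parse error")
  expect_error(parse_mapped_reaction("CC>>", "d", "noprod"), class = "record_skip")
  # multi-product records keep the largest product by heavy atoms
  rx <- parse_mapped_reaction("[CH3:1][CH2:2][OH:3]>>[CH3:1][CH2:2]O.[OH:3]",
                              "d", "multi")
  expect_equal(heavy_atom_count(rx$product), 3L)
  expect_error(parse_mapped_reaction("[CH3:1]O>>[CH3:1].O", "d", "multi2",
                                     multi_product = "reject"),
               class = "record_skip")
})

test_that("validate_mapping reports every violation and nothing else", {
  clean <- amide_coupling_rxn()
  expect_equal(nrow(validate_mapping(clean)), 0L)
  dup <- parse_mapped_reaction("[CH3:1][CH2:1][OH:2]>>[CH3:1][CH:1]=[O:2]",
                               "d", "dup")
  expect_true("duplicate map" %in% validate_mapping(dup)$type)
  orphan <- parse_mapped_reaction("[CH3:1][OH:2]>>[CH3:1][O:2][CH3:9]",
                                  "d", "orph")
  expect_true("orphan product atom" %in% validate_mapping(orphan)$type)
  unmapped <- parse_mapped_reaction("[CH3:1][OH:2]>>[CH3:1]OC", "d", "um")
  expect_true("incomplete mapping" %in% validate_mapping(unmapped)$type)
})

test_that("canonical serialization is invariant to atom input order", {
  # full enumeration on a small molecule: every atom order, one string
  m <- parse_smiles("CC(=O)O")
  perms <- expand.grid(rep(list(1:4), 4))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4L), ]
  strs <- apply(perms, 1, function(p)
    canonical_serialize(mol_permute(m, as.integer(p))))
  expect_length(unique(strs), 1L)
})

test_that("canonicalization is a congruence over many random relabelings", {
  w <- world_micro()
  mols <- unlist(lapply(w$corpus$documents, function(d)
    lapply(d$records, function(r) c(r$reactants, list(r$product)))),
    recursive = FALSE)
  mols <- unlist(mols, recursive = FALSE)
  set.seed(99)
  mols <- mols[sample.int(length(mols), min(120L, length(mols)))]
  for (m in mols) {
    ref <- canonical_serialize(m)
    perm <- sample.int(n_atoms(m))
    expect_identical(canonical_serialize(mol_permute(m, perm)), ref)
  }
})

test_that("marker classes are part of molecular identity", {
  plus <- parse_smiles("[2*]c1ccccc1")
  minus <- parse_smiles("[3*]c1ccccc1")
  expect_false(identical(canonical_serialize(plus),
                         canonical_serialize(minus)))
  # multiplicity-aware and insertion-order independent
  base <- parse_smiles("CC")
  a <- add_marker_twice(base, 1L, c(1L, 1L))
  b <- add_marker_twice(base, 1L, c(1L, 1L))
  expect_identical(canonical_serialize(a), canonical_serialize(b))
  expect_equal(sum(a$atoms$elem == "*"), 1L)
  expect_equal(a$atoms$mult[a$atoms$elem == "*"], 2L)
  # doubled marker survives serialization round-trip
  expect_identical(canonical_serialize(parse_smiles(canonical_serialize(a))),
                   canonical_serialize(a))
})

test_that("aromatic, charged, and multi-fragment molecules round-trip", {
  for (s in c("c1ccc2ccccc2c1", "C[N+](C)(C)C", "[O-]C(=O)c1ccccc1",
              "OS(=O)(=O)C(F)(F)F", "C#Cc1ccncc1", "CC(=O)Cl.NCC")) {
    cs <- canonical_serialize(parse_smiles(s))
    expect_identical(canonical_serialize(parse_smiles(cs)), cs)
  }
})
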