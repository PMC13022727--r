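test_that("fingerprints are deterministic and marker-class sensitive", {
  m <- parse_smiles("O=C(NCC)c1ccccc1")
  expect_identical(mol_fingerprint(m), mol_fingerprint(parse_smiles(
    canonical_serialize(m))))
  fp_plus <- mol_fingerprint(parse_smiles("[2*]c1ccccc1"))
  fp_minus <- mol_fingerprint(parse_smiles("[3*]c1ccccc1"))
  expect_false(identical(fp_plus, fp_minus))
  expect_equal(length(mol_fingerprint(m, bits = 512L)), 512L)
  expect_true(all(mol_fingerprint(m) >= 0L))
})

test_that("dataset splits are seeded partitions by unique pair", {
  w <- world_micro()
  sp1 <- split_dataset(w$ds_hl, seed = 7L)
  sp2 <- split_dataset(w$ds_hl, seed = 7L)
  expect_identical(sp1, sp2)
  all_idx <- sort(c(sp1$train, sp1$valid, sp1$test))
  expect_identical(all_idx, seq_along(w$ds_hl$pairs))
  expect_length(intersect(sp1$train, sp1$test), 0L)
  tiny <- list(pairs = w$ds_hl$pairs[1:5])
  expect_error(split_dataset(tiny), "too small")
})

test_that("a single-family corpus trains to perfect validation accuracy", {
  spec <- corpus_spec(n_documents = 30L, p_tactical = 0, p_protection = 0,
                      p_obn = 0, p_convergent = 0, min_steps = 1L,
                      max_steps = 1L, families = "amide", seed = 8L)
  w <- curate_corpus(generate_corpus(spec))
  cons <- consolidate_templates(lapply(w$ds_hl$pairs, function(p) p$rxn))
  sp <- split_dataset(w$ds_hl, seed = 8L)
  expect_warning(
    m <- train_classifier(w$ds_hl, cons, sp$train, sp$valid,
                          config = list(bits = 256L, hidden = 8L,
                                        epochs = 3L, seed = 8L)),
    "single-class")
  expect_equal(m$valid_top1, 1.0)
})

test_that("precursor ranking is ordered, deduplicated and honours k", {
  w <- world_micro()
  mp <- template_prior(w$cons_hl$templates)
  prod <- parse_smiles(w$ds_hl$pairs[[1]]$product)
  expect_length(rank_precursors(mp, w$cons_hl$templates, prod, 0L), 0L)
  entries <- rank_precursors(mp, w$cons_hl$templates, prod,
                             length(w$cons_hl$templates))
  expect_gt(length(entries), 0L)
  scores <- vapply(entries, function(e) e$score, 0)
  expect_true(all(diff(scores) <= 1e-12))
  # the recorded reactants appear among the proposals
  want <- w$ds_hl$pairs[[1]]$reactants
  expect_true(any(vapply(entries, function(e)
    identical(e$precursors, want), FALSE)))
})

test_that("pessimistic ranking counts the whole template block", {
  # one template, three inequivalent deprotection sites: the truth is found
  # in the top-3 but in neither the top-1 nor the top-2
  tpl <- deprotection_template(0L)
  triol <- "Oc1ccc(O)c(O)c1"
  psets <- apply_template(tpl, parse_smiles(triol))
  expect_length(psets, 3L)
  truth <- psets[[2]]$smiles
  ds <- list(pairs = list(list(product = triol, reactants = truth)))
  mp <- template_prior(list(tpl))
  pes <- top_k_accuracy(mp, list(tpl), ds, 1L, k_list = c(1L, 2L, 3L),
                        pessimistic = TRUE)
  expect_equal(pes$accuracy, c(0, 0, 100))
  opt <- top_k_accuracy(mp, list(tpl), ds, 1L, k_list = c(1L, 2L, 3L),
                        pessimistic = FALSE)
  expect_true(all(opt$accuracy >= pes$accuracy))
})

test_that("single-precursor templates make both conventions agree", {
  rx <- abstract_amide_rxn()
  tpl <- extract_template(rx, radius = 1L)
  ds <- list(pairs = list(list(
    product = canonical_serialize(rx$product),
    reactants = sort(vapply(rx$reactants, canonical_serialize, ""),
                     method = "radix"))))
  mp <- template_prior(list(tpl))
  pes <- top_k_accuracy(mp, list(tpl), ds, 1L, k_list = 1:3,
                        pessimistic = TRUE)
  opt <- top_k_accuracy(mp, list(tpl), ds, 1L, k_list = 1:3,
                        pessimistic = FALSE)
  expect_identical(pes$accuracy, opt$accuracy)
  expect_equal(pes$accuracy[1], 100)
})
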