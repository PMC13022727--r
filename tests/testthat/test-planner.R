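test_that("buyables catalogs canonicalize, deduplicate and keep metadata", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("CCO", "OCC", "c1ccccc1", "CC(=O)O", "NCC"), f)
  cat1 <- load_buyables(f)
  expect_length(cat1$strings, 4L)  # CCO and OCC are the same molecule
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("smiles,price", "CCO,1.5", "c1ccccc1,2.0"), f2)
  cat2 <- load_buyables(f2)
  expect_length(cat2$strings, 2L)
  expect_equal(cat2$metadata[[1]]$price, 1.5)
  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), f3)
  expect_length(load_buyables(f3)$strings, 0L)
})

test_that("substructure matching reverses the marker classification rule", {
  cat_b <- buyables_from_smiles(c("Brc1ccccc1", "Clc1ccccc1",
                                  "c1ccccc1OS(=O)(=O)C(F)(F)F",
                                  "OB(O)c1ccccc1"))
  q <- parse_smiles("[2*]c1ccccc1")  # aryl electrophile
  hits <- match_buyables(q, cat_b, mode = "substructure")
  expect_length(hits, 3L)  # all but the boronic acid
  expect_false(canonical_serialize(parse_smiles("OB(O)c1ccccc1")) %in% hits)
  qm <- parse_smiles("[3*]c1ccccc1")  # aryl nucleophile
  expect_identical(match_buyables(qm, cat_b, mode = "substructure"),
                   canonical_serialize(parse_smiles("OB(O)c1ccccc1")))
})

test_that("implicit hydrogens satisfy markers of hydrogen's own class", {
  cat_b <- buyables_from_smiles(c("NCc1ccccc1", "CC(C)(C)OC(=O)NCc1ccccc1"))
  q <- parse_smiles("[1*]NCc1ccccc1")  # amine with one abstracted attachment
  q$atoms$nH[q$atoms$elem == "N"] <- 1L
  hits <- match_buyables(q, cat_b, mode = "substructure")
  expect_length(hits, 2L)  # free amine via H, carbamate via substituent
  # exact mode requires the literal species
  expect_length(match_buyables(q, cat_b, mode = "exact"), 0L)
  conc <- parse_smiles("NCc1ccccc1")
  expect_length(match_buyables(conc, cat_b, mode = "exact"), 1L)
  # marker-free molecules require exact matching even in substructure mode
  expect_length(match_buyables(parse_smiles("NCCCC"), cat_b,
                               mode = "substructure"), 0L)
  # a C(-) marker on carbon is satisfied by hydrogen (terminal alkyne as
  # the nucleophilic coupling partner) but a C(+) marker is not
  alkynes <- buyables_from_smiles("C#Cc1ccccc1")
  qminus <- parse_smiles("[3*]C#Cc1ccccc1")
  expect_length(match_buyables(qminus, alkynes, mode = "substructure"), 1L)
  qplus <- parse_smiles("[2*]C#Cc1ccccc1")
  expect_length(match_buyables(qplus, alkynes, mode = "substructure"), 0L)
})

test_that("extra substituents away from marker positions block a match", {
  cat_b <- buyables_from_smiles("Brc1ccc(C)cc1")  # para-methyl extra
  q <- parse_smiles("[2*]c1ccccc1")
  expect_length(match_buyables(q, cat_b, mode = "substructure"), 0L)
})

test_that("a buyable target is solved with a zero-step route", {
  w <- world_micro()
  mp <- template_prior(w$cons_hl$templates)
  leaf <- w$stock_exact$strings[1]
  res <- run_search(leaf, mp, w$cons_hl$templates, w$stock_exact,
                    config = list(max_iterations = 5L))
  expect_true(res$success)
  expect_equal(res$routes[[1]]$n_reactions, 0L)
  expect_equal(res$iterations, 0L)
})

test_that("search results match the exhaustive oracle on a toy world", {
  w <- world_micro()
  mp <- template_prior(w$cons_hl$templates)
  targets <- vapply(w$corpus$documents[1:5], function(d) d$target, "")
  for (t in targets) {
    res <- run_search(t, mp, w$cons_hl$templates, w$stock_exact,
                      config = list(max_iterations = 400L, max_depth = 3L,
                                    expansion_width = 20L))
    oracle <- bfs_oracle(parse_smiles(t), w$cons_hl$templates,
                         w$stock_exact, 3L)
    expect_equal(res$success, oracle)
  }
})

test_that("with one model and stock, substructure solves a superset of exact", {
  w <- world_micro()
  mp <- template_prior(w$cons_hl$templates)
  targets <- vapply(w$corpus$documents[1:5], function(d) d$target, "")
  solved <- vapply(targets, function(t) {
    cfgs <- list(max_iterations = 120L, max_depth = 4L,
                 expansion_width = 20L)
    r_sub <- run_search(t, mp, w$cons_hl$templates, w$stock_exact,
                        config = c(cfgs, mode = "substructure"))
    r_ex <- run_search(t, mp, w$cons_hl$templates, w$stock_exact,
                       config = c(cfgs, mode = "exact"))
    if (r_ex$success) expect_true(r_sub$success)
    c(sub = r_sub$success, ex = r_ex$success)
  }, logical(2))
  # exact-string termination is a special case of substructure termination
  expect_true(all(solved["sub", ] >= solved["ex", ]))
})

test_that("route statistics and deltas follow the longest-linear-sequence rule", {
  steps_linear <- list(
    list(product = "A", template = 1L, precursors = "B"),
    list(product = "B", template = 1L, precursors = "C"))
  expect_equal(retrosynthon:::plan_route_depth(steps_linear), 2L)
  fake <- structure(list(success = TRUE, target = "A", iterations = 1L,
                         routes = list(list(depth = 3L, n_reactions = 3L))),
                    class = "plan_result")
  st <- route_stats(list(fake), list(fake))
  expect_equal(st$deltas$d_depth, 0L)
  expect_equal(success_rate(list(fake)), 100)
  empty <- structure(list(success = FALSE, target = "B", iterations = 5L,
                          routes = list()), class = "plan_result")
  expect_equal(success_rate(list(fake, empty)), 50)
  expect_equal(nrow(route_stats(list(empty))$per_route), 0L)
})
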