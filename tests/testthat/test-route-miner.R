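chain_records <- function() {
  list(
    parse_mapped_reaction("[CH3:1][CH2:2][OH:3]>>[CH3:1][CH:2]=[O:3]",
                          "doc", "r1"),
    parse_mapped_reaction(
      "[CH3:1][CH:2]=[O:3].[NH2:4][CH3:5]>>[CH3:1][CH:2]=[N:4][CH3:5]",
      "doc", "r2"),
    parse_mapped_reaction("[CH3:1][CH:2]=[N:4][CH3:5]>>[CH3:1][CH2:2][NH:4][CH3:5]",
                          "doc", "r3"))
}

test_that("networks deduplicate molecules and reactions and break cycles", {
  net <- build_network(chain_records())
  expect_length(net$molecules, 5L)  # ethanol, aldehyde, amine, imine, product
  expect_length(net$edges, 3L)
  # duplicate reactant-product pair collapses to one edge
  net2 <- build_network(c(chain_records(), list(
    parse_mapped_reaction("[CH3:1][CH2:2][OH:3]>>[CH3:1][CH:2]=[O:3]",
                          "doc", "r9"))))
  expect_length(net2$edges, 3L)
  # A->B and B->A: the earlier record survives
  cyc <- list(
    parse_mapped_reaction("[CH3:1][CH2:2][OH:3]>>[CH3:1][CH:2]=[O:3]",
                          "d2", "r1"),
    parse_mapped_reaction("[CH3:1][CH:2]=[O:3]>>[CH3:1][CH2:2][OH:3]",
                          "d2", "r2"))
  netc <- build_network(cyc)
  expect_length(netc$edges, 1L)
  expect_equal(netc$reactions[[netc$edges[[1]]$reaction]]$record_id, "r1")
  expect_length(build_network(list())$edges, 0L)
})

test_that("route extraction yields one route per terminal product", {
  routes <- extract_routes(build_network(chain_records()))
  expect_length(routes, 1L)
  expect_equal(routes[[1]]$depth, 3L)
  expect_equal(routes[[1]]$n_reactions, 3L)
  # a single reaction yields a depth-1 route
  one <- extract_routes(build_network(chain_records()[1]))
  expect_equal(one[[1]]$depth, 1L)
})

test_that("route depth equals brute-force longest path on a convergent DAG", {
  # fake steps over distinct molecules: branch of 2 and branch of 3 feed a
  # final convergent step: depth 4, six reactions total
  mk <- function(rs, p) list(product = parse_smiles(p),
                             reactants = lapply(rs, parse_smiles),
                             document_id = "x", record_id = p)
  steps <- list(
    mk("C", "CC"), mk("CC", "CCC"),                       # branch A (2)
    mk("O", "CO"), mk("CO", "CCO"), mk("CCO", "CCCO"),    # branch B (3)
    mk(c("CCC", "CCCO"), "CCCOCCC"))                      # final step
  got <- retrosynthon:::route_depth(steps)
  # independent oracle: recursive longest-path enumeration
  longest <- function(p) {
    i <- which(vapply(steps, function(s) canonical_serialize(s$product), "") ==
                 canonical_serialize(parse_smiles(p)))
    if (!length(i)) return(0L)
    rs <- vapply(steps[[i]]$reactants, canonical_serialize, "")
    1L + max(vapply(rs, longest, 0L))
  }
  expect_equal(got, longest("CCCOCCC"))
  expect_equal(got, 4L)
  expect_equal(length(steps), 6L)
})

test_that("provenance identifies leaving atoms along a triflate coupling", {
  phenol <- "[OH:1][c:2]1[cH:3][cH:4][c:5]([CH3:6])[cH:7][cH:8]1"
  tf2o <- paste0("[S:9](=[O:10])(=[O:11])([C:12]([F:13])([F:14])[F:15])",
                 "[O:16][S:17](=[O:18])(=[O:19])[C:20]([F:21])([F:22])[F:23]")
  otf <- paste0("[O:1]([c:2]1[cH:3][cH:4][c:5]([CH3:6])[cH:7][cH:8]1)",
                "[S:9](=[O:10])(=[O:11])[C:12]([F:13])([F:14])[F:15]")
  bor <- "[B:30]([OH:31])([OH:32])[c:33]1[cH:34][cH:35][cH:36][cH:37][cH:38]1"
  biaryl <- paste0("[CH3:6][c:5]1[cH:4][cH:3][c:2]([c:33]2[cH:34][cH:35]",
                   "[cH:36][cH:37][cH:38]2)[cH:8][cH:7]1")
  recs <- list(
    parse_mapped_reaction(paste0(phenol, ".", tf2o, ">>", otf), "d", "r1"),
    parse_mapped_reaction(paste0(otf, ".", bor, ">>", biaryl), "d", "r2"))
  rt <- extract_routes(build_network(recs))[[1]]
  pv <- trace_provenance(rt)
  expect_true(pv$ok)
  i1 <- which(vapply(rt$steps, function(s) s$record_id, "") == "r1")
  p1 <- rt$steps[[i1]]$product
  # the phenol O and the whole triflyl group never reach the biaryl target
  expect_setequal(p1$atoms$elem[pv$steps[[i1]]$product$leaving],
                  c("O", "S", "O", "O", "C", "F", "F", "F"))
  # phenol reactant: only its oxygen leaves
  ph <- rt$steps[[i1]]$reactants[[1]]
  expect_equal(ph$atoms$elem[pv$steps[[i1]]$reactants[[1]]$leaving], "O")
  # the anhydride donor is a spectator: all atoms leaving
  don <- rt$steps[[i1]]$reactants[[2]]
  expect_equal(length(pv$steps[[i1]]$reactants[[2]]$leaving),
               heavy_atom_count(don))
  # a reaction keeping all reactant atoms has zero leaving atoms
  keep <- parse_mapped_reaction(
    "[CH3:1][CH:2]=[O:3]>>[CH3:1][CH2:2][OH:3]", "k", "r1")
  rk <- extract_routes(build_network(list(keep)))[[1]]
  pk <- trace_provenance(rk)
  expect_length(pk$steps[[1]]$reactants[[1]]$leaving, 0L)
})

test_that("provenance conserves core atoms across toy intermediates", {
  w <- world_micro()
  for (i in seq_along(w$mined$routes)[1:6]) {
    rt <- w$mined$routes[[i]]
    pv <- w$mined$provenances[[i]]
    tgt <- rt$steps[[length(rt$steps)]]$product
    n_target <- heavy_atom_count(tgt)
    for (j in seq_along(rt$steps)) {
      p <- rt$steps[[j]]$product
      n_core <- heavy_atom_count(p) - length(pv$steps[[j]]$product$leaving)
      expect_lte(n_core, n_target)
      expect_gt(n_core, 0L)
    }
  }
})

test_that("tree-shaped networks return routes covering every edge", {
  w <- world_micro()
  for (d in w$corpus$documents[1:6]) {
    net <- build_network(d$records)
    routes <- extract_routes(net)
    used <- unlist(lapply(routes, function(r)
      vapply(r$steps, function(s) s$record_id, "")))
    expect_setequal(used, vapply(net$edges, function(e)
      net$reactions[[e$reaction]]$record_id, ""))
  }
})
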