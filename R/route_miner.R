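#' @title Per-document reaction networks and multistep routes
#' @description
#' Builds a network of single-step reactions within one document (nodes are
#' canonical molecules, directed edges are reactions) and extracts multistep
#' routes ending at terminal products. Atom provenance is then traced from
#' each route target back to the starting materials to identify leaving
#' atoms, i.e. atoms whose lineage never reaches the target.
#' @name route_miner
NULL

#' Build a per-document reaction network
#'
#' Molecules are deduplicated by canonical string. Reactions whose reactant
#' set contains the product (self-loops) are removed; duplicated
#' reactant-product pairs keep the first record; directed cycles are broken
#' by dropping the later record (by record_id order).
#'
#' @param records List of reaction objects sharing one document.
#' @param document_id Document identifier (checked against records).
#' @return A network object: \code{molecules} (canonical strings),
#'   \code{edges} (data frame: reaction index, product node, reactant
#'   nodes), \code{reactions}.
#' @export
build_network <- function(records, document_id = NULL) {
  if (!length(records))
    return(structure(list(molecules = character(0),
                          edges = list(), reactions = list()),
                     class = "rxn_network"))
  if (is.null(document_id)) document_id <- records[[1]]$document_id
  stopifnot(all(vapply(records, function(r) r$document_id, "") == document_id))
  records <- records[order_c(vapply(records, function(r) r$record_id, ""))]

  mol_key <- new.env(parent = emptyenv())
  molecules <- character(0)
  node_of <- function(mol) {
    cs <- canonical_serialize(mol)
    if (is.null(mol_key[[cs]])) {
      molecules[[length(molecules) + 1L]] <<- cs
      mol_key[[cs]] <<- length(molecules)
    }
    mol_key[[cs]]
  }

  edges <- list()
  seen_pairs <- character(0)
  for (ri in seq_along(records)) {
    r <- records[[ri]]
    pnode <- node_of(r$product)
    rnodes <- vapply(r$reactants, node_of, 0L)
    if (pnode %in% rnodes) next  # self-loop / null transformation
    key <- paste(paste(sort(unique(rnodes)), collapse = ","), pnode, sep = ">")
    if (key %in% seen_pairs) next
    seen_pairs <- c(seen_pairs, key)
    edges[[length(edges) + 1L]] <-
      list(reaction = ri, product = pnode, reactants = rnodes)
  }

  # break directed cycles: process edges in record order, dropping any edge
  # that would close a cycle (the later record loses)
  reach <- function(adj, from, to) {
    # TRUE if `to` reachable from `from` via adj (list: node -> successors)
    seen <- logical(length(molecules))
    queue <- from
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (v == to) return(TRUE)
      if (seen[v]) next
      seen[v] <- TRUE
      queue <- c(queue, adj[[v]])
    }
    FALSE
  }
  adj <- rep(list(integer(0)), length(molecules))
  kept <- list()
  for (e in edges) {
    closes <- any(vapply(e$reactants, function(rn)
      reach(adj, e$product, rn), FALSE))
    if (closes) next
    kept[[length(kept) + 1L]] <- e
    for (rn in e$reactants)
      adj[[rn]] <- unique(c(adj[[rn]], e$product))
  }

  structure(list(molecules = molecules, edges = kept, reactions = records),
            class = "rxn_network")
}

#' Extract multistep routes from a network
#'
#' One route per terminal product (molecule node with no outgoing edge that
#' is produced by at least one reaction), containing all ancestor reactions
#' within \code{max_depth} steps of the target. When several kept reactions
#' produce one molecule inside a route, the earliest record is used so the
#' route is a well-defined DAG with a single producer per molecule.
#'
#' @param net Network from \code{\link{build_network}}.
#' @param max_depth Maximum number of reaction steps from the target
#'   (default 10).
#' @return List of route objects with fields \code{target} (canonical
#'   string), \code{steps} (list of reaction objects, leaf-to-target order),
#'   \code{depth}, \code{n_reactions}.
#' @export
extract_routes <- function(net, max_depth = 10L) {
  if (!length(net$edges)) return(list())
  produced <- vapply(net$edges, function(e) e$product, 0L)
  consumed <- unique(unlist(lapply(net$edges, function(e) e$reactants)))
  sinks <- setdiff(unique(produced), consumed)
  producer <- rep(NA_integer_, length(net$molecules))
  for (ei in seq_along(net$edges)) {
    p <- net$edges[[ei]]$product
    if (is.na(producer[p])) producer[p] <- ei  # edges are in record order
  }
  routes <- list()
  for (t in sinks) {
    sel <- integer(0)           # selected edge indices
    depth_of <- integer(0)      # per selected edge: steps from target
    queue <- list(list(node = t, d = 0L))
    seen_nodes <- integer(0)
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      if (q$node %in% seen_nodes) next
      seen_nodes <- c(seen_nodes, q$node)
      if (q$d >= max_depth) next
      ei <- producer[q$node]
      if (is.na(ei)) next
      if (!(ei %in% sel)) { sel <- c(sel, ei); depth_of <- c(depth_of, q$d + 1L) }
      for (rn in net$edges[[ei]]$reactants)
        queue[[length(queue) + 1L]] <- list(node = rn, d = q$d + 1L)
    }
    if (!length(sel)) next
    ord <- order(-depth_of)  # leaves first
    steps <- lapply(sel[ord], function(ei) net$reactions[[net$edges[[ei]]$reaction]])
    routes[[length(routes) + 1L]] <- structure(
      list(target = net$molecules[t], steps = steps,
           depth = max(depth_of), n_reactions = length(sel)),
      class = "route")
  }
  routes
}

#' @export
print.route <- function(x, ...) {
  cat("<route> target ", x$target, ": ", x$n_reactions, " reactions, depth ",
      x$depth, "\n", sep = "")
  invisible(x)
}

# Longest-path depth of a route recomputed from its steps (reaction count on
# the longest chain from any starting material to the target).
route_depth <- function(steps) {
  if (!length(steps)) return(0L)
  prods <- vapply(steps, function(s) canonical_serialize(s$product), "")
  d <- integer(length(steps))
  for (i in seq_along(steps)) {
    rs <- vapply(steps[[i]]$reactants, canonical_serialize, "")
    up <- d[match(rs, prods)]
    up <- up[!is.na(up)]
    d[i] <- 1L + if (length(up)) max(up) else 0L
  }
  max(d)
}

#' Trace atom provenance through a route
#'
#' Atoms of every molecule instance in the route are labelled core (their
#' lineage reaches the target) or leaving. Lineage follows atom-map numbers
#' within each reaction; across reactions, the product instance of one step
#' is aligned to the matching reactant instance of the consuming step by
#' canonical atom ranks. Implicit hydrogens present on a core atom in an
#' intermediate but absent on that atom's image in the target are recorded
#' as leaving hydrogen counts.
#'
#' @param route Route from \code{\link{extract_routes}}.
#' @return Provenance object: per step, \code{product} and \code{reactants}
#'   entries each holding \code{leaving} (atom indices) and \code{leaving_h}
#'   (per-atom counts); plus \code{ok}/\code{reason} flags. A broken map
#'   chain flags the route as excluded.
#' @export
trace_provenance <- function(route) {
  steps <- route$steps
  k <- length(steps)
  prods <- vapply(steps, function(s) canonical_serialize(s$product), "")
  # status per step product: core flag + target nH per atom
  prod_status <- vector("list", k)
  res <- vector("list", k)

  # producer step of each step's reactant molecules (by canonical string);
  # process target-to-leaves so every consumer is handled before the
  # producer it feeds (reverse-topological order on the route DAG)
  consumers <- vector("list", k)  # per step: steps consuming its product
  for (i in seq_len(k)) {
    rs <- unique(vapply(steps[[i]]$reactants, canonical_serialize, ""))
    for (cs in rs) {
      src <- which(prods == cs)
      src <- src[src != i]
      if (length(src))
        consumers[[src[length(src)]]] <- c(consumers[[src[length(src)]]], i)
  } }
  n_pending <- vapply(consumers, length, 0L)
  tgt <- steps[[k]]$product
  prod_status[[k]] <- list(core = rep(TRUE, n_atoms(tgt)),
                           tnH = tgt$atoms$nH)
  proc_order <- integer(0)
  ready <- which(n_pending == 0L)  # starts with the target step only
  done <- logical(k)
  while (length(ready)) {
    i <- ready[1]; ready <- ready[-1]
    if (done[i]) next
    done[i] <- TRUE
    proc_order <- c(proc_order, i)
    for (j in seq_len(k)) {
      if (!done[j] && i %in% consumers[[j]]) {
        n_pending[j] <- n_pending[j] - 1L
        if (n_pending[j] == 0L) ready <- c(ready, j)
      }
    }
  }
  if (length(proc_order) != k)
    return(structure(list(ok = FALSE, reason = "unconsumed intermediate product"),
                     class = "provenance"))
  for (i in proc_order) {
    st <- steps[[i]]
    status <- prod_status[[i]]
    if (is.null(status))
      return(structure(list(ok = FALSE,
                            reason = "unconsumed intermediate product"),
                       class = "provenance"))
    p <- st$product
    core_p <- which(status$core & p$atoms$elem != "*")
    leaving_p <- setdiff(which(p$atoms$elem != "*"), core_p)
    lH_p <- pmax(0L, p$atoms$nH - status$tnH)
    lH_p[!status$core] <- 0L
    res[[i]] <- list(
      product = list(leaving = leaving_p, leaving_h = lH_p),
      reactants = vector("list", length(st$reactants)))
    # push status onto reactants via map numbers
    pmap <- p$atoms$map
    for (j in seq_along(st$reactants)) {
      rm <- st$reactants[[j]]
      nr <- n_atoms(rm)
      core_r <- logical(nr)
      tnH_r <- rm$atoms$nH
      for (ai in seq_len(nr)) {
        if (rm$atoms$elem[ai] == "*") next
        mnum <- rm$atoms$map[ai]
        if (mnum > 0L) {
          pi <- which(pmap == mnum & p$atoms$elem != "*")
          if (length(pi) == 1L && status$core[pi]) {
            core_r[ai] <- TRUE
            tnH_r[ai] <- status$tnH[pi]
          }
        }
      }
      res[[i]]$reactants[[j]] <- list(
        leaving = which(!core_r & rm$atoms$elem != "*"),
        leaving_h = pmax(0L, rm$atoms$nH - tnH_r) * as.integer(core_r))
      # propagate to the producing step of this reactant, if any; merge
      # when one product instance feeds several consumers
      cs <- canonical_serialize(rm)
      src <- which(prods == cs)
      src <- src[src != i]
      if (length(src)) {
        src <- src[length(src)]
        al <- mol_align(steps[[src]]$product, rm)
        if (is.null(al))
          return(structure(list(ok = FALSE, reason = "broken map chain"),
                           class = "provenance"))
        new_core <- core_r[al]
        new_tnH <- tnH_r[al]
        old <- prod_status[[src]]
        if (!is.null(old)) {
          new_core <- new_core | old$core
          new_tnH <- pmax(new_tnH, old$tnH)
        }
        prod_status[[src]] <- list(core = new_core, tnH = new_tnH)
      }
    }
  }
  structure(list(ok = TRUE, steps = res), class = "provenance")
}
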