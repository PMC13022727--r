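#' @title Multistep retrosynthetic planning
#' @description
#' Monte Carlo tree search over abstracted intermediates. Chemical and
#' reaction nodes alternate in a search graph rooted at the query target;
#' each iteration selects an unexpanded, non-terminal chemical node by a
#' PUCT-style tree policy, expands it with the single-step model, marks new
#' nodes terminal when they match the buyables catalog (exact string match,
#' or substructure match in which marker positions admit any substituent
#' whose attachment atom satisfies the marker's electronegativity class, or
#' an implicit hydrogen where hydrogen's class matches), and updates ancestor
#' values. Marker-free molecules always require an exact match.
#' @name planner
NULL

#' Build a buyables catalog from canonical SMILES
#' @param smiles Character vector (canonicalized and deduplicated here).
#' @param metadata Optional data frame with one row per input string.
#' @return A \code{buyables} catalog.
#' @export
buyables_from_smiles <- function(smiles, metadata = NULL) {
  mols <- list()
  strs <- character(0)
  meta <- list()
  n_bad <- 0L
  for (i in seq_along(smiles)) {
    m <- tryCatch(parse_smiles(smiles[i]), error = function(e) NULL)
    if (is.null(m)) { n_bad <- n_bad + 1L; next }
    cs <- canonical_serialize(m)
    if (cs %in% strs) next
    strs <- c(strs, cs)
    mols[[length(mols) + 1L]] <- m
    meta[[length(meta) + 1L]] <- if (!is.null(metadata)) metadata[i, , drop = FALSE]
  }
  if (n_bad) warning(n_bad, " unparseable buyable line(s) skipped")
  counts <- lapply(mols, elem_counts)
  heavies <- vapply(mols, heavy_atom_count, 0L)
  structure(list(strings = strs, mols = mols, counts = counts,
                 heavy = heavies, metadata = meta, n_skipped = n_bad),
            class = "buyables")
}

#' @export
print.buyables <- function(x, ...) {
  cat("<buyables> ", length(x$strings), " molecules\n", sep = "")
  invisible(x)
}

#' Load a buyables catalog from a file
#'
#' Accepts a plain SMILES list (one per line) or a CSV with a
#' \code{smiles} column; other CSV columns are retained as metadata keyed
#' by canonical string.
#'
#' @param path File path.
#' @return A \code{buyables} catalog.
#' @export
load_buyables <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first)) return(buyables_from_smiles(character(0)))
  if (grepl(",", first) || grepl("^smiles$", trimws(first))) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!("smiles" %in% names(df)))
      stop("CSV buyables file needs a 'smiles' column")
    buyables_from_smiles(df$smiles, metadata = df)
  } else {
    lines <- trimws(readLines(path))
    buyables_from_smiles(lines[nzchar(lines)])
  }
}

# does buyable molecule `b` structurally match abstracted query `q`?
# Rule: the marker-free core of q embeds in b; every extra atom of b lies in
# a substituent hanging off a marker position; each marker unit is satisfied
# by a distinct attachment bond whose attachment atom satisfies the marker's
# electronegativity class, or by an implicit hydrogen whose class at that
# core atom (HET on heteroatoms, C(-) on carbon, as in the abstraction rule)
# equals the marker's; non-marker atoms admit no extra neighbours and must
# agree in H count.
substructure_match <- function(q, b, table = pauling_en(), threshold = 0.1) {
  markers <- which(q$atoms$elem == "*")
  core_idx <- which(q$atoms$elem != "*")
  core <- mol_subgraph(q, core_idx)
  nb <- n_atoms(b)
  if (heavy_atom_count(b) < n_atoms(core)) return(FALSE)
  # marker units per core atom (in core indexing)
  adjq <- mol_adjacency(q)
  munits <- vector("list", n_atoms(core))
  for (mi in markers) {
    at <- adjq[[mi]][1]
    ci <- match(at, core_idx)
    munits[[ci]] <- c(munits[[ci]], rep(q$atoms$marker[mi], q$atoms$mult[mi]))
  }
  ca <- core$atoms; ba <- b$atoms
  domains <- vector("list", n_atoms(core))
  for (i in seq_len(n_atoms(core))) {
    cand <- which(ba$elem == ca$elem[i] & ba$arom == ca$arom[i] &
                    ba$chg == ca$chg[i])
    if (is.null(munits[[i]])) cand <- cand[ba$nH[cand] == ca$nH[i]]
    else cand <- cand[ba$nH[cand] >= ca$nH[i]]
    if (!length(cand)) return(FALSE)
    domains[[i]] <- cand
  }
  embeds <- find_monomorphisms(core, b, domains)
  adjb <- mol_adjacency(b)
  for (mp in embeds) {
    inside <- logical(nb)
    inside[mp] <- TRUE
    ok <- TRUE
    extra_used <- logical(nb)
    for (i in seq_len(n_atoms(core))) {
      bi <- mp[i]
      extras <- setdiff(adjb[[bi]], mp)
      units <- munits[[i]]
      if (is.null(units)) {
        if (length(extras) || ba$nH[bi] != ca$nH[i]) { ok <- FALSE; break }
        next
      }
      # classify each extra attachment bond
      cls <- vapply(extras, function(j)
        classify_marker(ba$elem[bi], ba$elem[j], table, threshold), 0L)
      extra_h <- ba$nH[bi] - ca$nH[i]
      if (extra_h < 0L) { ok <- FALSE; break }
      # match multiset: every attachment consumes a unit of its class;
      # remaining units must be HET satisfied by extra hydrogens
      avail <- units
      good <- TRUE
      for (cl in cls) {
        hit <- match(cl, avail)
        if (is.na(hit)) { good <- FALSE; break }
        avail <- avail[-hit]
      }
      if (!good) { ok <- FALSE; break }
      # remaining units must be satisfiable by implicit hydrogens: an H at
      # this core atom classes as classify_marker(core, "H") (HET on
      # heteroatoms, C(-) on carbon, matching the abstraction's own rule)
      if (length(avail)) {
        h_class <- classify_marker(ba$elem[bi], "H", table, threshold)
        if (!all(avail == h_class) || extra_h != length(avail)) {
          ok <- FALSE; break
        }
      } else if (extra_h != 0L) { ok <- FALSE; break }
      extra_used[extras] <- TRUE
    }
    if (!ok) next
    # all non-embedded atoms must belong to substituents at marker atoms:
    # i.e. reachable from extra attachment atoms without crossing the core
    outside <- which(!inside)
    if (length(outside)) {
      seen <- logical(nb)
      queue <- which(extra_used)
      seen[queue] <- TRUE
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        for (w in adjb[[v]]) if (!seen[w] && !inside[w]) {
          seen[w] <- TRUE; queue <- c(queue, w)
        }
      }
      if (!all(seen[outside])) next
    }
    return(TRUE)
  }
  FALSE
}

#' Match a molecule against the buyables catalog
#'
#' Exact mode tests canonical-string membership. Substructure mode applies
#' the marker-aware structural matching rule; marker-free molecules fall
#' back to exact matching. At most \code{cap} matches are reported, sorted
#' by heavy-atom count then canonical string.
#'
#' @param mol Molecule (possibly abstracted).
#' @param cat Buyables catalog.
#' @param mode \code{"exact"} or \code{"substructure"}.
#' @param table,threshold Electronegativity configuration.
#' @param cap Maximum number of matches returned (default 10).
#' @return Character vector of matching buyable canonical strings.
#' @export
match_buyables <- function(mol, cat, mode = c("substructure", "exact"),
                           table = pauling_en(), threshold = 0.1,
                           cap = 10L) {
  mode <- match.arg(mode)
  cs <- canonical_serialize(mol)
  has_markers <- any(mol$atoms$elem == "*")
  if (mode == "exact" || !has_markers) {
    return(if (cs %in% cat$strings) cs else character(0))
  }
  qc <- elem_counts(mol)
  nheavy <- heavy_atom_count(mol)
  hits <- character(0)
  ord <- order(cat$heavy, match(cat$strings, sort_c(cat$strings)))
  for (i in ord) {
    if (cat$heavy[i] < nheavy) next
    bc <- cat$counts[[i]]
    compat <- all(vapply(names(qc), function(e)
      !is.na(bc[e]) && bc[e] >= qc[[e]], FALSE))
    if (!compat) next
    if (substructure_match(mol, cat$mols[[i]], table, threshold)) {
      hits <- c(hits, cat$strings[i])
      if (length(hits) >= cap) break
    }
  }
  hits
}

# ---- search ---------------------------------------------------------------

#' Run a multistep retrosynthetic tree search
#'
#' Iterates select-expand-update until the iteration budget is exhausted,
#' no expandable node remains, or (optionally) the root is solved. The tree
#' policy descends by a PUCT-style score (node value plus
#' \code{c * prior * sqrt(parent visits) / (1 + visits)}); node values are
#' the fraction of descendant chemical nodes resolved to buyables.
#' Molecule nodes are deduplicated graph-wide by canonical string and a
#' precursor identical to any of its ancestors is pruned.
#'
#' @param target Target molecule (SMILES string or molecule object).
#' @param model Relevance model (see \code{\link{predict_template_scores}}).
#' @param templates Template list the model indexes into.
#' @param cat Buyables catalog.
#' @param config List: \code{max_iterations} (100), \code{max_depth} (10),
#'   \code{expansion_width} (25), \code{exploration_const} (1.4),
#'   \code{mode} ("substructure" or "exact"), \code{stop_on_solve} (TRUE),
#'   \code{max_routes} (25), \code{table}, \code{threshold}, \code{seed}.
#' @return A \code{plan_result}: \code{success}, \code{iterations},
#'   \code{routes} (each with \code{steps}, \code{leaves},
#'   \code{buyable_matches}, \code{depth}, \code{n_reactions}),
#'   \code{n_nodes}.
#' @export
run_search <- function(target, model, templates, cat, config = list()) {
  cfg <- utils::modifyList(
    list(max_iterations = 100L, max_depth = 10L, expansion_width = 25L,
         exploration_const = 1.4, mode = "substructure",
         stop_on_solve = TRUE, max_routes = 25L,
         table = pauling_en(), threshold = 0.1, seed = 1L), config)
  if (is.character(target)) target <- parse_smiles(target)

  nodes <- list()   # chem nodes: mol, smiles, expanded, terminal, matches,
                    # visits, depth, rxn children (indices), parents (rxn)
  key2node <- new.env(parent = emptyenv())
  rxns <- list()    # reaction nodes: product (node), template, score,
                    # precursors (node indices), visits

  add_node <- function(mol, depth) {
    cs <- canonical_serialize(mol)
    if (!is.null(key2node[[cs]])) {
      i <- key2node[[cs]]
      nodes[[i]]$depth <<- min(nodes[[i]]$depth, depth)
      return(i)
    }
    matches <- match_buyables(mol, cat, mode = cfg$mode, table = cfg$table,
                              threshold = cfg$threshold)
    nodes[[length(nodes) + 1L]] <<- list(
      mol = mol, smiles = cs, expanded = FALSE,
      terminal = length(matches) > 0L, matches = matches,
      visits = 0L, depth = depth, children = integer(0),
      parents = integer(0))
    key2node[[cs]] <<- length(nodes)
    length(nodes)
  }

  root <- add_node(target, 0L)

  solved <- function(i) {
    n <- nodes[[i]]
    if (n$terminal) return(TRUE)
    for (ri in n$children) {
      pre <- rxns[[ri]]$precursors
      if (all(vapply(pre, solved_memo, FALSE))) return(TRUE)
    }
    FALSE
  }
  solved_cache <- new.env(parent = emptyenv())
  solved_memo <- function(i) {
    key <- as.character(i)
    v <- solved_cache[[key]]
    if (!is.null(v)) return(v)
    solved_cache[[key]] <- FALSE  # cycle guard
    v <- solved(i)
    solved_cache[[key]] <- v
    v
  }
  reset_solved <- function() solved_cache <<- new.env(parent = emptyenv())

  # value: fraction of descendant chem nodes (incl. self) resolved buyable
  value_of <- function(i, seen = integer(0)) {
    if (i %in% seen) return(c(0, 0))
    seen <- c(seen, i)
    n <- nodes[[i]]
    tot <- 1; res <- as.numeric(n$terminal)
    for (ri in n$children) for (p in rxns[[ri]]$precursors) {
      v <- value_of(p, seen)
      tot <- tot + v[1]; res <- res + v[2]
    }
    c(tot, res)
  }

  ancestors_of <- function(i) {
    seen <- integer(0)
    queue <- i
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (ri in nodes[[v]]$parents) {
        p <- rxns[[ri]]$product
        if (!(p %in% seen)) { seen <- c(seen, p); queue <- c(queue, p) }
      }
    }
    seen
  }

  select_node <- function() {
    # policy descent from root with cycle guard
    i <- root
    path <- integer(0)
    for (guard in seq_len(200L)) {
      n <- nodes[[i]]
      if (!n$expanded && !n$terminal && n$depth < cfg$max_depth) return(i)
      if (!length(n$children)) break
      scores <- vapply(n$children, function(ri) {
        r <- rxns[[ri]]
        vals <- vapply(r$precursors, function(p) {
          v <- value_of(p)
          if (v[1] > 0) v[2] / v[1] else 0
        }, 0)
        mean(vals) + cfg$exploration_const * r$score *
          sqrt(n$visits + 1) / (1 + r$visits)
      }, 0)
      ri <- n$children[order(-scores, n$children)][1]
      rxns[[ri]]$visits <<- rxns[[ri]]$visits + 1L
      pre <- rxns[[ri]]$precursors
      open <- pre[!vapply(pre, solved_memo, FALSE) &
                    !vapply(pre, function(p) p %in% path, FALSE)]
      if (!length(open)) break
      path <- c(path, i)
      i <- open[1]
    }
    # fallback: any unexpanded, non-terminal node within depth
    for (j in seq_along(nodes)) {
      n <- nodes[[j]]
      if (!n$expanded && !n$terminal && n$depth < cfg$max_depth) return(j)
    }
    0L
  }

  iterations <- 0L
  while (iterations < cfg$max_iterations) {
    reset_solved()
    if (cfg$stop_on_solve && solved_memo(root)) break
    i <- select_node()
    if (i == 0L) break
    iterations <- iterations + 1L
    n <- nodes[[i]]
    nodes[[i]]$expanded <- TRUE
    entries <- rank_precursors(model, templates, n$mol, cfg$expansion_width)
    anc <- c(ancestors_of(i), i)
    anc_strs <- vapply(anc, function(a) nodes[[a]]$smiles, "")
    for (e in entries) {
      if (any(e$precursors %in% anc_strs)) next  # loop guard
      pre_idx <- vapply(e$mols, function(m) add_node(m, n$depth + 1L), 0L)
      ri <- length(rxns) + 1L
      rxns[[ri]] <- list(product = i, template = e$template,
                         score = e$score, precursors = pre_idx, visits = 0L)
      nodes[[i]]$children <- c(nodes[[i]]$children, ri)
      for (p in pre_idx)
        nodes[[p]]$parents <- unique(c(nodes[[p]]$parents, ri))
    }
    # update visit counts along ancestors
    for (a in anc) nodes[[a]]$visits <- nodes[[a]]$visits + 1L
  }
  reset_solved()

  # ---- route extraction ----
  routes <- list()
  emit_routes <- function(i, path) {
    # returns list of partial routes; each: list(steps, leaves)
    n <- nodes[[i]]
    if (n$terminal)
      return(list(list(steps = list(),
                       leaves = stats::setNames(list(n$matches), n$smiles))))
    out <- list()
    for (ri in n$children) {
      r <- rxns[[ri]]
      if (!all(vapply(r$precursors, solved_memo, FALSE))) next
      if (any(r$precursors %in% path)) next
      sub <- list(list(steps = list(), leaves = list()))
      ok <- TRUE
      for (p in r$precursors) {
        pr <- emit_routes(p, c(path, i))
        if (!length(pr)) { ok <- FALSE; break }
        newsub <- list()
        for (s in sub) for (q in pr) {
          newsub[[length(newsub) + 1L]] <- list(
            steps = c(s$steps, q$steps),
            leaves = c(s$leaves, q$leaves))
          if (length(newsub) >= cfg$max_routes) break
        }
        sub <- newsub
      }
      if (!ok) next
      step <- list(product = n$smiles, template = r$template,
                   precursors = vapply(r$precursors,
                                       function(p) nodes[[p]]$smiles, ""))
      for (s in sub) {
        routes_new <- list(steps = c(s$steps, list(step)), leaves = s$leaves)
        out[[length(out) + 1L]] <- routes_new
        if (length(out) >= cfg$max_routes) return(out)
      }
    }
    out
  }
  if (solved_memo(root)) {
    raw <- emit_routes(root, integer(0))
    for (r in raw) {
      routes[[length(routes) + 1L]] <- list(
        steps = r$steps,
        leaves = names(r$leaves),
        buyable_matches = r$leaves,
        depth = plan_route_depth(r$steps),
        n_reactions = length(r$steps))
    }
  }
  structure(list(success = length(routes) > 0L, iterations = iterations,
                 routes = routes, n_nodes = length(nodes),
                 target = nodes[[root]]$smiles, mode = cfg$mode),
            class = "plan_result")
}

# longest linear sequence over plan steps (product -> precursors edges)
plan_route_depth <- function(steps) {
  if (!length(steps)) return(0L)
  prods <- vapply(steps, function(s) s$product, "")
  depth_memo <- new.env(parent = emptyenv())
  depth_of <- function(smi) {
    v <- depth_memo[[smi]]
    if (!is.null(v)) return(v)
    i <- match(smi, prods)
    if (is.na(i)) return(0L)
    depth_memo[[smi]] <- 0L  # cycle guard
    d <- 1L + max(c(0L, vapply(steps[[i]]$precursors, depth_of, 0L)))
    depth_memo[[smi]] <- d
    d
  }
  max(vapply(prods, depth_of, 0L))
}

#' @export
print.plan_result <- function(x, ...) {
  cat("<plan_result> target ", x$target, ": ",
      if (x$success) paste0("solved (", length(x$routes), " route(s))")
      else "not solved",
      " after ", x$iterations, " iterations [", x$mode, " mode]\n", sep = "")
  invisible(x)
}

#' Per-route statistics and cross-result deltas
#'
#' @param results List of \code{plan_result} objects (one per target), or a
#'   single result.
#' @param results_b Optional second result list to compare against; deltas
#'   are \code{min depth(A) - min depth(B)} per target solved by both.
#' @return List: \code{per_route} data frame (target, depth, n_reactions),
#'   and when \code{results_b} is given, \code{deltas} (data frame of
#'   per-target depth and reaction-count differences).
#' @export
route_stats <- function(results, results_b = NULL) {
  if (inherits(results, "plan_result")) results <- list(results)
  per <- do.call(rbind, lapply(results, function(r) {
    if (!length(r$routes)) return(NULL)
    data.frame(target = r$target,
               depth = vapply(r$routes, function(x) x$depth, 0L),
               n_reactions = vapply(r$routes, function(x) x$n_reactions, 0L))
  }))
  if (is.null(per))
    per <- data.frame(target = character(0), depth = integer(0),
                      n_reactions = integer(0))
  out <- list(per_route = per)
  if (!is.null(results_b)) {
    if (inherits(results_b, "plan_result")) results_b <- list(results_b)
    mins <- function(rs) {
      do.call(rbind, lapply(rs, function(r) {
        if (!length(r$routes)) return(NULL)
        data.frame(target = r$target,
                   depth = min(vapply(r$routes, function(x) x$depth, 0L)),
                   n = min(vapply(r$routes, function(x) x$n_reactions, 0L)))
      }))
    }
    a <- mins(results); b <- mins(results_b)
    if (!is.null(a) && !is.null(b)) {
      shared <- intersect(a$target, b$target)
      d <- data.frame(
        target = shared,
        d_depth = a$depth[match(shared, a$target)] -
          b$depth[match(shared, b$target)],
        d_reactions = a$n[match(shared, a$target)] -
          b$n[match(shared, b$target)])
      out$deltas <- d
    } else {
      out$deltas <- data.frame(target = character(0), d_depth = integer(0),
                               d_reactions = integer(0))
    }
  }
  out
}

#' Multistep planning success rate
#'
#' @param results List of \code{plan_result} objects, one per target.
#' @return Percentage of targets with at least one route.
#' @export
success_rate <- function(results) {
  if (!length(results)) return(NaN)
  100 * mean(vapply(results, function(r) isTRUE(r$success), FALSE))
}
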