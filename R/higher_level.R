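#' @title Higher-level routes and dataset curation
#' @description
#' Converts concrete routes into higher-level routes: molecules are
#' abstracted per the route's atom provenance, spectator reactants (no atom
#' reaching the target) are dropped, and tactical reactions — steps whose
#' abstracted principal reactant equals the abstracted product, such as FGIs
#' of leaving groups and protections — are removed, with their endpoints
#' merged. The curated dataset is the set of unique abstracted
#' reactant-product pairs with precedent lists.
#' @name higher_level
NULL

#' Is an abstracted reaction tactical?
#'
#' A step is tactical when it only affects leaving substructures: after
#' abstraction under route provenance the principal (single
#' atom-contributing) reactant is structurally identical to the product.
#' Co-reactants contributing no atoms are already dropped from abstracted
#' steps and do not enter the comparison.
#'
#' @param step Abstracted step: list with \code{product} (molecule) and
#'   \code{reactants} (list of molecules, spectators removed).
#' @return TRUE if the step is tactical.
#' @export
is_tactical <- function(step) {
  if (length(step$reactants) != 1L) return(FALSE)
  identical(canonical_serialize(step$reactants[[1]]),
            canonical_serialize(step$product))
}

#' Build the higher-level route for a concrete route
#'
#' Abstracts every molecule instance per the traced provenance, drops
#' spectator molecules, removes tactical steps and recomputes depth and
#' reaction count. The target is marker-free by construction.
#'
#' @param route Route from \code{\link{extract_routes}}.
#' @param prov Provenance from \code{\link{trace_provenance}}.
#' @param table,threshold Electronegativity configuration (see
#'   \code{\link{classify_marker}}).
#' @return Higher-level route object: \code{target} (canonical string),
#'   \code{steps} (abstracted non-tactical reactions), \code{depth},
#'   \code{n_reactions}, \code{removed} (record ids of tactical steps),
#'   \code{empty} flag when the route collapsed to zero steps.
#' @export
build_higher_level_route <- function(route, prov, table = pauling_en(),
                                     threshold = 0.1) {
  stopifnot(inherits(prov, "provenance"))
  if (!prov$ok)
    stop("route excluded: ", prov$reason)
  hl_steps <- list()
  removed <- character(0)
  for (i in seq_along(route$steps)) {
    st <- route$steps[[i]]
    pv <- prov$steps[[i]]
    absp <- abstract_molecule(st$product, pv$product$leaving,
                              pv$product$leaving_h, table, threshold)
    if (is.null(absp)) { removed <- c(removed, st$record_id); next }
    absr <- list()
    for (j in seq_along(st$reactants)) {
      a <- abstract_molecule(st$reactants[[j]], pv$reactants[[j]]$leaving,
                             pv$reactants[[j]]$leaving_h, table, threshold)
      if (!is.null(a)) absr[[length(absr) + 1L]] <- a
    }
    hl <- list(product = absp, reactants = absr,
               document_id = st$document_id, record_id = st$record_id)
    if (is_tactical(hl)) removed <- c(removed, st$record_id)
    else hl_steps[[length(hl_steps) + 1L]] <- hl
  }
  structure(list(
    target = route$target,
    steps = hl_steps,
    depth = if (length(hl_steps)) route_depth(hl_steps) else 0L,
    n_reactions = length(hl_steps),
    removed = removed,
    empty = length(hl_steps) == 0L
  ), class = "hl_route")
}

#' Treat a concrete route as an unabstracted route object
#'
#' Produces the same container as \code{\link{build_higher_level_route}}
#' but with the recorded concrete molecules, so that the original
#' (non-abstracted) dataset can be curated through the same interface.
#'
#' @param route Route object.
#' @return Route container with concrete steps.
#' @export
concrete_route <- function(route) {
  steps <- lapply(route$steps, function(st)
    list(product = st$product, reactants = st$reactants,
         document_id = st$document_id, record_id = st$record_id))
  structure(list(target = route$target, steps = steps,
                 depth = route$depth, n_reactions = route$n_reactions,
                 removed = character(0), empty = length(steps) == 0L),
            class = "hl_route")
}

#' @export
print.hl_route <- function(x, ...) {
  cat("<hl_route> target ", x$target, ": ", x$n_reactions,
      " steps, depth ", x$depth,
      if (length(x$removed)) paste0(" (", length(x$removed), " tactical removed)"),
      "\n", sep = "")
  invisible(x)
}

pair_key <- function(product_str, reactant_strs) {
  paste0(paste(sort_c(reactant_strs), collapse = "."), ">>", product_str)
}

#' Curate the unique reaction dataset from routes
#'
#' Deduplicates reactions across routes by canonical reactant-product pair,
#' keeps one representative mapped reaction per pair for template
#' extraction, accumulates precedent ids, and removes excluded benchmark
#' pairs.
#'
#' @param hl_routes List of route containers (abstracted or concrete).
#' @param exclusions Character vector of pair keys to exclude (as produced
#'   by the \code{keys} element of a curated dataset), or NULL.
#' @return Curated dataset: \code{pairs} (list with \code{product},
#'   \code{reactants}, \code{precedents}, \code{count}, \code{rxn}),
#'   \code{keys} (pair keys, same order).
#' @export
curate_dataset <- function(hl_routes, exclusions = NULL) {
  idx <- new.env(parent = emptyenv())
  pairs <- list()
  keys <- character(0)
  for (rt in hl_routes) {
    for (st in rt$steps) {
      ps <- canonical_serialize(st$product)
      rs <- vapply(st$reactants, canonical_serialize, "")
      key <- pair_key(ps, rs)
      prec <- paste0(st$document_id, ":", st$record_id)
      if (!is.null(idx[[key]])) {
        k <- idx[[key]]
        pairs[[k]]$precedents <- unique(c(pairs[[k]]$precedents, prec))
        pairs[[k]]$count <- length(pairs[[k]]$precedents)
      } else {
        pairs[[length(pairs) + 1L]] <- list(
          product = ps, reactants = sort_c(rs), precedents = prec,
          count = 1L, rxn = st)
        keys <- c(keys, key)
        idx[[key]] <- length(pairs)
      }
    }
  }
  if (!is.null(exclusions) && length(exclusions)) {
    keep <- !(keys %in% exclusions)
    pairs <- pairs[keep]
    keys <- keys[keep]
  }
  structure(list(pairs = pairs, keys = keys), class = "curated_dataset")
}

#' @export
print.curated_dataset <- function(x, ...) {
  cat("<curated_dataset> ", length(x$pairs), " unique reactant-product pairs\n",
      sep = "")
  invisible(x)
}

#' Write a curated dataset as JSONL
#'
#' One JSON object per line: \code{product}, \code{reactants},
#' \code{precedents}, \code{count}, in the package's canonical abstracted
#' SMILES dialect.
#'
#' @param ds Curated dataset.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_dataset_jsonl <- function(ds, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (p in ds$pairs) {
    writeLines(jsonlite::toJSON(list(
      product = p$product, reactants = p$reactants,
      precedents = p$precedents, count = p$count
    ), auto_unbox = FALSE), con)
  }
  invisible(path)
}
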