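#' @title Atom-mapped reactions
#' @description
#' Reactions are parsed from the standard \code{reactants>agents>products}
#' SMILES dialect. Agents (between the two \code{>}) are discarded. A valid
#' mapped reaction has exactly one product and every product heavy atom must
#' carry a map number found in some reactant; violations are reported, not
#' silently repaired.
#' @name reaction
NULL

new_reaction <- function(reactants, product, document_id = "",
                         record_id = "") {
  structure(list(reactants = reactants, product = product,
                 document_id = document_id, record_id = record_id),
            class = "rxn")
}

#' @export
print.rxn <- function(x, ...) {
  cat("<rxn ", x$document_id, "/", x$record_id, "> ",
      reaction_smiles(x), "\n", sep = "")
  invisible(x)
}

#' Serialize a reaction as reaction SMILES
#' @param rxn Reaction object.
#' @param keep_maps Keep atom maps (default TRUE).
#' @return A \code{reactants>>product} string.
#' @export
reaction_smiles <- function(rxn, keep_maps = TRUE) {
  paste0(
    paste(vapply(rxn$reactants, write_smiles, "", keep_maps = keep_maps),
          collapse = "."),
    ">>", write_smiles(rxn$product, keep_maps = keep_maps))
}

#' Parse an atom-mapped reaction SMILES record
#'
#' Splits on \code{>} into reactants, agents (discarded) and products, parses
#' each dot-separated molecule, and validates single-product form. When the
#' product side holds several molecules, the behaviour follows
#' \code{multi_product}: \code{"largest"} keeps the product with the most
#' heavy atoms (mirroring a single-product-reactions filter),
#' \code{"reject"} raises a record-skip condition.
#'
#' @param smiles Reaction SMILES string (\code{reactants>agents>products}).
#' @param document_id Source document identifier.
#' @param record_id Record identifier within the document.
#' @param multi_product One of \code{"largest"}, \code{"reject"}.
#' @return A reaction object with fields \code{reactants} (list of molecules),
#'   \code{product}, \code{document_id}, \code{record_id}.
#' @export
parse_mapped_reaction <- function(smiles, document_id = "", record_id = "",
                                  multi_product = c("largest", "reject")) {
  multi_product <- match.arg(multi_product)
  parts <- strsplit(smiles, ">", fixed = TRUE)[[1]]
  if (length(parts) == 2L) parts <- c(parts[1], "", parts[2])
  if (length(parts) != 3L)
    stop("parse error in record '", record_id,
         "': expected reactants>agents>products, got '", smiles, "'")
  split_side <- function(s) {
    if (!nzchar(s)) return(list())
    lapply(strsplit(s, ".", fixed = TRUE)[[1]], parse_smiles)
  }
  reactants <- tryCatch(split_side(parts[1]), error = function(e)
    stop("parse error in record '", record_id, "': ", conditionMessage(e)))
  products <- tryCatch(split_side(parts[3]), error = function(e)
    stop("parse error in record '", record_id, "': ", conditionMessage(e)))
  if (!length(products))
    stop_record_skip(record_id, "zero products")
  if (!length(reactants))
    stop_record_skip(record_id, "zero reactants")
  if (length(products) > 1L) {
    if (multi_product == "reject") stop_record_skip(record_id, "multiple products")
    products <- products[order(-vapply(products, heavy_atom_count, 0L))][1]
  }
  new_reaction(reactants, products[[1]], document_id, record_id)
}

# condition signalling that a record should be skipped (not a hard error)
stop_record_skip <- function(record_id, reason) {
  cond <- structure(
    class = c("record_skip", "error", "condition"),
    list(message = paste0("record '", record_id, "' skipped: ", reason),
         call = sys.call(-1), record_id = record_id, reason = reason))
  stop(cond)
}

#' Validate atom mapping of a reaction
#'
#' Reports, without repairing: product heavy atoms missing a map number
#' (\code{"incomplete mapping"}), duplicate map numbers within one molecule
#' (\code{"duplicate map"}), and product map numbers absent from all
#' reactants (\code{"orphan product atom"}).
#'
#' @param rxn Reaction object.
#' @return A data frame with columns \code{type} and \code{detail}; zero rows
#'   for a clean reaction.
#' @export
validate_mapping <- function(rxn) {
  issues <- list()
  add <- function(type, detail)
    issues[[length(issues) + 1L]] <<- data.frame(type = type, detail = detail,
                                                 stringsAsFactors = FALSE)
  pmaps <- rxn$product$atoms$map[rxn$product$atoms$elem != "*"]
  if (any(pmaps == 0L))
    add("incomplete mapping",
        paste0(sum(pmaps == 0L), " product atom(s) without map number"))
  check_dup <- function(mol, label) {
    m <- mol_maps(mol)
    d <- unique(m[duplicated(m)])
    for (x in d) add("duplicate map", paste0("map ", x, " duplicated in ", label))
  }
  check_dup(rxn$product, "product")
  for (i in seq_along(rxn$reactants))
    check_dup(rxn$reactants[[i]], paste0("reactant ", i))
  rmaps <- unlist(lapply(rxn$reactants, mol_maps))
  orphan <- setdiff(pmaps[pmaps > 0L], rmaps)
  for (x in sort(orphan))
    add("orphan product atom", paste0("product map ", x, " absent from reactants"))
  if (!length(issues))
    return(data.frame(type = character(0), detail = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, issues)
}

#' Read a tab-separated reaction record file
#'
#' Line format: \code{document_id <TAB> record_id <TAB> reaction_smiles}.
#' Unparseable or skip-signalled records are dropped and counted.
#'
#' @param path Path to the record file.
#' @param multi_product Passed to \code{\link{parse_mapped_reaction}}.
#' @return List with \code{reactions} (list of reaction objects) and
#'   \code{n_skipped}.
#' @export
read_reaction_records <- function(path, multi_product = "largest") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  skipped <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 3L) { skipped <- skipped + 1L; next }
    r <- tryCatch(
      parse_mapped_reaction(f[3], document_id = f[1], record_id = f[2],
                            multi_product = multi_product),
      record_skip = function(e) NULL,
      error = function(e) NULL)
    if (is.null(r)) skipped <- skipped + 1L else out[[i]] <- r
  }
  list(reactions = Filter(Negate(is.null), out), n_skipped = skipped)
}

#' Write reaction records to a tab-separated file
#' @param reactions List of reaction objects.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_reaction_records <- function(reactions, path) {
  lines <- vapply(reactions, function(r)
    paste(r$document_id, r$record_id, reaction_smiles(r), sep = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
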