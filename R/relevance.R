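#' @title Template-relevance model
#' @description
#' Ranks retro templates for a product molecule from its circular
#' fingerprint. Marker pseudo-atoms contribute their class and multiplicity
#' to the initial atom invariants, so electrophilic and nucleophilic
#' abstracted environments hash differently. The classifier is a single
#' hidden layer feedforward network (ReLU, softmax cross-entropy) trained by
#' seeded mini-batch gradient descent with momentum and early stopping on
#' validation top-1 accuracy. Evaluation reports top-k accuracy in percent,
#' optionally under the pessimistic convention where the ground-truth
#' precursor is ranked last among the precursors generated by its template.
#' @name relevance_model
NULL

#' Circular count fingerprint of a molecule
#'
#' Morgan-style iterative neighbourhood hashing: atom invariants start from
#' (element, charge, H count, aromaticity, marker class, marker
#' multiplicity, degree) and are refined \code{radius} times over sorted
#' (bond order, neighbour invariant) pairs; every invariant at every radius
#' is folded into a fixed-length count vector.
#'
#' @param mol Molecule object.
#' @param bits Fingerprint length (default 2048).
#' @param radius Number of refinement iterations (default 2).
#' @return Integer count vector of length \code{bits}.
#' @export
mol_fingerprint <- function(mol, bits = 2048L, radius = 2L) {
  n <- n_atoms(mol)
  fp <- integer(bits)
  if (n == 0L) return(fp)
  a <- mol$atoms
  adj_b <- vector("list", n)  # list of c(neighbor, order)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    adj_b[[b$a1[k]]] <- c(adj_b[[b$a1[k]]], list(c(b$a2[k], b$order[k])))
    adj_b[[b$a2[k]]] <- c(adj_b[[b$a2[k]]], list(c(b$a1[k], b$order[k])))
  }
  inv <- vapply(seq_len(n), function(i) hash_ints(c(
    hash_string(a$elem[i]), a$chg[i] + 8L, a$nH[i], as.integer(a$arom[i]),
    a$marker[i], a$mult[i], length(adj_b[[i]]))), 0)
  for (i in seq_len(n)) fp[1L + inv[i] %% bits] <- fp[1L + inv[i] %% bits] + 1L
  for (r in seq_len(radius)) {
    newinv <- numeric(n)
    for (i in seq_len(n)) {
      pairs <- vapply(adj_b[[i]], function(x) x[2] * 2147483629 + inv[x[1]], 0)
      newinv[i] <- hash_ints(c(inv[i], sort(pairs)))
    }
    inv <- newinv
    for (i in seq_len(n)) fp[1L + inv[i] %% bits] <- fp[1L + inv[i] %% bits] + 1L
  }
  fp
}

#' Split a curated dataset into train/validation/test
#'
#' Splits by unique reactant-product pair, reproducibly for a given seed.
#'
#' @param ds Curated dataset.
#' @param fractions Numeric triple summing to 1 (default 80/10/10).
#' @param seed Integer seed.
#' @return List of integer index vectors \code{train}, \code{valid},
#'   \code{test} (disjoint, union = all pairs).
#' @export
split_dataset <- function(ds, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, length(fractions) == 3L)
  n <- length(ds$pairs)
  if (n < 10L) stop("dataset too small to split (need at least 10 pairs)")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  perm <- sample.int(n)
  n_tr <- floor(fractions[1] * n)
  n_va <- floor(fractions[2] * n)
  list(train = sort(perm[seq_len(n_tr)]),
       valid = sort(perm[n_tr + seq_len(n_va)]),
       test = sort(perm[(n_tr + n_va + 1L):n]))
}

# fingerprint matrix + labels for a set of pairs under a consolidation
build_design <- function(ds, cons, idx, bits = 2048L, radius = 2L) {
  X <- matrix(0, nrow = length(idx), ncol = bits)
  for (r in seq_along(idx)) {
    X[r, ] <- mol_fingerprint(parse_smiles(ds$pairs[[idx[r]]]$product),
                              bits = bits, radius = radius)
  }
  y <- cons$assignment[idx]
  list(X = X, y = y)
}

#' Train the template-relevance classifier
#'
#' One-hidden-layer feedforward network over product fingerprints with
#' softmax output across consolidated templates. Training is mini-batch
#' gradient descent with momentum under a fixed seed; early stopping
#' monitors validation top-1 accuracy.
#'
#' @param ds Curated dataset.
#' @param cons Consolidation result from
#'   \code{\link{consolidate_templates}}.
#' @param train_idx,valid_idx Pair indices for training and validation.
#' @param config List: \code{bits} (2048), \code{radius} (2), \code{hidden}
#'   (512), \code{epochs} (40), \code{lr} (0.05), \code{batch} (32),
#'   \code{momentum} (0.9), \code{patience} (5), \code{seed} (1).
#' @return A \code{template_classifier} object (weights, template count,
#'   config, per-epoch validation log).
#' @export
train_classifier <- function(ds, cons, train_idx, valid_idx,
                             config = list()) {
  cfg <- utils::modifyList(list(bits = 2048L, radius = 2L, hidden = 512L,
                                epochs = 40L, lr = 0.05, batch = 32L,
                                momentum = 0.9, patience = 5L, seed = 1L),
                           config)
  n_templates <- length(cons$templates)
  tr <- build_design(ds, cons, train_idx, cfg$bits, cfg$radius)
  va <- build_design(ds, cons, valid_idx, cfg$bits, cfg$radius)
  if (length(unique(tr$y)) < 2L)
    warning("single-class training set; classifier is trivial")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  d <- ncol(tr$X); h <- cfg$hidden; K <- n_templates
  W1 <- matrix(stats::rnorm(d * h, sd = sqrt(2 / d)), d, h)
  b1 <- numeric(h)
  W2 <- matrix(stats::rnorm(h * K, sd = sqrt(2 / h)), h, K)
  b2 <- numeric(K)
  vW1 <- matrix(0, d, h); vb1 <- numeric(h)
  vW2 <- matrix(0, h, K); vb2 <- numeric(K)
  n <- nrow(tr$X)
  fwd <- function(X) {
    H <- pmax(X %*% W1 + matrix(b1, nrow(X), h, byrow = TRUE), 0)
    S <- H %*% W2 + matrix(b2, nrow(X), K, byrow = TRUE)
    S <- S - apply(S, 1, max)
    E <- exp(S)
    list(H = H, P = E / rowSums(E))
  }
  top1 <- function(X, y) {
    if (!nrow(X)) return(NA_real_)
    mean(max.col(fwd(X)$P, ties.method = "first") == y)
  }
  best <- list(acc = -1, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  log <- data.frame(epoch = integer(0), valid_top1 = numeric(0))
  stale <- 0L
  for (ep in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    for (s in seq(1L, n, by = cfg$batch)) {
      ix <- perm[s:min(s + cfg$batch - 1L, n)]
      X <- tr$X[ix, , drop = FALSE]
      f <- fwd(X)
      G <- f$P
      G[cbind(seq_along(ix), tr$y[ix])] <- G[cbind(seq_along(ix), tr$y[ix])] - 1
      G <- G / length(ix)
      gW2 <- t(f$H) %*% G
      gb2 <- colSums(G)
      GH <- (G %*% t(W2)) * (f$H > 0)
      gW1 <- t(X) %*% GH
      gb1 <- colSums(GH)
      vW2 <- cfg$momentum * vW2 - cfg$lr * gW2; W2 <- W2 + vW2
      vb2 <- cfg$momentum * vb2 - cfg$lr * gb2; b2 <- b2 + vb2
      vW1 <- cfg$momentum * vW1 - cfg$lr * gW1; W1 <- W1 + vW1
      vb1 <- cfg$momentum * vb1 - cfg$lr * gb1; b1 <- b1 + vb1
    }
    acc <- top1(va$X, va$y)
    log <- rbind(log, data.frame(epoch = ep, valid_top1 = acc))
    if (!is.na(acc) && acc > best$acc + 1e-12) {
      best <- list(acc = acc, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= cfg$patience) break
    }
  }
  structure(list(W1 = best$W1, b1 = best$b1, W2 = best$W2, b2 = best$b2,
                 n_templates = n_templates, config = cfg, log = log,
                 valid_top1 = best$acc),
            class = "template_classifier")
}

#' Predict template scores for a product
#'
#' @param model A relevance model (\code{template_classifier} or
#'   \code{template_prior}).
#' @param product Molecule object.
#' @return Numeric score vector over templates, summing to 1.
#' @export
predict_template_scores <- function(model, product) {
  UseMethod("predict_template_scores")
}

#' @export
predict_template_scores.template_classifier <- function(model, product) {
  x <- mol_fingerprint(product, bits = model$config$bits,
                       radius = model$config$radius)
  H <- pmax(drop(x %*% model$W1) + model$b1, 0)
  s <- drop(H %*% model$W2) + model$b2
  s <- s - max(s)
  e <- exp(s)
  e / sum(e)
}

#' Precedent-frequency prior over templates
#'
#' A product-independent baseline model scoring each template by its
#' precedent count; useful as a search prior when no trained classifier is
#' available.
#'
#' @param templates List of templates (with \code{precedent_count}).
#' @return A \code{template_prior} model.
#' @export
template_prior <- function(templates) {
  w <- vapply(templates, function(t) t$precedent_count, 0L)
  structure(list(weights = w / sum(w), n_templates = length(templates)),
            class = "template_prior")
}

#' @export
predict_template_scores.template_prior <- function(model, product) {
  model$weights
}

#' Rank precursor proposals for a product
#'
#' Scores all templates, takes the \code{k} highest-scoring, applies each
#' to the product and returns one entry per precursor set, in template
#' score order (ties broken by template index) and canonical-string order
#' within a template. Non-applicable templates are skipped.
#'
#' @param model Relevance model.
#' @param templates Template list the model indexes into.
#' @param product Molecule object.
#' @param k Number of top templates to apply.
#' @return List of entries: \code{template} (index), \code{score},
#'   \code{precursors} (canonical strings), \code{mols}.
#' @export
rank_precursors <- function(model, templates, product, k) {
  if (k <= 0L) return(list())
  scores <- predict_template_scores(model, product)
  ord <- order(-scores, seq_along(scores))
  ord <- ord[seq_len(min(k, length(ord)))]
  counts <- elem_counts(product)
  out <- list()
  for (ti in ord) {
    if (!template_can_match(templates[[ti]], counts)) next
    psets <- apply_template(templates[[ti]], product)
    if (!length(psets)) next
    keyord <- order_c(vapply(psets, function(p)
      paste(p$smiles, collapse = "+"), ""))
    for (p in psets[keyord]) {
      out[[length(out) + 1L]] <- list(template = ti, score = scores[ti],
                                      precursors = p$smiles, mols = p$mols)
    }
  }
  out
}

#' Top-k accuracy of a relevance model
#'
#' For each test pair the ranked precursor entries are enumerated in
#' template score order; the pair counts as recovered at the rank of the
#' entry matching the recorded reactants. Under the pessimistic convention
#' the rank is the position of the last precursor entry generated by the
#' matched template.
#'
#' @param model Relevance model.
#' @param templates Template list.
#' @param ds Curated dataset.
#' @param test_idx Pair indices to evaluate.
#' @param k_list Integer vector of k values (default
#'   \code{c(1, 3, 5, 10, 25, 50)}).
#' @param pessimistic Use pessimistic ranks (default TRUE).
#' @return An \code{eval_report}: data frame of \code{k} and
#'   \code{accuracy} (percent), with attributes \code{n_products} and
#'   \code{pessimistic}.
#' @export
top_k_accuracy <- function(model, templates, ds, test_idx,
                           k_list = c(1L, 3L, 5L, 10L, 25L, 50L),
                           pessimistic = TRUE) {
  kmax <- max(k_list)
  ranks <- vapply(test_idx, function(i) {
    pair <- ds$pairs[[i]]
    product <- parse_smiles(pair$product)
    want <- sort_c(pair$reactants)
    scores <- predict_template_scores(model, product)
    ord <- order(-scores, seq_along(scores))
    counts <- elem_counts(product)
    pos <- 0L
    for (ti in ord) {
      if (pos >= kmax) break
      if (!template_can_match(templates[[ti]], counts)) next
      psets <- apply_template(templates[[ti]], product)
      if (!length(psets)) next
      keyord <- order_c(vapply(psets, function(p)
        paste(p$smiles, collapse = "+"), ""))
      block_start <- pos
      found_at <- NA_integer_
      for (p in psets[keyord]) {
        pos <- pos + 1L
        if (is.na(found_at) && identical(p$smiles, want)) found_at <- pos
      }
      if (!is.na(found_at))
        return(if (pessimistic) pos else found_at)
    }
    NA_integer_
  }, 0L)
  acc <- vapply(k_list, function(k)
    100 * mean(!is.na(ranks) & ranks <= k), 0)
  rep <- data.frame(k = k_list, accuracy = acc)
  attr(rep, "n_products") <- length(test_idx)
  attr(rep, "pessimistic") <- pessimistic
  class(rep) <- c("eval_report", "data.frame")
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Top-k accuracy (", if (isTRUE(attr(x, "pessimistic"))) "pessimistic"
      else "optimistic", ", n = ", attr(x, "n_products"), "):\n", sep = "")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  top-%-3d %6.1f%%\n", x$k[i], x$accuracy[i]))
  invisible(x)
}
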