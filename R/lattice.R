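#' Enumerate all formal concepts of a context
#'
#' A formal concept is a pair (A, B) where A (the extent) is the set of all
#' objects sharing every attribute in B, and B (the intent) is the set of
#' all attributes shared by every object in A. This function returns every
#' concept of the context exactly once, using the Close-by-One (CbO)
#' algorithm over attributes in canonical (file) order, which visits the
#' closed intents in lectic order. The result is deterministic for a given
#' context.
#'
#' @param ctx a [formal_context].
#' @return a list of concepts; each is a list with components `extent`
#'   (character vector of object ids), `intent` (character vector of
#'   attribute names) and `index` (position in the canonical enumeration).
#' @references Kuznetsov's Close-by-One scheme for enumerating closed sets.
#' @seealso [brute_force_concepts()] for the exhaustive oracle,
#'   [build_order()] to assemble the lattice.
#' @export
enumerate_concepts <- function(ctx) {
  stopifnot(inherits(ctx, "formal_context"))
  inc <- ctx$incidence
  n_att <- ncol(inc)
  out <- vector("list", 64L)
  n_out <- 0L
  emit <- function(extent, intent) {
    n_out <<- n_out + 1L
    if (n_out > length(out)) length(out) <<- 2L * n_out
    out[[n_out]] <<- list(extent = extent, intent = intent)
  }
  # B: logical intent membership; ext: integer object indices; y: last attr
  # added on this branch. Candidate attributes are tried in descending order
  # so the depth-first emission sequence is exactly the lectic order of
  # intents (ascending characteristic-vector order).
  cbo <- function(B, ext, y) {
    emit(ext, which(B))
    if (y >= n_att) return(invisible())
    for (j in rev(seq.int(y + 1L, n_att))) {
      if (B[j]) next
      new_ext <- ext[inc[ext, j]]
      D <- if (length(new_ext) == 0) rep(TRUE, n_att) else {
        colSums(inc[new_ext, , drop = FALSE]) == length(new_ext)
      }
      # canonicity: closure must not introduce attributes before j
      if (j > 1L && any(D[seq_len(j - 1L)] & !B[seq_len(j - 1L)])) next
      cbo(D, new_ext, j)
    }
  }
  # the top concept: extent = all objects, intent = their common attributes
  B0 <- if (nrow(inc) == 0) rep(TRUE, n_att) else colSums(inc) == nrow(inc)
  cbo(B0, seq_len(nrow(inc)), 0L)
  concepts <- vector("list", n_out)
  for (i in seq_len(n_out)) {
    concepts[[i]] <- list(extent = ctx$objects[out[[i]]$extent],
                          intent = ctx$attributes[out[[i]]$intent],
                          index = i)
  }
  concepts
}

#' Brute-force concept enumeration (test oracle)
#'
#' Exhaustively closes every subset of the smaller of the object/attribute
#' sets and deduplicates. Intended as an independent oracle against which
#' [enumerate_concepts()] is verified; refuses contexts where the smaller
#' side exceeds 16 elements.
#'
#' @param ctx a [formal_context] with `min(|G|, |M|) <= 16`.
#' @return a list of concepts in the same canonical order as
#'   [enumerate_concepts()] (sorted lectically by intent index set).
#' @export
brute_force_concepts <- function(ctx) {
  stopifnot(inherits(ctx, "formal_context"))
  inc <- ctx$incidence
  n_obj <- nrow(inc); n_att <- ncol(inc)
  k <- min(n_obj, n_att)
  if (k > 16) stop("context too large for exhaustive enumeration (min side ",
                   k, " > 16)")
  over_attrs <- n_att <= n_obj
  n <- if (over_attrs) n_att else n_obj
  seen <- new.env(hash = TRUE, parent = emptyenv())
  pairs <- list()
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    if (over_attrs) {
      ext <- .extent_of(inc, sel)
      int <- .intent_of(inc, ext)
    } else {
      int <- .intent_of(inc, sel)
      ext <- .extent_of(inc, int)
    }
    key <- paste(c("k", int), collapse = ",")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      pairs[[length(pairs) + 1L]] <- list(extent = ext, intent = int)
    }
  }
  # canonical order: lectic on intents = ascending order of the intent
  # characteristic vectors read as binary strings (matches CbO emission)
  ord <- order(.lectic_key(pairs, n_att))
  concepts <- vector("list", length(pairs))
  for (i in seq_along(ord)) {
    p <- pairs[[ord[i]]]
    concepts[[i]] <- list(extent = ctx$objects[p$extent],
                          intent = ctx$attributes[p$intent],
                          index = i)
  }
  concepts
}

# characteristic vector of each intent as a binary string; ascending
# lexicographic order of these strings is the lectic order
.lectic_key <- function(pairs, n_att) {
  vapply(pairs, function(p) {
    v <- rep("0", n_att); v[p$intent] <- "1"; paste(v, collapse = "")
  }, character(1))
}

#' Build the concept lattice (Hasse order)
#'
#' Orders concepts by extent inclusion (the subconcept–superconcept
#' relation) and computes the covering edges — the transitive reduction of
#' that order, the edges drawn in a line (Hasse) diagram. Moving down the
#' lattice, extents shrink and intents grow: subconcepts are more specific.
#'
#' @param ctx the [formal_context] the concepts belong to.
#' @param concepts the full concept list from [enumerate_concepts()];
#'   computed if missing.
#' @return an object of class `concept_lattice` with components `context`,
#'   `concepts`, `covering_edges` (two-column integer matrix, sub index then
#'   super index), `top` and `bottom` (concept indices).
#' @export
build_order <- function(ctx, concepts = enumerate_concepts(ctx)) {
  stopifnot(inherits(ctx, "formal_context"))
  n <- length(concepts)
  keys <- vapply(concepts, function(p) paste(p$intent, collapse = "\r"), character(1))
  if (anyDuplicated(keys)) stop("duplicate concepts passed to build_order")
  n_obj <- length(ctx$objects)
  E <- matrix(FALSE, n, n_obj)
  for (i in seq_len(n)) E[i, match(concepts[[i]]$extent, ctx$objects)] <- TRUE
  sizes <- rowSums(E)
  inter <- tcrossprod(E * 1)              # pairwise extent intersections
  leq <- inter == sizes                    # leq[i, j]: extent_i subset extent_j
  strict <- leq & !diag(TRUE, n)
  S <- Matrix::Matrix(strict, sparse = TRUE)
  two_step <- as.matrix(S %*% S) > 0       # a concept strictly between i and j
  covers <- strict & !two_step
  edges <- which(covers, arr.ind = TRUE)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  colnames(edges) <- c("sub", "super")
  top <- which(sizes == n_obj)
  bottom <- which(vapply(concepts, function(p)
    length(p$intent) == length(ctx$attributes), logical(1)))
  if (length(top) != 1 || length(bottom) != 1) {
    stop("concept set is not a complete lattice (missing top or bottom)")
  }
  structure(list(context = ctx, concepts = concepts,
                 covering_edges = edges, top = top, bottom = bottom),
            class = "concept_lattice")
}

#' @export
print.concept_lattice <- function(x, ...) {
  cat("Concept lattice: ", length(x$concepts), " concepts, ",
      nrow(x$covering_edges), " covering edges (context ",
      length(x$context$objects), "x", length(x$context$attributes), ")\n",
      sep = "")
  invisible(x)
}

#' Export a concept lattice as a Graphviz DOT line diagram
#'
#' One node per concept (id `c<index>`), labeled with its intent and,
#' optionally, a per-concept annotation such as a class label; one edge per
#' covering pair, drawn from subconcept to superconcept. Output is
#' byte-deterministic for a given lattice.
#'
#' @param lat a [build_order()] lattice.
#' @param labels optional character vector (or list) of per-concept
#'   annotations, length = number of concepts; `NA` entries are omitted.
#' @return a single string of DOT text.
#' @export
export_dot <- function(lat, labels = NULL) {
  stopifnot(inherits(lat, "concept_lattice"))
  n <- length(lat$concepts)
  if (!is.null(labels) && length(labels) != n) {
    stop("labels must have one entry per concept")
  }
  node_lines <- vapply(seq_len(n), function(i) {
    p <- lat$concepts[[i]]
    lab <- paste0("{", paste(p$intent, collapse = ","), "}")
    if (!is.null(labels) && !is.na(labels[[i]])) {
      lab <- paste0(lab, "\\nclass ", labels[[i]])
    }
    sprintf("  c%d [label=\"%s\"];", i, lab)
  }, character(1))
  e <- lat$covering_edges
  edge_lines <- if (nrow(e) > 0) {
    sprintf("  c%d -> c%d;", e[, "sub"], e[, "super"])
  } else character(0)
  paste(c("digraph lattice {", "  rankdir=BT;", node_lines, edge_lines, "}"),
        collapse = "\n")
}

#' Serialize a concept lattice to JSON
#'
#' @param lat a [build_order()] lattice.
#' @param labels optional per-concept annotations as in [export_dot()].
#' @param path optional file path; if given, JSON is written there.
#' @return the JSON string, invisibly if `path` is given.
#' @export
lattice_json <- function(lat, labels = NULL, path = NULL) {
  stopifnot(inherits(lat, "concept_lattice"))
  concepts <- lapply(lat$concepts, function(p) {
    rec <- list(index = p$index, extent = I(p$extent), intent = I(p$intent))
    if (!is.null(labels) && !is.na(labels[[p$index]])) rec$label <- labels[[p$index]]
    rec
  })
  e <- lat$covering_edges
  obj <- list(concepts = concepts,
              edges = lapply(seq_len(nrow(e)), function(i) unname(e[i, ])))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
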