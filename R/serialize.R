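#' Save a fitted lattice classifier to JSON
#'
#' Serializes the full model — context, concepts, per-concept class
#' tallies, labels, tie log, covering edges and any fitted binarizer — to a
#' versioned JSON schema, so the lattice stays inspectable after training.
#'
#' @param model an [fca_fit()] model.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_model()]
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "fca_model"))
  ctx <- model$context
  obj <- list(
    schema = "fcaclass-model",
    version = 1L,
    attributes = ctx$attributes,
    objects = ctx$objects,
    unique_vectors = lapply(seq_len(nrow(model$unique_vectors)), function(i)
      as.integer(model$unique_vectors[i, ])),
    label_multisets = lapply(model$label_multisets, function(v) I(unname(v))),
    classes = model$classes,
    concepts = lapply(model$lattice$concepts, function(p)
      list(index = p$index, extent = I(p$extent), intent = I(p$intent))),
    concept_labels = model$concept_labels,
    concept_counts = lapply(seq_len(nrow(model$concept_counts)), function(i)
      as.integer(model$concept_counts[i, ])),
    tie_log = I(model$tie_log),
    edges = if (is.null(model$lattice$covering_edges)) NULL else
      lapply(seq_len(nrow(model$lattice$covering_edges)), function(i)
        unname(model$lattice$covering_edges[i, ])),
    binarizer = if (is.null(model$binarizer)) NULL else list(
      normalization = model$binarizer$normalization,
      threshold = model$binarizer$threshold,
      stats = model$binarizer$stats,
      constant_features = I(model$binarizer$constant_features)
    )
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null"),
             path)
  invisible(path)
}

#' Load a fitted lattice classifier from JSON
#'
#' @param path path to a model file written by [write_model()].
#' @return an `fca_model` equivalent to the one saved.
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$schema, "fcaclass-model")) {
    stop("not an fcaclass model file: ", path)
  }
  atts <- unlist(obj$attributes)
  uid <- unlist(obj$objects)
  uniq <- do.call(rbind, lapply(obj$unique_vectors, unlist))
  dimnames(uniq) <- list(uid, atts)
  ctx <- formal_context(uniq, objects = uid, attributes = atts)
  concepts <- lapply(obj$concepts, function(p)
    list(extent = as.character(unlist(c(p$extent, character(0)))),
         intent = as.character(unlist(c(p$intent, character(0)))),
         index = p$index))
  edges <- if (is.null(obj$edges)) NULL else {
    e <- do.call(rbind, lapply(obj$edges, unlist))
    colnames(e) <- c("sub", "super")
    e
  }
  classes <- unlist(obj$classes)
  counts <- do.call(rbind, lapply(obj$concept_counts, unlist))
  colnames(counts) <- classes
  sizes <- vapply(concepts, function(p) length(p$extent), integer(1))
  top <- which(sizes == length(uid))
  bottom <- which(vapply(concepts, function(p)
    length(p$intent) == length(atts), logical(1)))
  lat <- structure(list(context = ctx, concepts = concepts,
                        covering_edges = edges,
                        top = if (length(top)) top else NA,
                        bottom = if (length(bottom)) bottom else NA),
                   class = "concept_lattice")
  binarizer <- NULL
  if (!is.null(obj$binarizer)) {
    b <- obj$binarizer
    st <- do.call(rbind, lapply(b$stats, function(r)
      data.frame(feature = r$feature, min = r$min, max = r$max,
                 mean = r$mean, sd = r$sd, stringsAsFactors = FALSE)))
    binarizer <- structure(list(normalization = b$normalization,
                                threshold = b$threshold,
                                fitted = TRUE, stats = st,
                                constant_features = as.character(unlist(
                                  c(b$constant_features, character(0))))),
                           class = "binarizer_spec")
  }
  structure(list(
    context = ctx, unique_vectors = uniq,
    label_multisets = lapply(obj$label_multisets, function(v)
      as.character(unlist(c(v, character(0))))),
    lattice = lat, classes = classes, concept_counts = counts,
    concept_labels = vapply(obj$concept_labels, function(v)
      if (is.null(v)) NA_character_ else as.character(v), character(1)),
    tie_log = as.integer(unlist(c(obj$tie_log, integer(0)))),
    binarizer = binarizer
  ), class = "fca_model")
}
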