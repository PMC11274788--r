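#' Construct a formal context
#'
#' A formal context is a triple (G, M, I): a set of objects G, a set of
#' attributes M, and a binary incidence relation I stating which objects
#' have which attributes. It is the input of formal concept analysis.
#'
#' @param incidence a numeric or logical matrix with one row per object and
#'   one column per attribute; entries must be exactly 0/1 (or FALSE/TRUE),
#'   with no missing values.
#' @param objects character vector of unique object identifiers; defaults to
#'   `rownames(incidence)` or `"1".."n"`.
#' @param attributes character vector of unique attribute names; defaults to
#'   `colnames(incidence)` or `"m1".."mK"`.
#'
#' @return an object of class `formal_context` with components `objects`,
#'   `attributes` and `incidence` (a logical matrix with dimnames).
#'
#' @details Object and attribute order is preserved exactly as given; this
#'   file/argument order defines the canonical index order used for all
#'   deterministic tie-breaking downstream (concept enumeration order,
#'   classifier tie resolution).
#'
#' @examples
#' inc <- matrix(c(1,0, 1,1), nrow = 2, byrow = TRUE)
#' ctx <- formal_context(inc, objects = c("o1", "o2"), attributes = c("a", "b"))
#' derive_extent(ctx, "a")
#' @export
formal_context <- function(incidence, objects = NULL, attributes = NULL) {
  if (!is.matrix(incidence)) {
    incidence <- as.matrix(incidence)
  }
  if (is.null(objects)) {
    objects <- rownames(incidence)
    if (is.null(objects)) objects <- as.character(seq_len(nrow(incidence)))
  }
  if (is.null(attributes)) {
    attributes <- colnames(incidence)
    if (is.null(attributes)) {
      attributes <- sprintf("m%d", seq_len(ncol(incidence)))
    }
  }
  objects <- as.character(objects)
  attributes <- as.character(attributes)
  if (anyDuplicated(objects)) {
    stop("duplicate object identifiers: ",
         paste(unique(objects[duplicated(objects)]), collapse = ", "))
  }
  if (anyDuplicated(attributes)) {
    stop("duplicate attribute names: ",
         paste(unique(attributes[duplicated(attributes)]), collapse = ", "))
  }
  if (nrow(incidence) != length(objects) || ncol(incidence) != length(attributes)) {
    stop("incidence must be ", length(objects), " x ", length(attributes),
         ", got ", nrow(incidence), " x ", ncol(incidence))
  }
  if (anyNA(incidence)) stop("incidence contains missing values")
  if (is.logical(incidence)) {
    inc <- incidence
  } else {
    bad <- which(!(incidence %in% c(0, 1)))
    if (length(bad) > 0) {
      pos <- arrayInd(bad[1], dim(incidence))
      stop("non-binary incidence entry at row ", pos[1], ", column ", pos[2])
    }
    inc <- incidence == 1
  }
  dimnames(inc) <- list(objects, attributes)
  structure(
    list(objects = objects, attributes = attributes, incidence = inc),
    class = "formal_context"
  )
}

#' @export
print.formal_context <- function(x, ...) {
  cat("Formal context: ", length(x$objects), " objects x ",
      length(x$attributes), " attributes, ",
      sum(x$incidence), " incidences\n", sep = "")
  if (length(x$objects) <= 12 && length(x$attributes) <= 20) {
    m <- matrix(ifelse(x$incidence, "X", "."),
                nrow = length(x$objects),
                dimnames = dimnames(x$incidence))
    print(m, quote = FALSE)
  }
  invisible(x)
}

#' @export
format.formal_context <- function(x, ...) {
  paste0("<formal_context: ", length(x$objects), "x", length(x$attributes), ">")
}

# resolve attribute names to column indices, with a helpful error
.attr_index <- function(ctx, attrs) {
  if (length(attrs) == 0) return(integer(0))
  idx <- match(as.character(attrs), ctx$attributes)
  if (anyNA(idx)) {
    stop("unknown attribute name(s): ",
         paste(as.character(attrs)[is.na(idx)], collapse = ", "))
  }
  idx
}

.obj_index <- function(ctx, objs) {
  if (length(objs) == 0) return(integer(0))
  idx <- match(as.character(objs), ctx$objects)
  if (anyNA(idx)) {
    stop("unknown object identifier(s): ",
         paste(as.character(objs)[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Derivation operator: attributes to objects
#'
#' Returns the set of all objects that have every attribute in `attrs`
#' (the "prime" operator of formal concept analysis applied to an
#' attribute set). The empty attribute set derives to all objects.
#'
#' @param ctx a [formal_context].
#' @param attrs character vector of attribute names (possibly empty).
#' @return character vector of object identifiers, in canonical order.
#' @seealso [derive_intent()], [closure()]
#' @export
derive_extent <- function(ctx, attrs = character(0)) {
  stopifnot(inherits(ctx, "formal_context"))
  idx <- .attr_index(ctx, attrs)
  if (length(idx) == 0) return(ctx$objects)
  keep <- rowSums(ctx$incidence[, idx, drop = FALSE]) == length(idx)
  ctx$objects[keep]
}

#' Derivation operator: objects to attributes
#'
#' Returns the set of all attributes shared by every object in `objs`.
#' The empty object set derives to all attributes.
#'
#' @param ctx a [formal_context].
#' @param objs character vector of object identifiers (possibly empty).
#' @return character vector of attribute names, in canonical order.
#' @seealso [derive_extent()], [closure()]
#' @export
derive_intent <- function(ctx, objs = character(0)) {
  stopifnot(inherits(ctx, "formal_context"))
  idx <- .obj_index(ctx, objs)
  if (length(idx) == 0) return(ctx$attributes)
  keep <- colSums(ctx$incidence[idx, , drop = FALSE]) == length(idx)
  ctx$attributes[keep]
}

#' Closure of an attribute set
#'
#' Double derivation: `derive_intent(ctx, derive_extent(ctx, attrs))`.
#' The result is the smallest concept intent containing `attrs`; closure is
#' extensive, monotone and idempotent, and the closed attribute sets are
#' exactly the concept intents of the context.
#'
#' @inheritParams derive_extent
#' @return character vector of attribute names (a closed set).
#' @export
closure <- function(ctx, attrs = character(0)) {
  derive_intent(ctx, derive_extent(ctx, attrs))
}

## ---- internal index-based derivations (hot path for enumeration) ----

# extent (integer object indices) of an attribute index set
.extent_of <- function(inc, attr_idx) {
  if (length(attr_idx) == 0) return(seq_len(nrow(inc)))
  which(rowSums(inc[, attr_idx, drop = FALSE]) == length(attr_idx))
}

# intent (integer attribute indices) of an object index set
.intent_of <- function(inc, obj_idx) {
  if (length(obj_idx) == 0) return(seq_len(ncol(inc)))
  which(colSums(inc[obj_idx, , drop = FALSE]) == length(obj_idx))
}
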