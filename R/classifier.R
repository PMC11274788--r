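#' Fit a concept-lattice classifier
#'
#' Implements the lattice-based learning step: training feature vectors are
#' deduplicated (keeping the class labels of all duplicates as a multiset
#' per unique vector), a concept lattice is built over the context whose
#' objects are the unique vectors and whose attributes are the features,
#' and every concept with a non-empty extent is labeled with the class
#' holding the maximum duplicate-aware image count in its extent. Concepts
#' with empty extent (typically the bottom of the lattice) stay unlabeled
#' and never take part in prediction.
#'
#' @param x the training data: a binary 0/1 matrix (rows = instances,
#'   columns = named features), a [formal_context], or a [feature_matrix]
#'   of continuous values (then binarized internally with `spec`).
#' @param labels class labels, one per row of `x`. Coerced to character;
#'   the canonical class ordering used for tie-breaking is the sorted order
#'   of the distinct labels.
#' @param spec a [binarizer()] spec, used only when `x` is a continuous
#'   [feature_matrix]; it is fitted on `x` and stored in the model so the
#'   identical transform applies at prediction time.
#' @param order build the covering (Hasse) edges of the lattice (default
#'   `TRUE`). Classification and rule extraction only need the concepts
#'   themselves, so large simulation loops can skip the edge computation.
#'
#' @return an object of class `fca_model` with components:
#'   `context` (unique-vector formal context), `unique_vectors` (0/1
#'   matrix), `label_multisets` (list, labels of all duplicates per unique
#'   vector), `lattice` (a `concept_lattice`, edges present iff
#'   `order = TRUE`), `classes` (canonical class ordering),
#'   `concept_counts` (concepts x classes tally matrix),
#'   `concept_labels` (majority class per concept, `NA` for empty extent),
#'   `tie_log` (indices of concepts whose majority was tie-broken), and
#'   optionally `binarizer`.
#'
#' @details Majority ties are broken deterministically toward the smallest
#'   class label in canonical order, and each tie-broken concept index is
#'   recorded in `tie_log` so the frequency of arbitrary decisions can be
#'   audited. Counting is duplicate-aware: each original training instance
#'   contributes one count to every concept whose extent contains its
#'   unique vector, so the tally at the top concept equals the training-set
#'   size.
#' @seealso [predict.fca_model()], [extract_rules()]
#' @examples
#' x <- matrix(c(1,0,0,0, 1,1,0,0, 1,1,0,0, 1,1,0,1, 1,1,1,0, 1,0,1,0),
#'             ncol = 4, byrow = TRUE,
#'             dimnames = list(1:6, c("a","b","c","d")))
#' m <- fca_fit(x, labels = c(0, 1, 1, 1, 1, 0))
#' m$concept_labels
#' @export
fca_fit <- function(x, labels, spec = binarizer(), order = TRUE) {
  fitted_binarizer <- NULL
  if (inherits(x, "feature_matrix")) {
    fitted_binarizer <- fit_binarizer(x, spec)
    ctx_full <- binarize(x, fitted_binarizer)
    mat <- ctx_full$incidence * 1L
  } else if (inherits(x, "formal_context")) {
    mat <- x$incidence * 1L
  } else {
    if (!is.matrix(x)) x <- as.matrix(x)
    if (anyNA(x) || !all(x %in% c(0, 1))) {
      stop("training matrix must be binary 0/1 with no missing values")
    }
    mat <- x * 1L
    if (is.null(colnames(mat))) colnames(mat) <- paste0("f", seq_len(ncol(mat)))
  }
  if (nrow(mat) == 0) stop("empty training set")
  labels <- as.character(labels)
  if (length(labels) != nrow(mat)) {
    stop("need one label per training row: ", nrow(mat), " rows, ",
         length(labels), " labels")
  }
  classes <- sort(unique(labels))
  if (length(classes) < 2) {
    warning("training labels contain a single class; every prediction will be '",
            classes, "'")
  }

  # Step 1: deduplicate vectors in first-occurrence order, accumulating the
  # label multiset of each unique vector
  key <- apply(mat, 1, paste, collapse = "")
  first <- !duplicated(key)
  uniq <- mat[first, , drop = FALSE]
  uid <- paste0("u", seq_len(nrow(uniq)))
  rownames(uniq) <- uid
  grp <- match(key, key[first])
  label_multisets <- split(labels, factor(grp, levels = seq_len(nrow(uniq))))
  names(label_multisets) <- uid

  ctx <- formal_context(uniq, objects = uid, attributes = colnames(mat))
  concepts <- enumerate_concepts(ctx)
  lat <- if (order) build_order(ctx, concepts) else
    structure(list(context = ctx, concepts = concepts,
                   covering_edges = NULL, top = NA, bottom = NA),
              class = "concept_lattice")

  # Step 2: duplicate-aware class tallies and majority label per concept
  per_obj <- matrix(0L, nrow(uniq), length(classes),
                    dimnames = list(uid, classes))
  for (i in seq_len(nrow(uniq))) {
    tab <- table(factor(label_multisets[[i]], levels = classes))
    per_obj[i, ] <- as.integer(tab)
  }
  n_con <- length(concepts)
  counts <- matrix(0L, n_con, length(classes),
                   dimnames = list(NULL, classes))
  concept_labels <- rep(NA_character_, n_con)
  tie_log <- integer(0)
  for (k in seq_len(n_con)) {
    ext <- concepts[[k]]$extent
    if (length(ext) == 0) next
    cc <- colSums(per_obj[match(ext, uid), , drop = FALSE])
    counts[k, ] <- as.integer(cc)
    winners <- which(cc == max(cc))
    if (length(winners) > 1) tie_log <- c(tie_log, k)
    concept_labels[k] <- classes[winners[1]]  # classes are sorted: smallest wins
  }

  structure(list(context = ctx, unique_vectors = uniq,
                 label_multisets = label_multisets, lattice = lat,
                 classes = classes, concept_counts = counts,
                 concept_labels = concept_labels, tie_log = tie_log,
                 binarizer = fitted_binarizer),
            class = "fca_model")
}

#' @export
print.fca_model <- function(x, ...) {
  n_lab <- sum(!is.na(x$concept_labels))
  cat("Concept-lattice classifier\n",
      "  training instances: ", sum(lengths(x$label_multisets)),
      " (", nrow(x$unique_vectors), " unique vectors)\n",
      "  attributes: ", ncol(x$unique_vectors), "\n",
      "  concepts: ", length(x$lattice$concepts),
      " (", n_lab, " labeled)\n",
      "  classes: ", paste(x$classes, collapse = ", "), "\n",
      "  majority ties broken: ", length(x$tie_log), "\n", sep = "")
  invisible(x)
}

#' Hamming distance between a binary vector and a concept intent
#'
#' Counts the coordinate positions where `x` differs from the indicator
#' vector of `intent` over the full attribute list `attributes`.
#'
#' @param x binary 0/1 (or logical) vector, one entry per attribute.
#' @param intent character vector of attribute names in the intent.
#' @param attributes the full ordered attribute list.
#' @return a non-negative integer, at most `length(attributes)`.
#' @export
hamming <- function(x, intent, attributes) {
  if (length(x) != length(attributes)) {
    stop("vector length ", length(x), " does not match attribute count ",
         length(attributes))
  }
  unknown <- setdiff(intent, attributes)
  if (length(unknown) > 0) {
    stop("intent attributes not in attribute list: ",
         paste(unknown, collapse = ", "))
  }
  ind <- attributes %in% intent
  sum((as.logical(x)) != ind)
}

#' Classify new instances by nearest concept intent
#'
#' For each test vector the Hamming distance to the intent indicator of
#' every *labeled* concept is computed; the concept at minimal distance
#' wins and its class is the prediction. Distance ties are broken
#' deterministically: larger extent first (more supporting training
#' vectors), then smaller canonical concept index; the number of concepts
#' tied at the minimal distance is reported per instance so the effect of
#' tie-breaking can be audited.
#'
#' @param object an [fca_fit()] model.
#' @param newdata a binary 0/1 matrix whose columns match the model's
#'   attributes in name and order, or a [feature_matrix] of continuous
#'   values when the model was fitted with a binarizer, or a
#'   [formal_context].
#' @param ... unused.
#' @return a data frame with one row per test instance and columns
#'   `object`, `predicted_label`, `concept_index`, `distance`, `n_tied`.
#' @export
predict.fca_model <- function(object, newdata, ...) {
  model <- object
  if (inherits(newdata, "feature_matrix")) {
    if (is.null(model$binarizer)) {
      stop("model was fitted on binary data; supply a binary matrix")
    }
    ctx <- binarize(newdata, model$binarizer)
    mat <- ctx$incidence * 1L
  } else if (inherits(newdata, "formal_context")) {
    mat <- newdata$incidence * 1L
  } else {
    if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
    mat <- newdata * 1L
  }
  atts <- model$context$attributes
  if (ncol(mat) != length(atts)) {
    stop("test data has ", ncol(mat), " columns, model expects ", length(atts))
  }
  if (!is.null(colnames(mat)) && !identical(colnames(mat), atts)) {
    stop("test columns do not match model attributes in name/order")
  }
  if (anyNA(mat) || !all(mat %in% c(0, 1))) {
    stop("test matrix must be binary 0/1 with no missing values")
  }
  lab_idx <- which(!is.na(model$concept_labels))
  if (length(lab_idx) == 0) stop("model has no labeled concepts")
  concepts <- model$lattice$concepts
  intents <- matrix(FALSE, length(lab_idx), length(atts))
  ext_size <- integer(length(lab_idx))
  for (i in seq_along(lab_idx)) {
    p <- concepts[[lab_idx[i]]]
    intents[i, match(p$intent, atts)] <- TRUE
    ext_size[i] <- length(p$extent)
  }
  n <- nrow(mat)
  ids <- rownames(mat)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  pred <- character(n); widx <- integer(n); dist <- integer(n); ntied <- integer(n)
  for (r in seq_len(n)) {
    xr <- mat[r, ] == 1
    d <- rowSums(intents != matrix(xr, nrow(intents), length(atts), byrow = TRUE))
    dmin <- min(d)
    cand <- which(d == dmin)
    ntied[r] <- length(cand)
    # tie-break: largest extent, then smallest canonical concept index
    best <- cand[order(-ext_size[cand], lab_idx[cand])][1]
    widx[r] <- lab_idx[best]
    dist[r] <- as.integer(dmin)
    pred[r] <- model$concept_labels[lab_idx[best]]
  }
  data.frame(object = ids, predicted_label = pred, concept_index = widx,
             distance = dist, n_tied = ntied,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Extract if-then rules from a fitted lattice classifier
#'
#' Each labeled concept yields one human-readable rule: IF an instance has
#' every attribute of the concept's intent THEN predict the concept's
#' majority class. Support is the duplicate-aware number of training
#' instances in the extent; confidence is the majority count divided by the
#' support, so a confidence of 1 marks a class-pure concept ("exclusively
#' associated" with one class). Unlabeled (empty-extent) concepts emit no
#' rule.
#'
#' @param model an [fca_fit()] model.
#' @return a data frame sorted by confidence then support (both
#'   descending) with columns `concept_index`, `intent` (comma-separated
#'   attribute names), `class`, `support`, `confidence`.
#' @export
extract_rules <- function(model) {
  stopifnot(inherits(model, "fca_model"))
  lab_idx <- which(!is.na(model$concept_labels))
  rows <- lapply(lab_idx, function(k) {
    cc <- model$concept_counts[k, ]
    support <- sum(cc)
    data.frame(
      concept_index = k,
      intent = paste(model$lattice$concepts[[k]]$intent, collapse = ","),
      class = model$concept_labels[k],
      support = support,
      confidence = max(cc) / support,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$confidence, -out$support, out$concept_index), ]
  rownames(out) <- NULL
  out
}

#' Per-attribute class association and co-occurrence summary
#'
#' Summarizes how attributes relate to classes across the labeled concepts
#' of a fitted model: for each attribute, the distribution of concept class
#' labels over the labeled concepts whose intents contain it (attributes
#' appearing only in class-1 intents are strong class-1 indicators); plus a
#' co-occurrence count matrix of attribute pairs appearing together in
#' concept intents, and the list of attribute pairs that never co-occur in
#' any intent (candidates for mutual exclusivity in the data).
#'
#' @param model an [fca_fit()] model.
#' @return a list with `association` (data frame: attribute, one column
#'   per class with the share of labeled intents containing the attribute
#'   that carry that class, and `n_concepts`), `cooccurrence` (symmetric
#'   integer matrix over attributes), and `never_cooccur` (two-column data
#'   frame of attribute pairs).
#' @export
feature_class_summary <- function(model) {
  stopifnot(inherits(model, "fca_model"))
  atts <- model$context$attributes
  lab_idx <- which(!is.na(model$concept_labels))
  inmat <- matrix(FALSE, length(lab_idx), length(atts),
                  dimnames = list(NULL, atts))
  for (i in seq_along(lab_idx)) {
    inmat[i, match(model$lattice$concepts[[lab_idx[i]]]$intent, atts)] <- TRUE
  }
  labs <- model$concept_labels[lab_idx]
  assoc <- data.frame(attribute = atts, stringsAsFactors = FALSE)
  for (cl in model$classes) {
    assoc[[cl]] <- vapply(seq_along(atts), function(j) {
      with_att <- inmat[, j]
      if (!any(with_att)) return(NA_real_)
      mean(labs[with_att] == cl)
    }, numeric(1))
  }
  assoc$n_concepts <- colSums(inmat)
  # co-occurrence over labeled intents only: the empty-extent bottom intent
  # contains every attribute and would make all pairs trivially co-occur
  cooc <- crossprod(inmat * 1L)
  storage.mode(cooc) <- "integer"
  never <- which(cooc == 0 & upper.tri(cooc), arr.ind = TRUE)
  never_df <- data.frame(attribute1 = atts[never[, 1]],
                         attribute2 = atts[never[, 2]],
                         stringsAsFactors = FALSE)
  list(association = assoc, cooccurrence = cooc, never_cooccur = never_df)
}
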