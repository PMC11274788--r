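#' Binarization specification
#'
#' Describes how a continuous feature matrix is turned into a binary formal
#' context: each feature is normalized (per feature, using statistics learned
#' from a training matrix) and then a single global threshold is applied to
#' every feature — a value strictly above the threshold becomes 1 (feature
#' present), otherwise 0.
#'
#' @param normalization `"minmax"` (default): rescale each feature to
#'   \[0, 1\] using the training min/max; `"zscore"`: center/scale by the
#'   training mean/sd; `"none"`: threshold the raw values.
#' @param threshold single numeric threshold applied to every normalized
#'   feature; default 0.5, the midpoint of the min-max normalized range.
#' @return an unfitted object of class `binarizer_spec`.
#' @details With min-max normalization a single global threshold is
#'   comparable across features, which is why it is the default. Held-out
#'   data is normalized with the *training* statistics and, for min-max,
#'   clipped to \[0, 1\] before thresholding, so the transform never leaks
#'   test information. Constant training features carry no information and
#'   are mapped to all-0 bits (and flagged in the fitted spec).
#' @seealso [fit_binarizer()], [binarize()]
#' @export
binarizer <- function(normalization = c("minmax", "zscore", "none"),
                      threshold = 0.5) {
  normalization <- match.arg(normalization)
  stopifnot(is.numeric(threshold), length(threshold) == 1, is.finite(threshold))
  if (normalization == "minmax" && (threshold < 0 || threshold > 1)) {
    stop("min-max threshold must lie in [0, 1], got ", threshold)
  }
  structure(list(normalization = normalization, threshold = threshold,
                 fitted = FALSE, stats = NULL),
            class = "binarizer_spec")
}

#' Fit a binarizer on a training feature matrix
#'
#' Learns the per-feature normalization statistics (min/max or mean/sd) from
#' `train` only. Once fitted, the spec is immutable and applies the
#' identical transform to any matrix with the same features.
#'
#' @param train a [feature_matrix] (non-empty).
#' @param spec an unfitted [binarizer()] spec.
#' @return the fitted `binarizer_spec`, carrying `stats` (a data frame with
#'   one row per feature) and `constant_features` (names of zero-variance
#'   features, which will map to all-0 bits).
#' @export
fit_binarizer <- function(train, spec = binarizer()) {
  stopifnot(inherits(train, "feature_matrix"), inherits(spec, "binarizer_spec"))
  if (isTRUE(spec$fitted)) stop("binarizer spec is already fitted; fit once and reuse")
  if (length(train$objects) == 0) stop("cannot fit a binarizer on an empty matrix")
  v <- train$values
  st <- data.frame(
    feature = train$features,
    min = apply(v, 2, min),
    max = apply(v, 2, max),
    mean = colMeans(v),
    sd = apply(v, 2, stats::sd),
    stringsAsFactors = FALSE
  )
  if (nrow(v) == 1) st$sd <- 0  # sd() is NA for a single row
  constant <- st$feature[st$max == st$min]
  if (length(constant) > 0) {
    message("constant training feature(s) mapped to all-0 bits: ",
            paste(constant, collapse = ", "))
  }
  spec$fitted <- TRUE
  spec$stats <- st
  spec$constant_features <- constant
  spec
}

#' @export
print.binarizer_spec <- function(x, ...) {
  cat("Binarizer: normalization=", x$normalization,
      ", threshold=", x$threshold,
      if (isTRUE(x$fitted)) paste0(", fitted on ", nrow(x$stats), " features")
      else ", unfitted",
      "\n", sep = "")
  invisible(x)
}

#' Binarize a feature matrix into a formal context
#'
#' Applies a fitted binarizer: normalizes each feature with the training
#' statistics, clips min-max-normalized values to \[0, 1\] (held-out values
#' can fall outside the training range), then sets a bit to 1 exactly when
#' the normalized value is strictly greater than the global threshold.
#'
#' @param m a [feature_matrix] whose features match (names and order) those
#'   the spec was fitted on.
#' @param fitted a fitted `binarizer_spec` from [fit_binarizer()].
#' @return a [formal_context] with the same objects and attributes named
#'   after the features.
#' @export
binarize <- function(m, fitted) {
  stopifnot(inherits(m, "feature_matrix"), inherits(fitted, "binarizer_spec"))
  if (!isTRUE(fitted$fitted)) stop("binarizer spec is not fitted; call fit_binarizer() first")
  if (!identical(m$features, fitted$stats$feature)) {
    stop("feature names/order do not match the fitted binarizer")
  }
  v <- m$values
  st <- fitted$stats
  norm <- switch(
    fitted$normalization,
    minmax = {
      rng <- st$max - st$min
      rng[rng == 0] <- 1  # constant features: numerator is forced below
      z <- sweep(sweep(v, 2, st$min, "-"), 2, rng, "/")
      z <- pmin(pmax(z, 0), 1)
      z
    },
    zscore = {
      sdv <- st$sd
      sdv[sdv == 0] <- 1
      sweep(sweep(v, 2, st$mean, "-"), 2, sdv, "/")
    },
    none = v
  )
  bits <- norm > fitted$threshold
  if (length(fitted$constant_features) > 0) {
    bits[, m$features %in% fitted$constant_features] <- FALSE
  }
  formal_context(bits, objects = m$objects, attributes = m$features)
}
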