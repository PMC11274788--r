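#' Read a formal context from CSV or Burmeister CXT
#'
#' Two on-disk dialects are supported. The CSV dialect has a header row
#' `object,<attr1>,...,<attrM>`, one row per object and cells that are
#' strictly `0` or `1`. The Burmeister CXT dialect is the classic format:
#' line 1 is `B`, line 2 blank, then the object and attribute counts, the
#' object names, the attribute names, and one row per object made of `.`
#' (absent) and `X` (present).
#'
#' @param path path to the context file.
#' @param format `"auto"` (default, decided by extension and content),
#'   `"csv"` or `"cxt"`.
#' @return a [formal_context]; object/attribute order is preserved from the
#'   file.
#' @seealso [write_context()]
#' @export
read_context <- function(path, format = c("auto", "csv", "cxt")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("context file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (ext == "cxt") {
      format <- "cxt"
    } else if (ext == "csv") {
      format <- "csv"
    } else {
      first <- readLines(path, n = 1L, warn = FALSE)
      format <- if (identical(trimws(first), "B")) "cxt" else "csv"
    }
  }
  switch(format,
         csv = .read_context_csv(path),
         cxt = .read_context_cxt(path))
}

.read_context_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        strip.white = TRUE)
  if (ncol(df) < 2) stop("context CSV needs an object column plus attributes: ", path)
  if (tolower(names(df)[1]) != "object") {
    stop("context CSV header must start with 'object', got '", names(df)[1], "'")
  }
  objects <- df[[1]]
  attributes <- names(df)[-1]
  cells <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!(cells %in% c("0", "1")))
  if (length(bad) > 0) {
    pos <- arrayInd(bad[1], dim(cells))
    stop("non-binary cell '", cells[pos[1], pos[2]], "' at data row ",
         pos[1], ", column '", attributes[pos[2]], "' in ", path)
  }
  inc <- matrix(as.integer(cells), nrow = nrow(cells))
  formal_context(inc, objects = objects, attributes = attributes)
}

.read_context_cxt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4 || trimws(lines[1]) != "B") {
    stop("not a Burmeister CXT file (expected 'B' on line 1): ", path)
  }
  # line 2 is blank by convention; counts follow
  i <- 2L
  while (i <= length(lines) && trimws(lines[i]) == "") i <- i + 1L
  n_obj <- suppressWarnings(as.integer(trimws(lines[i])))
  n_att <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
  if (is.na(n_obj) || is.na(n_att)) {
    stop("malformed CXT header counts at lines ", i, "-", i + 1L, " in ", path)
  }
  i <- i + 2L
  while (i <= length(lines) && trimws(lines[i]) == "") i <- i + 1L
  if (length(lines) < i + n_obj + n_att + n_obj - 1L) {
    stop("CXT file truncated: ", path)
  }
  objects <- lines[i:(i + n_obj - 1L)]
  attributes <- lines[(i + n_obj):(i + n_obj + n_att - 1L)]
  rows <- lines[(i + n_obj + n_att):(i + n_obj + n_att + n_obj - 1L)]
  inc <- matrix(FALSE, n_obj, n_att)
  for (r in seq_len(n_obj)) {
    chars <- strsplit(rows[r], "", fixed = TRUE)[[1]]
    if (length(chars) != n_att) {
      stop("CXT incidence row ", r, " has ", length(chars),
           " cells, expected ", n_att, " in ", path)
    }
    ok <- chars %in% c(".", "X", "x")
    if (!all(ok)) {
      stop("invalid CXT cell '", chars[which(!ok)[1]], "' in incidence row ", r)
    }
    inc[r, ] <- chars %in% c("X", "x")
  }
  formal_context(inc, objects = objects, attributes = attributes)
}

#' Write a formal context to CSV or Burmeister CXT
#'
#' @param ctx a [formal_context].
#' @param path output path.
#' @param format `"csv"` or `"cxt"`; default decided by file extension
#'   (`.cxt` gives CXT, anything else CSV).
#' @return `path`, invisibly.
#' @details Round trip is lossless: `read_context(write_context(ctx, f))`
#'   reproduces `ctx` bit-exactly, including object/attribute order.
#' @export
write_context <- function(ctx, path, format = c("auto", "csv", "cxt")) {
  stopifnot(inherits(ctx, "formal_context"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "cxt") "cxt" else "csv"
  }
  if (format == "csv") {
    df <- data.frame(object = ctx$objects,
                     matrix(as.integer(ctx$incidence), nrow = length(ctx$objects),
                            dimnames = list(NULL, ctx$attributes)),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    rows <- apply(ctx$incidence, 1, function(r) paste(ifelse(r, "X", "."), collapse = ""))
    writeLines(c("B", "",
                 as.character(length(ctx$objects)),
                 as.character(length(ctx$attributes)),
                 "",
                 ctx$objects, ctx$attributes, rows),
               path)
  }
  invisible(path)
}

#' Construct a continuous feature matrix
#'
#' Container for real-valued per-object features (for example, high-level
#' embeddings extracted from a CNN) prior to binarization.
#'
#' @param values numeric matrix, one row per object, one column per feature;
#'   all values must be finite.
#' @param objects character vector of unique object identifiers.
#' @param features character vector of unique feature names.
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, objects = NULL, features = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(objects)) {
    objects <- rownames(values)
    if (is.null(objects)) objects <- as.character(seq_len(nrow(values)))
  }
  if (is.null(features)) {
    features <- colnames(values)
    if (is.null(features)) features <- sprintf("f%d", seq_len(ncol(values)))
  }
  objects <- as.character(objects)
  features <- as.character(features)
  if (anyDuplicated(objects)) stop("duplicate object identifiers")
  if (anyDuplicated(features)) stop("duplicate feature names")
  if (nrow(values) != length(objects) || ncol(values) != length(features)) {
    stop("values must be ", length(objects), " x ", length(features))
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop("non-finite value at row ", bad[1], ", column ", bad[2])
  }
  dimnames(values) <- list(objects, features)
  structure(list(objects = objects, features = features, values = values),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix: ", length(x$objects), " objects x ",
      length(x$features), " features\n", sep = "")
  invisible(x)
}

#' Read a continuous feature matrix from CSV
#'
#' Expects a header `object,<feat1>,...,<featN>` and real-valued cells;
#' NaN/Inf and empty cells are rejected at load time.
#'
#' @param path path to the CSV file.
#' @return a [feature_matrix].
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, strip.white = TRUE)
  if (ncol(df) < 2) stop("feature CSV needs an object column plus features: ", path)
  if (tolower(names(df)[1]) != "object") {
    stop("feature CSV header must start with 'object', got '", names(df)[1], "'")
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  feature_matrix(vals, objects = as.character(df[[1]]), features = names(df)[-1])
}

#' Read per-object class labels from CSV
#'
#' Expects a header `object,label`. Labels are kept as character strings.
#'
#' @param path path to the CSV file.
#' @return named character vector of labels, names = object identifiers.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        strip.white = TRUE)
  if (ncol(df) < 2 || tolower(names(df)[1]) != "object" ||
      tolower(names(df)[2]) != "label") {
    stop("labels CSV must have header 'object,label': ", path)
  }
  stats::setNames(df[[2]], df[[1]])
}
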