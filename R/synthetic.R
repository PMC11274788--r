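#' Synthetic data generator with known class structure
#'
#' Generates class-conditional data emulating binarized high-level image
#' features (for example, a 16-dimensional CNN embedding thresholded into
#' presence/absence bits). Each class owns a disjoint "signature" subset of
#' attributes: in binary mode a signature attribute is 1 with probability
#' `p_signal` inside its class and every other attribute is 1 with
#' probability `p_noise`; in continuous mode signature features are drawn
#' from a high-mean Gaussian and the rest from a low-mean Gaussian, to
#' exercise the binarization step. The seed fully determines the output.
#'
#' @param n_per_class integer vector: number of objects per class (recycled
#'   from a scalar across `n_classes`).
#' @param n_attributes total number of attributes; default 16, the
#'   embedding width the classifier is designed around.
#' @param n_classes number of classes; default 2 (benign/malignant-style
#'   binary labels `"0"` and `"1"`).
#' @param signatures optional list of disjoint attribute-index vectors, one
#'   per class; default splits the attributes evenly between classes.
#' @param p_signal probability a signature attribute is present within its
#'   class (binary mode); default 0.9.
#' @param p_noise probability any other attribute is present; default 0.05.
#'   Must satisfy `0 <= p_noise < p_signal <= 1`.
#' @param mode `"binary"` (default) or `"continuous"`.
#' @param signal_mean,noise_mean,feature_sd Gaussian parameters for
#'   continuous mode: signature features ~ N(`signal_mean`, `feature_sd`),
#'   others ~ N(`noise_mean`, `feature_sd`). Defaults 1, 0 and 0.25, so a
#'   min-max binarizer at threshold 0.5 recovers the binary structure.
#' @param seed integer seed; required for reproducibility.
#' @return a list with `x` (binary 0/1 matrix in binary mode, a
#'   [feature_matrix] in continuous mode; objects named `s1, s2, ...`),
#'   `labels` (character vector `"0", "1", ...`, one per row) and
#'   `signatures` (the attribute-name signature sets actually used).
#' @examples
#' d <- generate_synthetic(n_per_class = 10, n_attributes = 8, seed = 1)
#' table(d$labels)
#' @export
generate_synthetic <- function(n_per_class = 100, n_attributes = 16,
                               n_classes = 2, signatures = NULL,
                               p_signal = 0.9, p_noise = 0.05,
                               mode = c("binary", "continuous"),
                               signal_mean = 1, noise_mean = 0,
                               feature_sd = 0.25, seed) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("a seed is required for reproducible generation")
  if (!(p_noise >= 0 && p_noise < p_signal && p_signal <= 1)) {
    stop("need 0 <= p_noise < p_signal <= 1, got p_noise=", p_noise,
         ", p_signal=", p_signal)
  }
  n_per_class <- rep_len(as.integer(n_per_class), n_classes)
  if (is.null(signatures)) {
    # even split of attribute indices across classes
    cut <- split(seq_len(n_attributes),
                 rep(seq_len(n_classes), length.out = n_attributes,
                     each = ceiling(n_attributes / n_classes))[seq_len(n_attributes)])
    signatures <- cut[seq_len(n_classes)]
  }
  if (length(signatures) != n_classes) stop("need one signature set per class")
  allsig <- unlist(signatures)
  if (anyDuplicated(allsig)) stop("signature sets must be pairwise disjoint")
  if (any(allsig < 1 | allsig > n_attributes)) stop("signature index out of range")
  set.seed(seed)
  n_total <- sum(n_per_class)
  atts <- letters_names(n_attributes)
  labels <- rep(as.character(seq_len(n_classes) - 1L), times = n_per_class)
  prob <- matrix(p_noise, n_total, n_attributes)
  mu <- matrix(noise_mean, n_total, n_attributes)
  row0 <- cumsum(c(0, n_per_class))
  for (k in seq_len(n_classes)) {
    rows <- (row0[k] + 1):row0[k + 1]
    prob[rows, signatures[[k]]] <- p_signal
    mu[rows, signatures[[k]]] <- signal_mean
  }
  ids <- paste0("s", seq_len(n_total))
  if (mode == "binary") {
    x <- matrix(as.integer(stats::runif(n_total * n_attributes) < prob),
                n_total, n_attributes, dimnames = list(ids, atts))
  } else {
    vals <- matrix(stats::rnorm(n_total * n_attributes, mean = mu,
                                sd = feature_sd),
                   n_total, n_attributes, dimnames = list(ids, atts))
    x <- feature_matrix(vals, objects = ids, features = atts)
  }
  list(x = x, labels = labels,
       signatures = lapply(signatures, function(s) atts[s]))
}

# attribute names a, b, ..., z, a1, b1, ... for arbitrary width
letters_names <- function(n) {
  if (n <= 26) return(letters[seq_len(n)])
  paste0(rep(letters, length.out = n),
         rep(c("", seq_len(ceiling(n / 26) - 1)), each = 26)[seq_len(n)])
}
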