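test_that("fitting the worked example reproduces the hand-traced labels", {
  m <- fca_fit(worked_incidence(), worked_labels())
  intents <- vapply(m$lattice$concepts, function(p) paste(p$intent, collapse = ","),
                    character(1))

  i_ab <- which(intents == "a,b")
  expect_identical(m$concept_labels[i_ab], "1")
  expect_identical(unname(m$concept_counts[i_ab, ]), c(0L, 4L))

  # extent of {a,c} is {5,6}: one label each -> tie, broken to the smaller
  # class label, and recorded
  i_ac <- which(intents == "a,c")
  expect_identical(m$concept_labels[i_ac], "0")
  expect_identical(unname(m$concept_counts[i_ac, ]), c(1L, 1L))
  expect_true(i_ac %in% m$tie_log)

  # the empty-extent bottom concept carries no label
  i_bot <- which(intents == "a,b,c,d")
  expect_true(is.na(m$concept_labels[i_bot]))
  # every non-empty-extent concept is labeled
  sizes <- vapply(m$lattice$concepts, function(p) length(p$extent), integer(1))
  expect_identical(is.na(m$concept_labels), sizes == 0)
})

test_that("duplicate rows accumulate a label multiset on one unique vector", {
  m <- fca_fit(worked_incidence(), worked_labels())
  # rows 2 and 3 are identical (1,1,0,0): one unique vector, two labels
  expect_identical(nrow(m$unique_vectors), 5L)
  key <- apply(worked_incidence(), 1, paste, collapse = "")
  dup_uid <- rownames(m$unique_vectors)[
    apply(m$unique_vectors, 1, paste, collapse = "") == key[["2"]]]
  expect_identical(m$label_multisets[[dup_uid]], c("1", "1"))
  # label conservation: top-concept tally equals the training-set size
  expect_identical(sum(m$concept_counts[m$lattice$top, ]), 6L)
  expect_identical(sum(lengths(m$label_multisets)), 6L)
})

test_that("degenerate training sets are handled", {
  x <- matrix(c(1, 0, 1, 0, 1, 0), 3, 2, byrow = TRUE,
              dimnames = list(NULL, c("a", "b")))
  m <- suppressWarnings(fca_fit(x, c("z", "z", "z")))
  expect_identical(nrow(m$unique_vectors), 1L)
  labeled <- m$concept_labels[!is.na(m$concept_labels)]
  expect_true(all(labeled == "z"))
  expect_warning(fca_fit(x, c("z", "z", "z")), "single class")
  expect_error(fca_fit(x[0, , drop = FALSE], character(0)), "empty")
  expect_error(fca_fit(matrix(2, 1, 1), "a"), "binary")
  expect_error(fca_fit(x, "z"), "one label per")
})

test_that("hamming counts differing positions against the intent indicator", {
  M <- c("a", "b", "c", "d")
  expect_identical(hamming(c(1, 1, 0, 0), c("a", "b"), M), 0L)
  expect_identical(hamming(c(1, 0, 1, 0), c("a", "b"), M), 2L)
  expect_identical(hamming(rep(1, 4), character(0), M), 4L)
  expect_error(hamming(c(1, 0), c("a"), M), "does not match")
  expect_error(hamming(c(1, 0, 0, 0), "zz", M), "not in attribute list")
})

test_that("prediction follows the nearest labeled intent with documented ties", {
  m <- fca_fit(worked_incidence(), worked_labels())
  test <- matrix(c(1, 1, 0, 0,
                   1, 0, 1, 0), 2, 4, byrow = TRUE,
                 dimnames = list(c("t1", "t2"), c("a", "b", "c", "d")))
  p <- predict(m, test)
  expect_identical(p$object, c("t1", "t2"))
  expect_identical(p$predicted_label, c("1", "0"))
  expect_identical(p$distance, c(0L, 0L))
  intents <- vapply(m$lattice$concepts, function(q) paste(q$intent, collapse = ","),
                    character(1))
  expect_identical(intents[p$concept_index], c("a,b", "a,c"))
  expect_error(predict(m, test[, c(2, 1, 3, 4)]), "name/order")
  expect_error(predict(m, test[, 1:3]), "columns")
})

test_that("zero-distance exact matches dominate prediction", {
  set.seed(31)
  for (i in 1:10) {
    d <- generate_synthetic(n_per_class = 30, n_attributes = 8,
                            p_signal = 0.95, p_noise = 0.05, seed = 100 + i)
    m <- fca_fit(d$x, d$labels, order = FALSE)
    lab_idx <- which(!is.na(m$concept_labels))
    atts <- m$context$attributes
    for (k in sample(lab_idx, min(5, length(lab_idx)))) {
      intent <- m$lattice$concepts[[k]]$intent
      x <- matrix(as.integer(atts %in% intent), 1,
                  dimnames = list("q", atts))
      others <- setdiff(lab_idx, k)
      d_others <- vapply(others, function(j)
        hamming(x, m$lattice$concepts[[j]]$intent, atts), integer(1))
      if (all(d_others > 0)) {
        p <- predict(m, x)
        expect_identical(p$predicted_label, m$concept_labels[k])
        expect_identical(p$distance, 0L)
        expect_identical(p$n_tied, 1L)
      }
    }
  }
})

test_that("concept labels are invariant under training-row permutation", {
  set.seed(37)
  d <- generate_synthetic(n_per_class = 40, n_attributes = 8,
                          p_signal = 0.9, p_noise = 0.1, seed = 55)
  m1 <- fca_fit(d$x, d$labels, order = FALSE)
  perm <- sample(nrow(d$x))
  m2 <- fca_fit(d$x[perm, , drop = FALSE], d$labels[perm], order = FALSE)
  key <- function(m) {
    intents <- vapply(m$lattice$concepts, function(p)
      paste(sort(p$intent), collapse = ","), character(1))
    stats::setNames(m$concept_labels, intents)[order(intents)]
  }
  expect_identical(key(m1), key(m2))
})

test_that("rules carry duplicate-aware support and confidence, sorted", {
  m <- fca_fit(worked_incidence(), worked_labels())
  r <- extract_rules(m)
  expect_identical(nrow(r), 5L)  # the empty-extent concept emits no rule
  ab <- r[r$intent == "a,b", ]
  expect_identical(ab$class, "1")
  expect_identical(ab$support, 4L)
  expect_equal(ab$confidence, 1.0)
  # class-pure concepts get confidence exactly 1
  expect_true(all(r$confidence[r$intent %in% c("a,b", "a,b,d", "a,b,c")] == 1))
  expect_equal(r[r$intent == "a,c", "confidence"], 0.5)
  expect_true(all(diff(r$confidence) <= 0))
  expect_true(all(diff(r$support[r$confidence == 1]) <= 0))
})

test_that("feature/class summary reports associations and co-occurrence", {
  m <- fca_fit(worked_incidence(), worked_labels())
  s <- feature_class_summary(m)
  assoc <- s$association
  # b appears only in class-1-labeled intents
  expect_equal(assoc[assoc$attribute == "b", "1"], 1.0)
  expect_equal(assoc[assoc$attribute == "b", "0"], 0.0)
  # b and c co-occur (in intent {a,b,c}); c and d never share an intent
  expect_true(s$cooccurrence["b", "c"] > 0)
  expect_identical(s$cooccurrence["c", "d"], 0L)
  expect_true(any(s$never_cooccur$attribute1 == "c" &
                    s$never_cooccur$attribute2 == "d"))
})

test_that("model JSON serialization round-trips bit-exact predictions", {
  d <- generate_synthetic(n_per_class = 25, n_attributes = 8,
                          p_signal = 0.9, p_noise = 0.1, seed = 77)
  m <- fca_fit(d$x, d$labels)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(m, f)
  back <- read_model(f)
  expect_identical(back$concept_labels, m$concept_labels)
  expect_identical(back$classes, m$classes)
  expect_identical(unname(back$concept_counts), unname(m$concept_counts))
  expect_identical(back$tie_log, m$tie_log)
  test <- generate_synthetic(n_per_class = 10, n_attributes = 8,
                             p_signal = 0.9, p_noise = 0.1, seed = 78)
  expect_identical(predict(back, test$x), predict(m, test$x))
})

test_that("continuous pipeline: binarizer is stored and reapplied at predict", {
  d <- generate_synthetic(n_per_class = 40, n_attributes = 10,
                          mode = "continuous", seed = 91)
  m <- fca_fit(d$x, d$labels, spec = binarizer("minmax", 0.5), order = FALSE)
  expect_false(is.null(m$binarizer))
  t2 <- generate_synthetic(n_per_class = 20, n_attributes = 10,
                           mode = "continuous", seed = 92)
  p <- predict(m, t2$x)
  expect_identical(nrow(p), 40L)
  expect_gt(mean(p$predicted_label == t2$labels), 0.8)
  # round-trip through JSON preserves the binarizer
  f <- withr::local_tempfile(fileext = ".json")
  write_model(m, f)
  expect_identical(predict(read_model(f), t2$x), p)
})
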