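# Shared fixtures: the 6-object, 4-attribute worked-example context and a
# random-context generator for property tests.

worked_incidence <- function() {
  matrix(c(1, 0, 0, 0,
           1, 1, 0, 0,
           1, 1, 0, 0,
           1, 1, 0, 1,
           1, 1, 1, 0,
           1, 0, 1, 0),
         ncol = 4, byrow = TRUE,
         dimnames = list(as.character(1:6), c("a", "b", "c", "d")))
}

worked_context <- function() {
  formal_context(worked_incidence())
}

worked_labels <- function() {
  c("1" = "0", "2" = "1", "3" = "1", "4" = "1", "5" = "1", "6" = "0")
}

random_context <- function(n_obj, n_att, density = 0.5) {
  inc <- matrix(as.integer(stats::runif(n_obj * n_att) < density),
                n_obj, n_att,
                dimnames = list(paste0("g", seq_len(n_obj)),
                                paste0("m", seq_len(n_att))))
  formal_context(inc)
}

# order-free representation of a concept list for set comparisons
concept_set <- function(concepts) {
  keys <- vapply(concepts, function(p) {
    paste(paste(sort(p$extent), collapse = ","),
          paste(sort(p$intent), collapse = ","), sep = " | ")
  }, character(1))
  sort(keys)
}
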