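#' Patient-level cross-validated split plan
#'
#' Randomly partitions the patient ids into five near-equal subsets
#' (sizes differing by at most one). In each of the five rounds, four
#' subsets form the training set and the remaining subset is held out and
#' split at patient level between the test set (`ceiling(k/2)` patients)
#' and the validation set (`floor(k/2)`), giving the
#' training:validation:test ratio of roughly 0.8:0.1:0.1. Train,
#' validation and test patients are pairwise disjoint within a round;
#' test sets are pairwise disjoint across rounds; and over the five
#' rounds the union of test and validation patients consumes the entire
#' cohort exactly once (for 96 patients: 50 test, 46 validation in
#' total).
#'
#' @param patient_ids character vector of unique patient ids (>= 10).
#' @param seed integer seed (plan is reproducible from it).
#' @param n_rounds number of rounds/subsets (default 5).
#' @return An object of class `split_plan`: list with `rounds` (each a
#'   list of `train`, `validation`, `test` id vectors), `subsets`, and
#'   `seed`.
#' @export
make_splits <- function(patient_ids, seed = 1, n_rounds = 5) {
  patient_ids <- as.character(patient_ids)
  if (anyDuplicated(patient_ids)) stop("patient_ids must be unique")
  n <- length(patient_ids)
  if (n < 10) stop("need at least 10 patients")
  with_seed(seed, {
    ids <- sample(patient_ids)
    base <- n %/% n_rounds
    sizes <- rep(base, n_rounds) + c(rep(1L, n %% n_rounds),
                                     rep(0L, n_rounds - n %% n_rounds))
    subsets <- split(ids, rep(seq_len(n_rounds), times = sizes))
    rounds <- lapply(seq_len(n_rounds), function(r) {
      held <- subsets[[r]]
      k <- length(held)
      test <- held[seq_len(ceiling(k / 2))]
      validation <- setdiff(held, test)
      list(train = unlist(subsets[-r], use.names = FALSE),
           validation = validation, test = test)
    })
    structure(list(rounds = rounds, subsets = subsets, seed = seed),
              class = "split_plan")
  })
}

#' @export
print.split_plan <- function(x, ...) {
  sz <- vapply(x$rounds, function(r)
    sprintf("%d/%d/%d", length(r$train), length(r$validation),
            length(r$test)), character(1))
  cat(sprintf("<split_plan> %d rounds (train/val/test): %s\n",
              length(x$rounds), paste(sz, collapse = ", ")))
  invisible(x)
}
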