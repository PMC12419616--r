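#' Build the binary dataset for one prediction horizon
#'
#' Positives are patient states `n` days before death; negatives are the
#' same cohort's states `negative_day` days before death (a self-referenced
#' design, so the label ratio is exactly 1:1 by construction). A patient is
#' included iff at least `min_observed` features are unmasked at both
#' anchor days.
#'
#' @param set a `patient_matrix_set` from [resample_cohort()].
#' @param n prediction horizon in days (1 <= n < negative_day).
#' @param negative_day negative reference day (default 168 = 24 weeks).
#' @param min_observed minimum number of unmasked features required at
#'   each anchor day for inclusion (default 1).
#' @return A `horizon_dataset`: list with `horizon`, `X` (feature matrix
#'   with `NA` missing markers; two rows per included patient), `y`
#'   (1 = dies `n` days later, 0 = negative reference), `patient_id`,
#'   `role` (`"positive"`/`"negative"`), `features`.
#' @export
build_horizon_dataset <- function(set, n, negative_day = 168, min_observed = 1) {
  stopifnot(inherits(set, "patient_matrix_set"))
  if (n < 1 || n >= negative_day)
    stop("horizon must satisfy 1 <= n < negative_day")
  if (!all(c(n, negative_day) %in% set$days))
    stop("anchor days not on the resampled grid")
  pos <- extract_day_matrix(set, n)
  neg <- extract_day_matrix(set, negative_day)
  ok <- rowSums(!is.na(pos)) >= min_observed & rowSums(!is.na(neg)) >= min_observed
  if (!any(ok)) {
    return(structure(list(horizon = as.integer(n), X = pos[0, , drop = FALSE],
                          y = integer(0), patient_id = character(0),
                          role = character(0), features = set$features,
                          negative_day = as.integer(negative_day),
                          empty = TRUE),
                     class = "horizon_dataset"))
  }
  pos <- pos[ok, , drop = FALSE]
  neg <- neg[ok, , drop = FALSE]
  ids <- set$patient_ids[ok]
  structure(list(horizon = as.integer(n),
                 X = rbind(pos, neg),
                 y = c(rep(1L, nrow(pos)), rep(0L, nrow(neg))),
                 patient_id = c(ids, ids),
                 role = rep(c("positive", "negative"), each = length(ids)),
                 features = set$features,
                 negative_day = as.integer(negative_day),
                 empty = FALSE),
            class = "horizon_dataset")
}

#' @export
print.horizon_dataset <- function(x, ...) {
  cat(sprintf("<horizon_dataset> n = %d days, %d patients (%d rows, 1:1 balanced), %d features\n",
              x$horizon, length(unique(x$patient_id)), length(x$y),
              length(x$features)))
  invisible(x)
}

#' Patient-level train/validation/test split
#'
#' Partitions patients (never rows) into test, validation and train sets,
#' so both rows of a patient always share one assignment and no patient
#' can leak across the split.
#'
#' @param dataset a `horizon_dataset` (or a character vector of patient ids).
#' @param test_fraction fraction of patients held out for testing
#'   (default 0.2).
#' @param validation_fraction_of_train fraction of the remaining training
#'   patients set aside for validation (default 0.2, i.e. a 4:1 split).
#' @param seed RNG seed for the shuffle.
#' @return A `split_plan` data.frame with `patient_id` and `assignment`.
#' @export
grouped_split <- function(dataset, test_fraction = 0.2,
                          validation_fraction_of_train = 0.2, seed = 0) {
  ids <- if (inherits(dataset, "horizon_dataset"))
    unique(dataset$patient_id) else unique(as.character(dataset))
  n <- length(ids)
  if (n < 5) stop("need at least 5 patients to split")
  set.seed(seed)
  ids <- sample(ids)
  n_test <- round(n * test_fraction)
  n_val <- round((n - n_test) * validation_fraction_of_train)
  if (n_test < 1 || n_val < 1 || n - n_test - n_val < 1)
    stop("too few patients for the requested fractions")
  assignment <- rep("train", n)
  assignment[seq_len(n_test)] <- "test"
  assignment[n_test + seq_len(n_val)] <- "validation"
  plan <- data.frame(patient_id = ids, assignment = assignment,
                     stringsAsFactors = FALSE)
  plan <- plan[order(plan$patient_id), ]
  rownames(plan) <- NULL
  class(plan) <- c("split_plan", "data.frame")
  plan
}

# Row indices of a horizon dataset belonging to a split-plan subset.
split_rows <- function(dataset, plan, which) {
  keep <- plan$patient_id[plan$assignment %in% which]
  which(dataset$patient_id %in% keep)
}
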