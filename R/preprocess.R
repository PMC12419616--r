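#' Align calendar-dated events to the days-before-death axis
#'
#' Converts calendar timestamps to the canonical time coordinate used
#' throughout the package: integer days before death, with death at day 0.
#' Events after the recorded death date are dropped with a warning.
#'
#' @param events data.frame with `patient_id`, `date` (Date or ISO-8601
#'   string), `parameter`, `value`.
#' @param deaths data.frame with `patient_id`, `death_date`.
#' @return event table with a `days_before_death` column.
#' @export
align_events_to_death <- function(events, deaths) {
  stopifnot(all(c("patient_id", "date", "parameter", "value") %in% names(events)),
            all(c("patient_id", "death_date") %in% names(deaths)))
  dd <- as.Date(deaths$death_date[match(events$patient_id, deaths$patient_id)])
  if (anyNA(dd)) stop("death date missing for some patients")
  days <- as.integer(dd - as.Date(events$date))
  bad <- days < 0
  if (any(bad)) {
    warning(sum(bad), " events dated after death were dropped")
    events <- events[!bad, , drop = FALSE]
    days <- days[!bad]
  }
  events$days_before_death <- days
  events[, c("patient_id", "days_before_death", "parameter", "value")]
}

#' Keep only the first laboratory result per patient, day and parameter
#'
#' When the same analyte is measured more than once on a day, the earliest
#' result is retained. Intra-day order is taken from a `timestamp` column
#' when present, otherwise from stable input order (with a warning if that
#' fallback is actually exercised).
#'
#' @param events long-format event table.
#' @return deduplicated event table.
#' @export
dedup_first_per_day <- function(events) {
  stopifnot(all(c("patient_id", "days_before_death", "parameter", "value")
                %in% names(events)))
  key <- interaction(events$patient_id, events$days_before_death,
                     events$parameter, drop = TRUE)
  if (!anyDuplicated(key)) return(events)
  if ("timestamp" %in% names(events)) {
    ord <- order(key, events$timestamp)
  } else {
    warning("same-day duplicates without a timestamp: keeping first by input order")
    ord <- order(key, seq_len(nrow(events)))
  }
  ev <- events[ord, , drop = FALSE]
  keep <- !duplicated(key[ord])
  out <- ev[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Retain parameters measured in more than a given fraction of patients
#'
#' A parameter is kept iff strictly more than `min_patient_fraction` of the
#' patients have at least one event for it. Also reports the patients who
#' lack any event for a retained parameter, for the follow-on exclusion
#' rule.
#'
#' @param events long-format event table.
#' @param min_patient_fraction coverage threshold (default 0.5, i.e. "more
#'   than half of the patients").
#' @return list with `parameters` (kept, sorted), `excluded_patients`
#'   (ids lacking a retained parameter entirely), and `coverage`
#'   (data.frame of per-parameter patient fractions).
#' @export
coverage_filter <- function(events, min_patient_fraction = 0.5) {
  if (!nrow(events)) stop("empty event table")
  pats <- unique(events$patient_id)
  n <- length(pats)
  tab <- unique(events[, c("patient_id", "parameter")])
  cov <- table(tab$parameter) / n
  keep <- names(cov)[as.numeric(cov) > min_patient_fraction]
  keep <- sort(keep)
  has <- table(factor(tab$patient_id[tab$parameter %in% keep], levels = pats),
               factor(tab$parameter[tab$parameter %in% keep], levels = keep))
  excluded <- if (length(keep)) pats[rowSums(has == 0) > 0] else pats
  list(parameters = keep,
       excluded_patients = sort(as.character(excluded)),
       coverage = data.frame(parameter = names(cov),
                             patient_fraction = as.numeric(cov),
                             stringsAsFactors = FALSE))
}

# Core windowed-mean resampler for one (patient, feature) pair is expressed
# over the whole cohort at once: cumulative sums per day bin, then window
# sums per grid day. `align = "centered"` averages raw events in
# [t - floor(w/2), t + floor(w/2)]; `"trailing"` uses [t, t + w - 1]
# (only data at or before the queried time point, looking further from
# death).
resample_core <- function(events, window_days, max_day, align, features) {
  if (window_days < 1) stop("`window_days` must be >= 1")
  align <- match.arg(align, c("centered", "trailing"))
  h <- window_days %/% 2
  lo_off <- if (align == "centered") -h else 0L
  hi_off <- if (align == "centered") h else window_days - 1L
  pats <- sort(unique(events$patient_id))
  n <- length(pats)
  if (is.null(features)) features <- sort(unique(events$parameter))
  nb <- max_day + hi_off + 1L  # day bins 0 .. max_day + hi_off
  D <- max_day + 1L
  vals <- array(NA_real_, dim = c(n, D, length(features)),
                dimnames = list(pats, as.character(0:max_day), features))
  ev <- events[events$days_before_death <= max_day + hi_off, , drop = FALSE]
  pi <- match(ev$patient_id, pats)
  for (j in seq_along(features)) {
    sel <- ev$parameter == features[j]
    if (!any(sel)) next
    key <- ev$days_before_death[sel] * n + pi[sel]  # column-major cell index
    S <- matrix(0, n, nb)
    C <- matrix(0, n, nb)
    sums <- rowsum(ev$value[sel], key)
    cnts <- rowsum(rep(1, sum(sel)), key)
    pos <- as.integer(rownames(sums))
    S[pos] <- sums
    C[pos] <- cnts
    CS <- cbind(0, t(apply(S, 1, cumsum)))
    CC <- cbind(0, t(apply(C, 1, cumsum)))
    for (t in 0:max_day) {
      lo <- max(0L, t + lo_off)
      hi <- min(nb - 1L, t + hi_off)
      cnt <- CC[, hi + 2] - CC[, lo + 1]
      val <- (CS[, hi + 2] - CS[, lo + 1]) / ifelse(cnt > 0, cnt, NA_real_)
      vals[, t + 1, j] <- val
    }
  }
  structure(list(values = vals, days = 0:max_day, features = features,
                 patient_ids = pats, window_days = as.integer(window_days),
                 align = align),
            class = "patient_matrix_set")
}

#' Resample one patient's events onto a daily grid by moving average
#'
#' The estimate at day `t` before death is the arithmetic mean of the raw
#' values whose day falls in the smoothing window; a grid cell with no raw
#' event in its window is masked (`NA`).
#'
#' @param events events for a single patient (deduplicated, aligned to
#'   days before death).
#' @param window_days moving-average window width in days (default 5).
#' @param max_day last grid day (default: latest event day).
#' @param align `"centered"` (default) or `"trailing"` window alignment.
#' @param features feature set and order for the columns (default: those
#'   present).
#' @return a days x features matrix (class `patient_matrix`) with
#'   attributes `patient_id`, `days`, `window_days`.
#' @export
resample_moving_average <- function(events, window_days = 5, max_day = NULL,
                                    align = "centered", features = NULL) {
  stopifnot(length(unique(events$patient_id)) == 1)
  if (is.null(max_day)) max_day <- max(events$days_before_death)
  set <- resample_core(events, window_days, as.integer(max_day), align, features)
  m <- set$values[1, , , drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, ncol = length(set$features),
                                   dimnames = list(as.character(set$days),
                                                   set$features))
  structure(m, class = c("patient_matrix", class(m)),
            patient_id = set$patient_ids[1], days = set$days,
            window_days = set$window_days, align = set$align)
}

#' Resample a whole cohort onto the daily grid
#'
#' @inheritParams resample_moving_average
#' @param events long-format event table for many patients.
#' @return a `patient_matrix_set`: list with `values` (patients x days x
#'   features array, `NA` = masked), `days`, `features`, `patient_ids`.
#' @export
resample_cohort <- function(events, window_days = 5, max_day = NULL,
                            align = "centered", features = NULL) {
  if (is.null(max_day)) max_day <- max(events$days_before_death)
  resample_core(events, window_days, as.integer(max_day), align, features)
}

#' Extract the feature vector of one patient at one day
#'
#' Missing cells stay `NA` (flagged, never imputed); the caller decides
#' how to treat them.
#'
#' @param matrix a `patient_matrix` (single patient).
#' @param t day before death, within the grid.
#' @return named numeric vector (one entry per feature).
#' @export
extract_day_vector <- function(matrix, t) {
  days <- attr(matrix, "days")
  if (!t %in% days) stop("day ", t, " outside the resampled grid")
  row <- matrix[match(t, days), , drop = FALSE]
  setNames(as.vector(row), colnames(matrix))
}

#' Extract the day-`t` slice of a cohort matrix set
#'
#' @param set a `patient_matrix_set`.
#' @param t day before death.
#' @return patients x features matrix (rownames = patient ids).
#' @export
extract_day_matrix <- function(set, t) {
  stopifnot(inherits(set, "patient_matrix_set"))
  if (!t %in% set$days) stop("day ", t, " outside the resampled grid")
  m <- set$values[, match(t, set$days), , drop = FALSE]
  matrix(m, nrow = length(set$patient_ids),
         dimnames = list(set$patient_ids, set$features))
}

#' Serialize resampled matrices to tidy CSV
#'
#' One row per (patient, day, feature) cell, with the observed flag; the
#' inverse of [read_patient_matrices()].
#'
#' @param set a `patient_matrix_set`.
#' @param path output CSV path.
#' @param days subset of grid days to write (default: all).
#' @export
write_patient_matrices <- function(set, path, days = set$days) {
  stopifnot(inherits(set, "patient_matrix_set"), all(days %in% set$days))
  di <- match(days, set$days)
  grid <- expand.grid(patient_id = set$patient_ids, day = days,
                      parameter = set$features, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid$value <- as.vector(set$values[, di, , drop = FALSE])
  grid$observed <- !is.na(grid$value)
  write.csv(grid, path, row.names = FALSE)
  invisible(path)
}

#' Read resampled matrices from tidy CSV
#'
#' @param path CSV written by [write_patient_matrices()].
#' @param window_days,align metadata to restore on the object.
#' @return a `patient_matrix_set` over the days present in the file.
#' @export
read_patient_matrices <- function(path, window_days = 5, align = "centered") {
  tidy <- read.csv(path, stringsAsFactors = FALSE)
  pats <- sort(unique(tidy$patient_id))
  days <- sort(unique(tidy$day))
  feats <- sort(unique(tidy$parameter))
  vals <- array(NA_real_, dim = c(length(pats), length(days), length(feats)),
                dimnames = list(pats, as.character(days), feats))
  idx <- cbind(match(tidy$patient_id, pats), match(tidy$day, days),
               match(tidy$parameter, feats))
  vals[idx] <- tidy$value
  structure(list(values = vals, days = days, features = feats,
                 patient_ids = pats, window_days = as.integer(window_days),
                 align = align),
            class = "patient_matrix_set")
}
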