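#' Missingness filter for embedding features
#'
#' A feature survives iff its masked fraction across patients is below
#' `max_missing` at every requested horizon (the "at all time points"
#' quantifier: one bad horizon drops the feature).
#'
#' @param set a `patient_matrix_set`.
#' @param horizons horizons over which the filter quantifies (default
#'   1:90).
#' @param max_missing maximum tolerated masked fraction (default 0.10).
#' @return list with `features` (kept), `missing_fraction` (features x
#'   horizons matrix).
#' @export
missingness_filter <- function(set, horizons = 1:90, max_missing = 0.10) {
  stopifnot(inherits(set, "patient_matrix_set"), all(horizons %in% set$days))
  di <- match(horizons, set$days)
  mf <- matrix(NA_real_, length(set$features), length(di),
               dimnames = list(set$features, as.character(horizons)))
  for (j in seq_along(set$features))
    mf[j, ] <- colMeans(is.na(matrix(set$values[, di, j], ncol = length(di))))
  keep <- set$features[apply(mf < max_missing, 1, all)]
  if (!length(keep))
    stop("no feature passes the missingness filter; relax `max_missing`")
  list(features = keep, missing_fraction = mf)
}

#' Stack patient states across horizons for embedding
#'
#' Builds the two paired row-aligned matrices the embedding compares: one
#' of attribution vectors, one of (optionally standardized) raw resampled
#' laboratory values, with one row per (patient, horizon) pair. Rows are
#' restricted to correctly predicted positives, and samples with a missing
#' raw value on the selected features are excluded so both variants are
#' complete.
#'
#' @param set a `patient_matrix_set`.
#' @param panels per-horizon `shap_panel`s (attributed positives and
#'   negatives; positives are filtered here).
#' @param features embedding feature subset (from
#'   [missingness_filter()]).
#' @param threshold correct-positive probability threshold (default 0.5).
#' @param standardize standardize each raw-value column to zero mean and
#'   unit variance (default TRUE, as raw analytes live on incomparable
#'   scales).
#' @return A `stacked_state`: list with `shap` and `raw` matrices sharing
#'   the row index described by `meta` (`patient_id`, `horizon`).
#' @export
build_state_matrices <- function(set, panels, features, threshold = 0.5,
                                 standardize = TRUE) {
  stopifnot(inherits(set, "patient_matrix_set"),
            all(features %in% set$features))
  shap_rows <- list(); raw_rows <- list(); meta <- list()
  for (panel in panels) {
    cp <- select_correct_positives(panel, threshold)
    if (!nrow(cp$phi)) next
    raw <- extract_day_matrix(set, panel$horizon)[cp$patient_id, features,
                                                  drop = FALSE]
    ok <- complete.cases(raw)
    if (!any(ok)) next
    shap_rows[[length(shap_rows) + 1L]] <- cp$phi[ok, features, drop = FALSE]
    raw_rows[[length(raw_rows) + 1L]] <- raw[ok, , drop = FALSE]
    meta[[length(meta) + 1L]] <- data.frame(
      patient_id = cp$patient_id[ok], horizon = panel$horizon,
      stringsAsFactors = FALSE)
  }
  if (!length(shap_rows)) stop("no retained (patient, horizon) samples")
  shap <- do.call(rbind, shap_rows)
  raw <- do.call(rbind, raw_rows)
  if (standardize) raw <- scale(raw)
  meta <- do.call(rbind, meta)
  rownames(shap) <- rownames(raw) <- NULL
  structure(list(shap = shap, raw = raw, meta = meta, features = features,
                 standardized = standardize),
            class = "stacked_state")
}

#' Two-dimensional embedding of stacked patient states
#'
#' @param X numeric matrix (rows = samples).
#' @param method `"umap"` (default; euclidean metric, `n_neighbors = 10`,
#'   `min_dist = 0.5`), `"tsne"`, or `"pca"` (components ordered by
#'   explained variance).
#' @param params named list of method-specific overrides (e.g.
#'   `n_neighbors`, `min_dist`, `perplexity`).
#' @param seed RNG seed; embeddings are deterministic given input and
#'   seed (single-threaded).
#' @return data.frame with `dim1`, `dim2`.
#' @export
embed_2d <- function(X, method = c("umap", "tsne", "pca"), params = list(),
                     seed = 0) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (method == "umap") {
    nn <- params$n_neighbors %||% 10
    if (nrow(X) <= nn) stop("fewer rows than the UMAP neighborhood size")
    set.seed(seed)
    co <- uwot::umap(X, n_neighbors = nn, min_dist = params$min_dist %||% 0.5,
                     metric = params$metric %||% "euclidean",
                     n_threads = 1, n_sgd_threads = 1, batch = TRUE)
  } else if (method == "tsne") {
    per <- params$perplexity %||% min(30, floor((nrow(X) - 1) / 3))
    if (per < 1) stop("too few rows for t-SNE")
    set.seed(seed)
    co <- Rtsne::Rtsne(X, perplexity = per, check_duplicates = FALSE,
                       num_threads = 1)$Y
  } else {
    co <- prcomp(X, center = TRUE, scale. = FALSE)$x[, 1:2, drop = FALSE]
  }
  data.frame(dim1 = co[, 1], dim2 = co[, 2])
}

#' Temporal-separation score of an embedding
#'
#' Operationalizes "the embedding shows temporal transitions" as the best
#' absolute Spearman correlation between the horizon of each stacked row
#' and either embedding coordinate: a coordinate that orders samples by
#' time from death scores near 1, an embedding blind to time scores near
#' 0.
#'
#' @param coords data.frame from [embed_2d()].
#' @param horizon integer vector of per-row horizons.
#' @return single number in [0, 1].
#' @export
temporal_separation_score <- function(coords, horizon) {
  stopifnot(nrow(coords) == length(horizon))
  max(abs(spearman(coords$dim1, horizon)), abs(spearman(coords$dim2, horizon)))
}

#' Embed both state variants and score their temporal separation
#'
#' Convenience wrapper running [embed_2d()] on the attribution and
#' raw-value variants of a stacked state matrix with identical settings,
#' returning coordinates and [temporal_separation_score()]s for both.
#'
#' @param stacked a `stacked_state`.
#' @inheritParams embed_2d
#' @return list with `coords` (data.frame: `patient_id`, `horizon`,
#'   `variant`, `dim1`, `dim2`) and `scores` (named numeric: `shap`,
#'   `raw`).
#' @export
embed_state_variants <- function(stacked, method = "umap", params = list(),
                                 seed = 0) {
  stopifnot(inherits(stacked, "stacked_state"))
  co_s <- embed_2d(stacked$shap, method, params, seed)
  co_r <- embed_2d(stacked$raw, method, params, seed)
  scores <- c(shap = temporal_separation_score(co_s, stacked$meta$horizon),
              raw = temporal_separation_score(co_r, stacked$meta$horizon))
  coords <- rbind(cbind(stacked$meta, variant = "shap", co_s),
                  cbind(stacked$meta, variant = "raw", co_r))
  rownames(coords) <- NULL
  list(coords = coords, scores = scores)
}
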