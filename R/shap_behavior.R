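#' Exact Shapley attributions for a feature matrix
#'
#' Computes path-dependent TreeSHAP values for every row, in margin (log
#' odds) space and double precision: for each row,
#' `base + sum(phi) == margin` to machine precision. Missing values are
#' attributed through the trees' default (missing) branches, matching how
#' the model itself routes them.
#'
#' @param model a `horizon_model`.
#' @param X feature matrix (columns in model feature order, `NA` allowed).
#' @return list with `phi` (rows x features), `base` (scalar expected
#'   margin), `margin` (row margins, `= base + rowSums(phi)`).
#' @export
shap_values <- function(model, X) {
  stopifnot(inherits(model, "horizon_model"))
  if (!is.null(colnames(X))) {
    if (!setequal(colnames(X), model$features))
      stop("feature set of `X` does not match the model")
    X <- X[, model$features, drop = FALSE]
  } else if (ncol(X) != length(model$features)) {
    stop("feature set of `X` does not match the model")
  }
  res <- .treeshap_cpp(model$trees, X)
  colnames(res$phi) <- model$features
  res$base <- res$base + model$intercept
  res$margin <- res$margin + model$intercept
  res
}

#' Attribution panel for one horizon model
#'
#' Attributes every selected row of the horizon dataset. By default only
#' held-out (test) rows are attributed, so the panel reflects
#' out-of-sample explanations; `use = "all"` attributes the full dataset
#' (useful on small synthetic cohorts).
#'
#' @param model a `horizon_model`.
#' @param dataset the model's own `horizon_dataset`.
#' @param split the [grouped_split()] plan used in training (required for
#'   `use = "test"`).
#' @param use `"test"` (default) or `"all"`.
#' @return A `shap_panel`: list with `horizon`, `patient_id`, `label`,
#'   `phi` (rows x features, margin units), `base`, `margin`, `prob`.
#' @export
attribute_panel <- function(model, dataset, split = NULL,
                            use = c("test", "all")) {
  stopifnot(inherits(model, "horizon_model"),
            inherits(dataset, "horizon_dataset"))
  if (dataset$horizon != model$horizon)
    stop("dataset horizon does not match the model")
  use <- match.arg(use)
  idx <- if (use == "test") {
    if (is.null(split)) stop("`use = \"test\"` requires the split plan")
    split_rows(dataset, split, "test")
  } else seq_along(dataset$y)
  sv <- shap_values(model, dataset$X[idx, , drop = FALSE])
  structure(list(horizon = dataset$horizon,
                 patient_id = dataset$patient_id[idx],
                 label = dataset$y[idx],
                 phi = sv$phi, base = sv$base, margin = sv$margin,
                 prob = plogis(sv$margin)),
            class = "shap_panel")
}

#' @export
print.shap_panel <- function(x, ...) {
  cat(sprintf("<shap_panel> horizon = %d days, %d rows x %d features\n",
              x$horizon, nrow(x$phi), ncol(x$phi)))
  invisible(x)
}

# Subset a panel's rows, keeping all parallel fields aligned.
panel_subset <- function(panel, idx) {
  structure(list(horizon = panel$horizon,
                 patient_id = panel$patient_id[idx],
                 label = panel$label[idx],
                 phi = panel$phi[idx, , drop = FALSE],
                 base = panel$base,
                 margin = panel$margin[idx],
                 prob = panel$prob[idx]),
            class = "shap_panel")
}

#' Restrict a panel to correctly predicted positives
#'
#' Keeps rows with true label 1 whose predicted death probability reaches
#' the classification threshold; only these rows enter behavior estimation
#' and stratification. An empty result is returned as a zero-row panel
#' (flagged via its row count) rather than being treated as zeros.
#'
#' @param panel a `shap_panel`.
#' @param threshold probability threshold (default 0.5).
#' @return the filtered `shap_panel`.
#' @export
select_correct_positives <- function(panel, threshold = 0.5) {
  stopifnot(inherits(panel, "shap_panel"))
  keep <- which(panel$label == 1 & panel$prob >= threshold)
  out <- panel_subset(panel, keep)
  attr(out, "n_dropped") <- nrow(panel$phi) - length(keep)
  out
}

#' Max-scaled mean attributions at one horizon
#'
#' The signed mean attribution of each feature over the panel's rows,
#' divided by the largest absolute mean, so the dominant feature sits at
#' +/-1 and every entry lies in [-1, 1].
#'
#' @param panel a `shap_panel` (usually after
#'   [select_correct_positives()]).
#' @return list with `scaled` (s_j), `mean` (unscaled m_j), `scale_factor`
#'   (max_j |m_j|), `n` (rows used).
#' @export
scaled_mean_shap <- function(panel) {
  stopifnot(inherits(panel, "shap_panel"))
  if (!nrow(panel$phi)) stop("no rows retained in the panel")
  m <- colMeans(panel$phi)
  sf <- max(abs(m))
  if (sf == 0) stop("all attributions are zero: scale undefined")
  list(scaled = m / sf, mean = m, scale_factor = sf, n = nrow(panel$phi))
}

#' Assemble the behavior matrix across horizons
#'
#' Column `n` holds the max-scaled mean attributions of horizon `n`'s
#' panel; the per-horizon scale factors and retained sample counts are
#' kept alongside. Horizons whose panel retained no row are marked
#' unavailable (`NA` column), never zero.
#'
#' @param panels list of `shap_panel`s (typically correct positives per
#'   horizon).
#' @return A `shap_behavior_matrix`: list with `scaled` (features x
#'   horizons), `mean` (unscaled), `scale_factor`, `n`, `horizons`,
#'   `features`.
#' @export
behavior_matrix <- function(panels) {
  stopifnot(length(panels) > 0, all(vapply(panels, inherits, logical(1),
                                           "shap_panel")))
  horizons <- vapply(panels, `[[`, integer(1), "horizon")
  ord <- order(horizons)
  panels <- panels[ord]; horizons <- horizons[ord]
  features <- colnames(panels[[1]]$phi)
  scaled <- means <- matrix(NA_real_, length(features), length(horizons),
                            dimnames = list(features, as.character(horizons)))
  sf <- rep(NA_real_, length(horizons))
  nn <- integer(length(horizons))
  for (i in seq_along(panels)) {
    if (!identical(colnames(panels[[i]]$phi), features))
      stop("panels disagree on the feature set")
    nn[i] <- nrow(panels[[i]]$phi)
    if (nn[i] == 0) next
    s <- scaled_mean_shap(panels[[i]])
    scaled[, i] <- s$scaled
    means[, i] <- s$mean
    sf[i] <- s$scale_factor
  }
  structure(list(scaled = scaled, mean = means, scale_factor = sf, n = nn,
                 horizons = horizons, features = features),
            class = "shap_behavior_matrix")
}

#' @export
print.shap_behavior_matrix <- function(x, ...) {
  cat(sprintf("<shap_behavior_matrix> %d features x %d horizons\n",
              length(x$features), length(x$horizons)))
  invisible(x)
}

#' Feature ranking and attribution-share series
#'
#' Ranks features at one horizon by absolute scaled mean attribution
#' (ties broken lexicographically), and computes each focus feature's
#' share of total absolute mean attribution -- as a percentage of the sum
#' over all features, with non-focus features lumped as `"others"` -- at
#' every available horizon.
#'
#' @param bm a `shap_behavior_matrix`.
#' @param horizon horizon at which to rank.
#' @param k how many top features to list (default 10; truncated with a
#'   warning if larger than the feature count).
#' @param focus features for the share series (default: the top-k at
#'   `horizon`).
#' @return list with `top` (data.frame `rank`, `feature`, `scaled_mean`)
#'   and `proportions` (data.frame `feature` x horizon shares in percent,
#'   summing to 100 per horizon).
#' @export
rank_and_proportions <- function(bm, horizon, k = 10, focus = NULL) {
  stopifnot(inherits(bm, "shap_behavior_matrix"))
  ci <- match(horizon, bm$horizons)
  if (is.na(ci) || bm$n[ci] == 0) stop("horizon ", horizon, " unavailable")
  if (k > length(bm$features)) {
    warning("k exceeds the number of features; truncated")
    k <- length(bm$features)
  }
  s <- bm$scaled[, ci]
  ord <- order(-abs(s), names(s))
  top <- data.frame(rank = seq_len(k), feature = names(s)[ord][seq_len(k)],
                    scaled_mean = unname(s[ord][seq_len(k)]),
                    stringsAsFactors = FALSE)
  if (is.null(focus)) focus <- top$feature
  avail <- which(bm$n > 0)
  prop <- vapply(avail, function(j) {
    am <- abs(bm$mean[, j])
    tot <- sum(am)
    c(am[focus], others = sum(am[setdiff(bm$features, focus)])) / tot * 100
  }, numeric(length(focus) + 1))
  prop <- as.data.frame(prop)
  names(prop) <- as.character(bm$horizons[avail])
  prop <- cbind(data.frame(feature = c(focus, "others"),
                           stringsAsFactors = FALSE), prop)
  rownames(prop) <- NULL
  list(top = top, proportions = prop)
}

#' Serialize a behavior matrix to CSV
#'
#' Rows are features; columns are horizons; two trailing rows carry the
#' per-horizon scale factor and retained sample count.
#'
#' @param bm a `shap_behavior_matrix`.
#' @param path output CSV path.
#' @export
write_behavior_matrix <- function(bm, path) {
  m <- rbind(bm$scaled,
             `.scale_factor` = bm$scale_factor,
             `.n_rows` = bm$n)
  df <- data.frame(feature = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
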