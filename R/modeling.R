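# Parse an xgboost booster's JSON dump into flat per-tree arrays for the
# double-precision C++ traversals (margin + Shapley attributions). Covers
# (hessian sums) are the node weights the attribution recursion uses.
parse_booster_trees <- function(booster, features) {
  dump <- xgboost::xgb.dump(booster, dump_format = "json", with_stats = TRUE)
  trees <- jsonlite::fromJSON(paste(dump, collapse = "\n"),
                              simplifyVector = FALSE)
  lapply(trees, function(tree) {
    nodes <- list()
    collect <- function(nd) {
      nodes[[length(nodes) + 1L]] <<- nd
      if (!is.null(nd$children)) for (ch in nd$children) collect(ch)
    }
    collect(tree)
    ids <- vapply(nodes, function(nd) as.integer(nd$nodeid), integer(1))
    pos <- function(id) match(id, ids) - 1L  # 0-based
    k <- length(nodes)
    out <- list(feature = integer(k), split = numeric(k), yes = integer(k),
                no = integer(k), missing = integer(k), value = numeric(k),
                cover = numeric(k))
    for (i in seq_len(k)) {
      nd <- nodes[[i]]
      out$cover[i] <- as.numeric(nd$cover)
      if (is.null(nd$leaf)) {
        f <- nd$split
        fi <- match(f, features)
        if (is.na(fi)) fi <- as.integer(sub("^f", "", f)) + 1L
        out$feature[i] <- fi - 1L
        out$split[i] <- as.numeric(nd$split_condition)
        out$yes[i] <- pos(as.integer(nd$yes))
        out$no[i] <- pos(as.integer(nd$no))
        out$missing[i] <- pos(as.integer(nd$missing))
      } else {
        out$feature[i] <- -1L
        out$yes[i] <- out$no[i] <- out$missing[i] <- -1L
        out$value[i] <- as.numeric(nd$leaf)
      }
    }
    out
  })
}

default_tree_params <- function() {
  list(objective = "binary:logistic", max_depth = 3, eta = 0.1,
       min_child_weight = 4, subsample = 1, colsample_bytree = 1,
       lambda = 1, alpha = 0, nthread = 1)
}

fit_booster <- function(X, y, params, nrounds, seed) {
  dm <- xgboost::xgb.DMatrix(X, label = y)
  params$seed <- seed
  xgboost::xgb.train(params = params, data = dm, nrounds = nrounds, verbose = 0)
}

#' Train the boosted-tree mortality classifier for one horizon
#'
#' Fits a gradient-boosted decision-tree ensemble on the horizon dataset.
#' Missing values are routed natively by the trees (no imputation). The
#' returned model carries a double-precision parsed copy of the ensemble
#' so that margins and exact per-feature Shapley attributions satisfy the
#' additivity contract to machine precision.
#'
#' With `search_budget > 0`, hyperparameters are chosen by random search:
#' each candidate is fit on the training patients and scored by AUROC on
#' the validation patients of the split (the 4:1 inner split); the best
#' candidate is refit. Test patients are never touched by selection.
#'
#' @param dataset a `horizon_dataset`.
#' @param split optional [grouped_split()] plan; when given, the model is
#'   fit on train (+ validation, see `refit_with_validation`) patients only.
#' @param params named list overriding the documented default
#'   hyperparameters (`max_depth = 3`, `eta = 0.1`, `min_child_weight = 4`).
#' @param nrounds boosting rounds (default 100).
#' @param search_budget number of random-search candidates (0 = use
#'   defaults, no search).
#' @param refit_with_validation refit the final model on train + validation
#'   patients (default TRUE).
#' @param seed RNG seed.
#' @return A `horizon_model`.
#' @export
train_horizon_model <- function(dataset, split = NULL, params = list(),
                                nrounds = 100, search_budget = 0,
                                refit_with_validation = TRUE, seed = 0) {
  stopifnot(inherits(dataset, "horizon_dataset"))
  if (isTRUE(dataset$empty) || !length(dataset$y)) stop("empty horizon dataset")
  base_params <- modifyList(default_tree_params(), params)

  fit_idx <- seq_along(dataset$y)
  if (!is.null(split)) {
    fit_idx <- split_rows(dataset, split,
                          if (refit_with_validation) c("train", "validation")
                          else "train")
  }
  y_fit <- dataset$y[fit_idx]
  if (length(unique(y_fit)) < 2) stop("training data contain a single class")

  chosen <- base_params
  search_log <- NULL
  if (search_budget > 0) {
    if (is.null(split)) stop("hyperparameter search requires a split plan")
    tr <- split_rows(dataset, split, "train")
    va <- split_rows(dataset, split, "validation")
    set.seed(derive_seed(seed, "hp_search"))
    cand <- lapply(seq_len(search_budget), function(i) {
      list(eta = exp(runif(1, log(0.03), log(0.3))),
           max_depth = sample(2:6, 1),
           min_child_weight = sample(c(1, 2, 4, 8, 16), 1),
           lambda = exp(runif(1, log(0.1), log(10))),
           alpha = sample(c(0, 0.1, 1), 1))
    })
    scores <- vapply(seq_along(cand), function(i) {
      p <- modifyList(base_params, cand[[i]])
      bst <- fit_booster(dataset$X[tr, , drop = FALSE], dataset$y[tr], p,
                         nrounds, derive_seed(seed, paste0("cand", i)))
      pr <- predict(bst, xgboost::xgb.DMatrix(dataset$X[va, , drop = FALSE]))
      auroc(dataset$y[va], pr)
    }, numeric(1))
    chosen <- modifyList(base_params, cand[[which.max(scores)]])
    search_log <- data.frame(candidate = seq_along(scores),
                             validation_auroc = scores)
  }

  bst <- fit_booster(dataset$X[fit_idx, , drop = FALSE], y_fit, chosen,
                     nrounds, derive_seed(seed, "final_fit"))
  trees <- parse_booster_trees(bst, dataset$features)
  # the learner's global intercept (margin-space base score), recovered as
  # the constant offset between its margin output and the summed leaves
  samp <- fit_idx[seq_len(min(64L, length(fit_idx)))]
  Xs <- dataset$X[samp, , drop = FALSE]
  xgb_margin <- predict(bst, xgboost::xgb.DMatrix(Xs), outputmargin = TRUE)
  intercept <- median(xgb_margin - .tree_margin_cpp(trees, Xs))

  structure(list(booster = bst, trees = trees, intercept = intercept,
                 features = dataset$features, horizon = dataset$horizon,
                 params = chosen, nrounds = nrounds, seed = seed,
                 split = split, search_log = search_log,
                 n_fit = length(fit_idx)),
            class = "horizon_model")
}

#' Predict from a horizon model
#'
#' Margins are computed by the package's double-precision traversal of the
#' parsed ensemble (plus the learner intercept); probabilities are the
#' logistic transform of the margin.
#'
#' @param object a `horizon_model`.
#' @param newdata feature matrix (columns in the model's feature order;
#'   `NA` = missing).
#' @param type `"prob"` (default) or `"margin"`.
#' @param ... unused.
#' @export
predict.horizon_model <- function(object, newdata, type = c("prob", "margin"),
                                  ...) {
  type <- match.arg(type)
  if (is.null(colnames(newdata)) ||
      !identical(colnames(newdata), object$features)) {
    if (!is.null(colnames(newdata)) &&
        setequal(colnames(newdata), object$features)) {
      newdata <- newdata[, object$features, drop = FALSE]
    } else if (ncol(newdata) != length(object$features)) {
      stop("feature set of `newdata` does not match the model")
    }
  }
  m <- .tree_margin_cpp(object$trees, newdata) + object$intercept
  if (type == "margin") m else plogis(m)
}

#' @export
print.horizon_model <- function(x, ...) {
  cat(sprintf("<horizon_model> horizon = %d days, %d trees, %d features, fit on %d rows\n",
              x$horizon, length(x$trees), length(x$features), x$n_fit))
  invisible(x)
}

#' Patient-level k-fold cross-validated AUROC
#'
#' Folds partition patients, not rows, so the two rows of a patient are
#' always held out together. Each fold's model is fit with the supplied
#' (or default) hyperparameters and scored on its held-out rows; a fold
#' whose held-out rows contain a single class is skipped with a warning.
#'
#' @param dataset a `horizon_dataset`.
#' @param folds number of folds (default 5).
#' @param seed RNG seed for the patient shuffle.
#' @param params,nrounds passed to the fold models.
#' @return list with `mean`, `sd`, `fold_auroc`, `n_patients`.
#' @export
cv_auroc <- function(dataset, folds = 5, seed = 0, params = list(),
                     nrounds = 100) {
  stopifnot(inherits(dataset, "horizon_dataset"))
  ids <- unique(dataset$patient_id)
  if (length(ids) < folds) stop("fewer patients than folds")
  p <- modifyList(default_tree_params(), params)
  set.seed(derive_seed(seed, "cv_folds"))
  fold_of <- setNames(sample(rep(seq_len(folds), length.out = length(ids))),
                      sample(ids))
  fold_id <- fold_of[dataset$patient_id]
  out <- rep(NA_real_, folds)
  for (k in seq_len(folds)) {
    te <- which(fold_id == k)
    tr <- which(fold_id != k)
    if (length(unique(dataset$y[te])) < 2 ||
        length(unique(dataset$y[tr])) < 2) {
      warning("fold ", k, " has a single class; skipped")
      next
    }
    bst <- fit_booster(dataset$X[tr, , drop = FALSE], dataset$y[tr], p,
                       nrounds, derive_seed(seed, paste0("cvfold", k)))
    pr <- predict(bst, xgboost::xgb.DMatrix(dataset$X[te, , drop = FALSE]))
    out[k] <- auroc(dataset$y[te], pr)
  }
  list(mean = mean(out, na.rm = TRUE), sd = sd(out[!is.na(out)]),
       fold_auroc = out, fold_assignment = fold_of, n_patients = length(ids))
}

#' Train one model per prediction horizon
#'
#' Builds the horizon dataset, the patient-level split and the fitted model
#' for every requested horizon, and records per-horizon sizes and
#' cross-validated AUROC. Sparse horizon grids (e.g. every 15 days) are
#' supported for fast runs. Horizons with an empty dataset are skipped and
#' reported in the metrics table.
#'
#' @param set a `patient_matrix_set`.
#' @param horizons integer vector of horizons (subset of
#'   `[1, negative_day)`).
#' @param negative_day negative reference day (default 168).
#' @param min_observed inclusion rule passed to [build_horizon_dataset()].
#' @param params,nrounds,search_budget model options (see
#'   [train_horizon_model()]).
#' @param folds cross-validation folds (0 disables CV metrics).
#' @param test_fraction,validation_fraction_of_train split fractions.
#' @param seed master seed; all per-horizon seeds derive from it.
#' @return A `model_family`: list with `models` (by horizon), `datasets`,
#'   `splits`, and a `metrics` data.frame (`horizon`, `n_patients`,
#'   `mean_auroc`, `sd_auroc`).
#' @export
train_model_family <- function(set, horizons = seq(1, 90), negative_day = 168,
                               min_observed = 1, params = list(),
                               nrounds = 100, search_budget = 0, folds = 5,
                               test_fraction = 0.2,
                               validation_fraction_of_train = 0.2, seed = 0) {
  stopifnot(all(horizons >= 1), all(horizons < negative_day),
            !anyDuplicated(horizons))
  models <- list(); datasets <- list(); splits <- list()
  rows <- list()
  for (n in horizons) {
    ds <- build_horizon_dataset(set, n, negative_day, min_observed)
    if (isTRUE(ds$empty)) {
      message("horizon ", n, ": empty dataset, skipped")
      rows[[as.character(n)]] <- data.frame(horizon = n, n_patients = 0,
                                            n_rows = 0, mean_auroc = NA,
                                            sd_auroc = NA)
      next
    }
    sp <- grouped_split(ds, test_fraction, validation_fraction_of_train,
                        seed = derive_seed(seed, paste0("split", n)))
    md <- train_horizon_model(ds, sp, params = params, nrounds = nrounds,
                              search_budget = search_budget,
                              seed = derive_seed(seed, paste0("model", n)))
    cv <- if (folds > 0)
      cv_auroc(ds, folds, seed = derive_seed(seed, paste0("cv", n)),
               params = params, nrounds = nrounds)
    else list(mean = NA_real_, sd = NA_real_)
    key <- as.character(n)
    models[[key]] <- md; datasets[[key]] <- ds; splits[[key]] <- sp
    rows[[key]] <- data.frame(horizon = n,
                              n_patients = length(unique(ds$patient_id)),
                              n_rows = length(ds$y),
                              mean_auroc = cv$mean, sd_auroc = cv$sd)
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  structure(list(models = models, datasets = datasets, splits = splits,
                 metrics = metrics, horizons = horizons,
                 negative_day = negative_day, seed = seed),
            class = "model_family")
}

#' @export
print.model_family <- function(x, ...) {
  cat(sprintf("<model_family> %d fitted horizons (negative day %d)\n",
              length(x$models), x$negative_day))
  print(x$metrics)
  invisible(x)
}
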