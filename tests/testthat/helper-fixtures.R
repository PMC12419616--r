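# Shared fixtures, all built in code at test time.

# Small long-format event table for one patient.
one_patient_events <- function(days, values, parameter = "alb",
                               patient_id = "P1") {
  data.frame(patient_id = patient_id, days_before_death = days,
             parameter = parameter, value = values,
             stringsAsFactors = FALSE)
}

# Brute-force windowed-mean resampler: the independent oracle for the
# moving-average grid. Explicit loop over window membership.
oracle_resample <- function(days, values, window_days, max_day,
                            align = "centered") {
  h <- window_days %/% 2
  out <- rep(NA_real_, max_day + 1)
  for (t in 0:max_day) {
    if (align == "centered") {
      lo <- t - h; hi <- t + h
    } else {
      lo <- t; hi <- t + window_days - 1
    }
    inw <- days >= lo & days <= hi
    if (any(inw)) out[t + 1] <- mean(values[inw])
  }
  out
}

# Brute-force Shapley values for a single parsed tree (the package's flat
# array format), enumerating all feature coalitions. The value function
# v(S) follows the tree: features in S follow the input, features outside
# S are marginalized over the tree's cover weights.
oracle_tree_shap <- function(tree, x, n_features) {
  descend <- function(node, inS) {
    if (tree$feature[node + 1] < 0) return(tree$value[node + 1])
    f <- tree$feature[node + 1]  # 0-based feature index
    if (inS[f + 1]) {
      xf <- x[f + 1]
      child <- if (is.na(xf)) tree$missing[node + 1]
      else if (xf < tree$split[node + 1]) tree$yes[node + 1]
      else tree$no[node + 1]
      descend(child, inS)
    } else {
      # weights are child cover over *parent* cover, the convention the
      # recorded hessian statistics use
      cy <- tree$cover[tree$yes[node + 1] + 1]
      cn <- tree$cover[tree$no[node + 1] + 1]
      (cy * descend(tree$yes[node + 1], inS) +
         cn * descend(tree$no[node + 1], inS)) / tree$cover[node + 1]
    }
  }
  v <- function(S) {
    inS <- rep(FALSE, n_features)
    inS[S] <- TRUE
    descend(0L, inS)
  }
  M <- n_features
  phi <- numeric(M)
  others <- function(j) setdiff(seq_len(M), j)
  for (j in seq_len(M)) {
    rest <- others(j)
    for (k in 0:length(rest)) {
      combs <- if (k == 0) list(integer(0)) else
        utils::combn(rest, k, simplify = FALSE)
      w <- factorial(k) * factorial(M - k - 1) / factorial(M)
      for (S in combs) phi[j] <- phi[j] + w * (v(c(S, j)) - v(S))
    }
  }
  list(phi = phi, base = v(integer(0)))
}

# A tiny fitted horizon model on synthetic separable data.
fit_toy_model <- function(n = 300, p = 5, seed = 7, nrounds = 40,
                          informative = 2) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("f", seq_len(p))
  y <- as.integer(rowSums(X[, seq_len(informative), drop = FALSE]) +
                    rnorm(n, sd = 0.5) > 0)
  ds <- structure(list(horizon = 1L, X = X, y = y,
                       patient_id = sprintf("P%03d", seq_len(n)),
                       role = rep("positive", n), features = colnames(X),
                       negative_day = 168L, empty = FALSE),
                  class = "horizon_dataset")
  list(dataset = ds,
       model = shapdyn::train_horizon_model(ds, nrounds = nrounds, seed = seed))
}

# Hand-assembled shap_panel.
make_panel <- function(phi, label, prob, horizon = 1L, base = 0) {
  margin <- base + rowSums(phi)
  structure(list(horizon = as.integer(horizon),
                 patient_id = sprintf("P%03d", seq_len(nrow(phi))),
                 label = label, phi = phi, base = base, margin = margin,
                 prob = prob),
            class = "shap_panel")
}

# A small drift cohort shared by the cheaper integration tests (memoized).
.fixture_env <- new.env(parent = emptyenv())
small_cohort_state <- function() {
  if (!is.null(.fixture_env$state)) return(.fixture_env$state)
  spec <- cohort_spec(n_patients = 150, seed = 11)
  coh <- generate_cohort(spec, missing_rates = terminal_drift_missing_rates())
  set <- resample_cohort(coh$events, window_days = 5, max_day = 168)
  .fixture_env$state <- list(spec = spec, cohort = coh, set = set)
  .fixture_env$state
}
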