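test_that("attributions are additive to machine precision", {
  toy <- fit_toy_model(n = 250, p = 5, seed = 17)
  X <- toy$dataset$X
  X[sample(length(X), 100)] <- NA
  sv <- shap_values(toy$model, X)
  expect_lt(max(abs(sv$base + rowSums(sv$phi) - sv$margin)), 1e-9)
  # margins agree with the learner's own output at float32 resolution
  xm <- predict(toy$model$booster, xgboost::xgb.DMatrix(X),
                outputmargin = TRUE)
  expect_lt(max(abs(sv$margin - xm)), 1e-4)
})

test_that("attributions match the learner's own TreeSHAP and a brute-force oracle", {
  # depth-2 trees on 3 binary features, all 8 inputs enumerated
  set.seed(5)
  G <- as.matrix(expand.grid(f1 = 0:1, f2 = 0:1, f3 = 0:1))
  X <- G[rep(1:8, times = c(40, 10, 25, 15, 20, 30, 10, 50)), ]
  y <- as.integer(X[, 1] & X[, 2])  # outcome ignores f3
  dm <- xgboost::xgb.DMatrix(X, label = y)
  bst <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 2, eta = 1,
                  lambda = 0, min_child_weight = 0, nthread = 1),
    data = dm, nrounds = 1, verbose = 0)
  trees <- shapdyn:::parse_booster_trees(bst, colnames(X))
  expect_length(trees, 1)
  sv <- shapdyn:::.treeshap_cpp(trees, G * 1.0)
  for (i in 1:8) {
    oracle <- oracle_tree_shap(trees[[1]], G[i, ] * 1.0, 3)
    expect_equal(unname(sv$phi[i, ]), oracle$phi, tolerance = 1e-10)
    expect_equal(sv$base, oracle$base, tolerance = 1e-10)
  }
  # and the learner's built-in contributions agree
  ctr <- predict(bst, xgboost::xgb.DMatrix(G * 1.0), predcontrib = TRUE)
  expect_equal(unname(sv$phi), unname(ctr[, 1:3]), tolerance = 1e-5)
})

test_that("a model that never splits a feature attributes nothing to it", {
  toy <- fit_toy_model(n = 300, p = 5, seed = 23, informative = 1,
                       nrounds = 3)
  used <- unique(unlist(lapply(toy$model$trees, function(t)
    t$feature[t$feature >= 0]))) + 1
  unused <- setdiff(1:5, used)
  expect_gt(length(unused), 0)
  sv <- shap_values(toy$model, toy$dataset$X)
  expect_true(all(sv$phi[, unused] == 0))
})

test_that("correct-positive selection matches hand counts", {
  phi <- matrix(0, 6, 2, dimnames = list(NULL, c("a", "b")))
  panel <- make_panel(phi, label = c(1, 1, 1, 0, 0, 1),
                      prob = c(0.9, 0.4, 0.5, 0.9, 0.2, 0.65))
  kept <- select_correct_positives(panel)
  # positives with prob >= 0.5: rows 1, 3, 6
  expect_equal(kept$patient_id, sprintf("P%03d", c(1, 3, 6)))
  expect_equal(attr(kept, "n_dropped"), 3)
  # an unreachable threshold empties the panel but does not error
  none <- select_correct_positives(panel, threshold = 1.0)
  expect_equal(nrow(none$phi), 0)
})

test_that("scaled means follow the max-scaling arithmetic", {
  phi <- rbind(c(2.5, 1.5, -0.5), c(1.5, 0.5, -0.5))
  colnames(phi) <- c("x", "y", "z")
  panel <- make_panel(phi, label = c(1, 1), prob = c(0.9, 0.9))
  s <- scaled_mean_shap(panel)
  expect_equal(unname(s$mean), c(2, 1, -0.5))
  expect_equal(unname(s$scaled), c(1, 0.5, -0.25))
  expect_equal(s$scale_factor, 2)
  # scaling is idempotent
  panel2 <- make_panel(rbind(s$scaled), label = 1, prob = 0.9)
  expect_equal(scaled_mean_shap(panel2)$scaled, s$scaled)
  # permutation equivariance
  perm <- c("z", "x", "y")
  panel3 <- make_panel(phi[, perm], label = c(1, 1), prob = c(0.9, 0.9))
  expect_equal(scaled_mean_shap(panel3)$scaled, s$scaled[perm])
  # single feature self-scales to +/-1
  p1 <- make_panel(matrix(-0.3, 2, 1, dimnames = list(NULL, "w")),
                   label = c(1, 1), prob = c(0.9, 0.9))
  expect_equal(unname(scaled_mean_shap(p1)$scaled), -1)
  # degenerate all-zero attributions are an error, not a zero row
  p0 <- make_panel(matrix(0, 2, 2, dimnames = list(NULL, c("a", "b"))),
                   label = c(1, 1), prob = c(0.9, 0.9))
  expect_error(scaled_mean_shap(p0), "scale undefined")
})

test_that("behavior matrices normalize per horizon and flag empty ones", {
  mk <- function(h, m) make_panel(matrix(rep(m, each = 4), 4,
                                         dimnames = list(NULL, c("a", "b"))),
                                  label = rep(1, 4), prob = rep(0.9, 4),
                                  horizon = h)
  empty <- select_correct_positives(mk(30, c(1, 2)), threshold = 1.0)
  bm <- behavior_matrix(list(mk(1, c(2, 1)), mk(15, c(-1, 3)), empty))
  expect_equal(bm$horizons, c(1, 15, 30))
  avail <- bm$n > 0
  expect_equal(unname(apply(abs(bm$scaled[, avail]), 2, max)), c(1, 1))
  expect_true(all(is.na(bm$scaled[, !avail])))
  expect_true(all(abs(bm$scaled) <= 1, na.rm = TRUE))
})

test_that("rankings break ties lexicographically and shares sum to 100", {
  mk <- function(h, m) make_panel(matrix(rep(m, each = 3), 3,
                                         dimnames = list(NULL, c("c", "a", "b"))),
                                  label = rep(1, 3), prob = rep(0.9, 3),
                                  horizon = h)
  bm <- behavior_matrix(list(mk(1, c(1, -1, 0.5)), mk(10, c(2, 1, 1))))
  rk <- rank_and_proportions(bm, 1, k = 3)
  # |c| == |a|: alphabetical order decides
  expect_equal(rk$top$feature, c("a", "c", "b"))
  sums <- colSums(rk$proportions[, -1, drop = FALSE])
  expect_equal(unname(sums), rep(100, 2), tolerance = 1e-9)
  expect_warning(rank_and_proportions(bm, 1, k = 10), "truncated")
  expect_error(rank_and_proportions(bm, 99), "unavailable")
})

test_that("attribution panels restrict to held-out rows by default", {
  st <- small_cohort_state()
  ds <- build_horizon_dataset(st$set, 15)
  plan <- grouped_split(ds, seed = 2)
  md <- train_horizon_model(ds, plan, nrounds = 40, seed = 2)
  panel <- attribute_panel(md, ds, plan)
  test_ids <- plan$patient_id[plan$assignment == "test"]
  expect_setequal(unique(panel$patient_id), intersect(test_ids, ds$patient_id))
  expect_lt(max(abs(panel$base + rowSums(panel$phi) - panel$margin)), 1e-9)
  expect_error(attribute_panel(md, ds), "split")
})
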