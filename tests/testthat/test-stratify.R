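test_that("well-separated blobs are recovered exactly with k = 2", {
  set.seed(6)
  X <- rbind(matrix(rnorm(40 * 3, mean = 0), 40, 3),
             matrix(rnorm(40 * 3, mean = 8), 40, 3))
  rownames(X) <- sprintf("P%03d", 1:80)
  truth <- rep(1:2, each = 40)
  res <- cluster_and_select_k(X, k_range = 2:6)
  expect_equal(res$k, 2)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(res$labels, truth), 1.0)
})

test_that("clustering is stable under duplication of every patient", {
  set.seed(8)
  X <- rbind(matrix(rnorm(30 * 2), 30, 2),
             matrix(rnorm(30 * 2, mean = 6), 30, 2))
  rownames(X) <- sprintf("P%03d", 1:60)
  X2 <- rbind(X, X)
  rownames(X2) <- c(rownames(X), sprintf("Q%03d", 1:60))
  r1 <- cluster_and_select_k(X, k_range = 2:5)
  r2 <- cluster_and_select_k(X2, k_range = 2:5)
  expect_equal(r2$k, r1$k)
  # duplicates co-cluster with their originals
  map <- table(r1$labels, r2$labels[1:60])
  expect_true(all(rowSums(map > 0) == 1))
  expect_equal(unname(r2$labels[1:60]), unname(r2$labels[61:120]))
})

test_that("Ward merge heights never decrease", {
  st <- small_cohort_state()
  X <- extract_day_matrix(st$set, 1)
  X <- X[complete.cases(X), ]
  res <- cluster_and_select_k(X, k_range = 2:5, standardize = TRUE)
  expect_true(all(diff(res$tree$height) >= -1e-12))
  expect_true(all(res$selection$wss > 0))
  # a fixed k overrides silhouette selection
  res4 <- cluster_and_select_k(X, k_range = 2:5, k = 4, standardize = TRUE)
  expect_equal(res4$k, 4)
  expect_equal(length(unique(res4$labels)), 4)
})

test_that("clustering input is validated", {
  X <- matrix(c(1, NA, 2, 3), 2, 2, dimnames = list(c("a", "b"), NULL))
  expect_error(cluster_and_select_k(X), "missing")
  Y <- matrix(rnorm(6), 3, 2, dimnames = list(c("a", "a", "b"), NULL))
  expect_error(cluster_and_select_k(Y, k_range = 1), "one row per patient")
})

test_that("subtype summaries report exact order statistics", {
  labels <- setNames(rep(1:2, each = 5), sprintf("P%03d", 1:10))
  labs <- data.frame(patient_id = sprintf("P%03d", 1:10),
                     alb = c(1, 2, 3, 4, 5, 11, 12, 13, 14, 15))
  s <- subtype_summary_and_tests(labels, labs, alpha = 0.01)
  row1 <- s$lab_summary[s$lab_summary$subtype == 1, ]
  expect_equal(row1$median, 3)
  expect_equal(row1$q25, 2)
  expect_equal(row1$q75, 4)
  expect_true(all(s$lab_summary$q25 <= s$lab_summary$median &
                    s$lab_summary$median <= s$lab_summary$q75))
})

test_that("identical distributions yield no corrected rejections", {
  set.seed(12)
  labels <- setNames(sample(rep(1:3, each = 40)), sprintf("P%03d", 1:120))
  labs <- data.frame(patient_id = sprintf("P%03d", 1:120),
                     a = rnorm(120), b = rnorm(120), c = rexp(120))
  attrs <- data.frame(patient_id = sprintf("P%03d", 1:120),
                      sex = sample(c("f", "m"), 120, TRUE))
  s <- subtype_summary_and_tests(labels, labs, attrs, alpha = 0.01)
  expect_false(any(s$tests$significant))
  expect_null(s$pairwise)
})

test_that("a planted location shift is detected and localized", {
  set.seed(13)
  labels <- setNames(rep(1:3, each = 100), sprintf("P%03d", 1:300))
  alb <- rnorm(300)
  alb[labels == 2] <- alb[labels == 2] - 1.0  # subtype 2 shifted down
  labs <- data.frame(patient_id = names(labels), alb = alb, noise = rnorm(300))
  s <- subtype_summary_and_tests(labels, labs, alpha = 0.01)
  expect_true(s$tests$significant[s$tests$variable == "alb"])
  expect_false(s$tests$significant[s$tests$variable == "noise"])
  pw <- s$pairwise
  involves2 <- pw$group1 == "2" | pw$group2 == "2"
  expect_true(all(pw$significant[involves2]))
  expect_false(any(pw$significant[!involves2]))
})

test_that("tiny subtypes are excluded from testing and flagged", {
  labels <- setNames(c(rep(1, 20), rep(2, 20), rep(3, 2)),
                     sprintf("P%03d", 1:42))
  set.seed(2)
  labs <- data.frame(patient_id = names(labels), a = rnorm(42))
  s <- subtype_summary_and_tests(labels, labs)
  expect_equal(s$skipped, "3")
  expect_false(is.null(s$tests))
})

test_that("per-subtype behaviors recombine to the global means", {
  st <- small_cohort_state()
  hz <- c(1, 30)
  fam <- train_model_family(st$set, horizons = hz, folds = 0, nrounds = 40,
                            seed = 9)
  panels <- lapply(names(fam$models), function(h)
    attribute_panel(fam$models[[h]], fam$datasets[[h]], use = "all"))
  cp <- lapply(panels, select_correct_positives)
  global <- behavior_matrix(cp)
  ids <- unique(unlist(lapply(cp, `[[`, "patient_id")))
  labels <- setNames(rep_len(1:2, length(ids)), ids)
  per <- subtype_behaviors(labels, cp)
  # patient-weighted average of per-subtype unscaled means recovers the
  # global unscaled means (linearity of the mean)
  for (ci in seq_along(hz)) {
    w <- vapply(per, function(b) b$n[ci], numeric(1))
    if (any(w == 0)) next
    rec <- Reduce(`+`, Map(function(b, wt) b$mean[, ci] * wt, per, w)) / sum(w)
    expect_equal(rec, global$mean[, ci], tolerance = 1e-9)
  }
  # a single-subtype partition reproduces the global matrix exactly
  solo <- subtype_behaviors(setNames(rep(1, length(ids)), ids), cp)[["1"]]
  expect_equal(solo$scaled, global$scaled)
  expect_equal(solo$n, global$n)
})

test_that("family-wise error stays controlled under the global null", {
  # scaled-down replication loop; the full 1000-replicate calibration runs
  # in the acceptance suite
  set.seed(40)
  rejections <- 0
  for (r in 1:150) {
    labels <- setNames(rep(1:3, each = 25), sprintf("P%03d", 1:75))
    labs <- data.frame(patient_id = names(labels),
                       a = rnorm(75), b = rnorm(75))
    s <- subtype_summary_and_tests(labels, labs, alpha = 0.01)
    if (any(s$tests$significant)) rejections <- rejections + 1
  }
  expect_lte(rejections / 150, 0.03)
})
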