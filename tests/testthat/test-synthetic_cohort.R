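test_that("latent mean follows the linear terminal-drift ramp", {
  tab <- data.frame(subtype = 1, feature = c("flat", "drop"),
                    baseline = c(5, 4), shift = c(0, -2), onset = c(0, 60),
                    noise_sd = 0.1, patient_sd = 0.1)
  p <- trajectory_params(tab)
  # nuisance feature is flat everywhere
  expect_equal(latent_mean(p, 1, "flat", c(0, 10, 300)), rep(5, 3))
  # full shift exactly at death
  expect_equal(latent_mean(p, 1, "drop", 0), 2.0)
  # halfway up the ramp: 30/60 of the shift remains
  expect_equal(latent_mean(p, 1, "drop", 30), 3.0)
  # flat at and beyond onset
  expect_equal(latent_mean(p, 1, "drop", c(60, 90)), c(4, 4))
  expect_error(latent_mean(p, 1, "drop", -1), "non-negative")
})

test_that("visit schedules hit the target median gap and stay in range", {
  spec <- cohort_spec(n_patients = 1000, seed = 5)
  set.seed(spec$seed)
  visits <- sample_visit_days(spec)
  gaps <- unlist(lapply(visits, function(d) abs(diff(d))))
  expect_gte(median(gaps), 4)
  expect_lte(median(gaps), 6)
  expect_true(all(unlist(visits) >= 0 & unlist(visits) <= 365))
  expect_true(all(vapply(visits, function(d) all(diff(d) < 0), logical(1))))

  spec10 <- cohort_spec(n_patients = 50, observation_window = 10, seed = 5)
  set.seed(5)
  v10 <- sample_visit_days(spec10)
  expect_true(all(unlist(v10) >= 0 & unlist(v10) <= 10))
})

test_that("cohort generation is reproducible and respects its contract", {
  spec <- cohort_spec(n_patients = 40, seed = 99, missing_rate = 0)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$events, b$events)
  expect_identical(a$truth, b$truth)
  expect_equal(length(unique(a$events$patient_id)), 40)
  expect_true(all(a$events$days_before_death >= 0 &
                    a$events$days_before_death <= 365))
  expect_false(anyNA(a$events$value))
  # every patient has exactly one subtype label
  expect_setequal(a$truth$patient_id, unique(a$events$patient_id))
  expect_true(all(a$truth$subtype %in% 1:3))
  # events = visits x features when nothing is dropped
  nv <- vapply(split(a$events$days_before_death, a$events$patient_id),
               function(d) length(unique(d)), integer(1))
  expect_equal(nrow(a$events), sum(nv) * length(unique(a$events$parameter)))
})

test_that("subtype counts match their multinomial expectation", {
  tab <- data.frame(subtype = rep(1:3, each = 1), feature = "x",
                    baseline = 0, shift = 0, onset = 0,
                    noise_sd = 1, patient_sd = 1)
  spec <- cohort_spec(n_patients = 10000, n_subtypes = 3,
                      mixing_proportions = c(0.2, 0.1, 0.7),
                      observation_window = 12, seed = 21)
  coh <- generate_cohort(spec, params = trajectory_params(tab))
  counts <- table(factor(coh$truth$subtype, levels = 1:3))
  expected <- 10000 * c(0.2, 0.1, 0.7)
  sds <- sqrt(10000 * c(0.2, 0.1, 0.7) * (1 - c(0.2, 0.1, 0.7)))
  expect_true(all(abs(counts - expected) <= 3 * sds))
})

test_that("invalid cohort specifications are rejected", {
  expect_error(cohort_spec(n_patients = 0), "positive integer")
  expect_error(cohort_spec(n_subtypes = 2, mixing_proportions = c(0.5, 0.4)),
               "sum to 1")
  expect_error(cohort_spec(n_subtypes = 2, mixing_proportions = c(0.5)),
               "one entry per subtype")
  expect_error(cohort_spec(observation_window = -1), "positive")
  expect_error(cohort_spec(missing_rate = 1), "missing_rate")
  tab <- data.frame(subtype = 1, feature = "x", baseline = 0, shift = 0,
                    onset = -5, noise_sd = 1, patient_sd = 1)
  expect_error(trajectory_params(tab), "onset")
})

test_that("missing rate controls emitted events", {
  tab <- data.frame(subtype = 1, feature = c("a", "b"), baseline = 0,
                    shift = 0, onset = 0, noise_sd = 1, patient_sd = 1)
  spec <- cohort_spec(n_patients = 200, n_subtypes = 1,
                      mixing_proportions = 1, observation_window = 60,
                      missing_rate = c(a = 0, b = 0.4), seed = 3)
  coh <- generate_cohort(spec, params = trajectory_params(tab))
  nv <- sum(vapply(split(coh$events$days_before_death, coh$events$patient_id),
                   function(d) length(unique(d)), integer(1)))
  n_a <- sum(coh$events$parameter == "a")
  n_b <- sum(coh$events$parameter == "b")
  expect_gte(n_a, n_b)  # b is dropped at rate 0.4
  expect_equal(n_b / n_a, 0.6, tolerance = 0.1)
})

test_that("nuisance features show no temporal trend", {
  st <- small_cohort_state()
  ev <- st$cohort$events
  for (f in c("cl", "mcv", "amy")) {
    sub <- ev[ev$parameter == f, ]
    fit <- summary(lm(value ~ days_before_death, data = sub))$coefficients
    ci <- fit[2, 1] + c(-1, 1) * 1.96 * fit[2, 2]
    expect_true(ci[1] <= 0 && ci[2] >= 0)
  }
})

test_that("planted subtypes overlap in single-feature day-1 marginals", {
  st <- small_cohort_state()
  sep <- subtype_separation_auc(st$cohort, day = 1)
  # small-n fixture: allow the max-statistic a little extra room; the
  # full-size check lives in the acceptance suite
  expect_lt(max(sep$max_pairwise_auc), 0.80)
  expect_true(all(sep$max_pairwise_auc >= 0.5))
})
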