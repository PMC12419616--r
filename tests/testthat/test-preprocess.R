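test_that("same-day duplicates keep the earliest result", {
  ev <- data.frame(patient_id = "P1", days_before_death = c(3, 3, 2),
                   parameter = "alb", value = c(3.1, 2.9, 2.5),
                   timestamp = c("08:00", "14:00", "09:00"),
                   stringsAsFactors = FALSE)
  out <- dedup_first_per_day(ev)
  expect_equal(nrow(out), 2)
  expect_equal(out$value[out$days_before_death == 3], 3.1)
  # duplicates on different days are both retained
  expect_true(2 %in% out$days_before_death)
  # idempotent on clean tables
  expect_identical(dedup_first_per_day(out), out)
  # no timestamp: stable input order wins, with a warning
  ev2 <- ev[, setdiff(names(ev), "timestamp")]
  expect_warning(out2 <- dedup_first_per_day(ev2), "input order")
  expect_equal(out2$value[out2$days_before_death == 3], 3.1)
})

test_that("coverage filter applies a strict more-than-half rule", {
  pats <- sprintf("P%03d", 1:100)
  ev <- rbind(
    data.frame(patient_id = pats[1:51], days_before_death = 1,
               parameter = "kept", value = 1),
    data.frame(patient_id = pats[1:50], days_before_death = 1,
               parameter = "dropped", value = 1),
    data.frame(patient_id = pats, days_before_death = 2,
               parameter = "anchor", value = 1)
  )
  res <- coverage_filter(ev, 0.5)
  expect_setequal(res$parameters, c("anchor", "kept"))
  # patients lacking a retained parameter are reported for exclusion
  expect_setequal(res$excluded_patients, pats[52:100])
  # threshold 0 keeps everything
  expect_setequal(coverage_filter(ev, 0)$parameters,
                  c("anchor", "dropped", "kept"))
  expect_error(coverage_filter(ev[0, ]), "empty")
})

test_that("moving-average grid matches direct window means", {
  ev <- one_patient_events(c(10, 12), c(2, 4))
  m <- resample_moving_average(ev, window_days = 5, max_day = 15)
  expect_equal(unname(extract_day_vector(m, 11)["alb"]), 3.0)
  # only day 10 falls in day 8's window [6, 10]
  expect_equal(unname(extract_day_vector(m, 8)["alb"]), 2.0)
  # nothing within [t-2, t+2] of day 5 -> masked
  expect_true(is.na(extract_day_vector(m, 5)["alb"]))
  expect_error(extract_day_vector(m, 99), "outside")

  cst <- one_patient_events(seq(0, 20, by = 2), rep(7, 11))
  mc <- resample_moving_average(cst, window_days = 5, max_day = 20)
  expect_true(all(mc[, "alb"] == 7, na.rm = TRUE))
  expect_error(resample_moving_average(ev, window_days = 0), "window_days")
})

test_that("resampler equals the brute-force oracle on random series", {
  set.seed(42)
  for (rep in 1:60) {
    nd <- sample(1:12, 1)
    days <- sort(sample(0:30, nd))
    vals <- rnorm(nd)
    w <- sample(c(1, 3, 5, 7), 1)
    align <- sample(c("centered", "trailing"), 1)
    ev <- one_patient_events(days, vals)
    m <- resample_moving_average(ev, window_days = w, max_day = 25,
                                 align = align)
    expect_equal(unname(m[, "alb"]),
                 oracle_resample(days, vals, w, 25, align))
  }
})

test_that("smoothing is shift-equivariant", {
  set.seed(9)
  days <- sort(sample(0:40, 12))
  vals <- rnorm(12)
  m0 <- resample_moving_average(one_patient_events(days, vals),
                                window_days = 5, max_day = 60)
  m7 <- resample_moving_average(one_patient_events(days + 7, vals),
                                window_days = 5, max_day = 60)
  expect_equal(unname(m7[8:61, "alb"]), unname(m0[1:54, "alb"]))
})

test_that("cohort resampling slices agree with per-patient resampling", {
  st <- small_cohort_state()
  set <- st$set
  pid <- set$patient_ids[7]
  ev <- st$cohort$events[st$cohort$events$patient_id == pid, ]
  single <- resample_moving_average(ev, window_days = 5, max_day = 168,
                                    features = set$features)
  expect_equal(unname(extract_day_matrix(set, 30)[pid, ]),
               unname(extract_day_vector(single, 30)))
})

test_that("resampled matrices round-trip through tidy CSV", {
  st <- small_cohort_state()
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_patient_matrices(st$set, tmp, days = c(1, 30, 168))
  back <- read_patient_matrices(tmp)
  expect_equal(extract_day_matrix(back, 30), extract_day_matrix(st$set, 30))
  expect_equal(extract_day_matrix(back, 168), extract_day_matrix(st$set, 168))
})

test_that("calendar events align to the days-before-death axis", {
  ev <- data.frame(patient_id = c("A", "A", "B"),
                   date = c("2020-01-01", "2020-01-05", "2020-03-01"),
                   parameter = "alb", value = 1:3,
                   stringsAsFactors = FALSE)
  deaths <- data.frame(patient_id = c("A", "B"),
                       death_date = c("2020-01-10", "2020-02-01"),
                       stringsAsFactors = FALSE)
  expect_warning(out <- align_events_to_death(ev, deaths), "after death")
  expect_equal(out$days_before_death, c(9, 5))
  expect_equal(nrow(out), 2)  # B's post-death event dropped
})
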