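#' Specify a synthetic decedent cohort
#'
#' Defines the study conditions for the simulator: every generated patient is
#' a decedent observed over the final `observation_window` days of life, with
#' laboratory panels collected at irregular visits whose median spacing is
#' `median_visit_gap` days, and with per-feature event-level missingness.
#'
#' @param n_patients number of decedents to simulate.
#' @param n_subtypes number of latent patient-state subtypes K.
#' @param mixing_proportions probability of each subtype; must sum to 1.
#' @param observation_window days of pre-death follow-up (death = day 0).
#' @param median_visit_gap target median spacing between laboratory visits,
#'   in days. Visit gaps are drawn from a low-dispersion distribution on
#'   `{gap - 1, gap, gap + 1}` so that the resampled daily grid is mostly
#'   observed, emulating the dense terminal testing of a hospital decedent
#'   cohort.
#' @param missing_rate per-feature probability that a measured visit omits
#'   that analyte. Either a single number or a named vector (by feature);
#'   unnamed features fall back to the scalar default.
#' @param seed integer seed; the entire cohort is reproducible from it.
#' @return A `cohort_spec` object (list).
#' @seealso [terminal_drift_params()], [generate_cohort()]
#' @export
cohort_spec <- function(n_patients = 600,
                        n_subtypes = 3,
                        mixing_proportions = rep(1 / n_subtypes, n_subtypes),
                        observation_window = 365,
                        median_visit_gap = 5,
                        missing_rate = 0.01,
                        seed = 1) {
  stop_if_not_scalar_count(n_patients, "n_patients")
  stop_if_not_scalar_count(n_subtypes, "n_subtypes")
  if (length(mixing_proportions) != n_subtypes)
    stop("`mixing_proportions` must have one entry per subtype")
  if (abs(sum(mixing_proportions) - 1) > 1e-12)
    stop("`mixing_proportions` must sum to 1 (tolerance 1e-12)")
  if (any(mixing_proportions < 0)) stop("`mixing_proportions` must be non-negative")
  if (observation_window <= 0) stop("`observation_window` must be positive")
  if (median_visit_gap < 1) stop("`median_visit_gap` must be >= 1")
  if (any(missing_rate < 0 | missing_rate >= 1))
    stop("`missing_rate` must be in [0, 1)")
  structure(list(n_patients = as.integer(n_patients),
                 n_subtypes = as.integer(n_subtypes),
                 mixing_proportions = as.numeric(mixing_proportions),
                 observation_window = as.integer(observation_window),
                 median_visit_gap = as.integer(median_visit_gap),
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Per-subtype feature trajectory parameters
#'
#' Builds the parameter table that drives the latent mean of each analyte:
#' for subtype `z` and feature `j` the mean at `t` days before death is
#' `baseline + shift * ramp(t; onset)`, where the ramp is 0 for `t >= onset`
#' and rises linearly to 1 at `t = 0` (death). `shift = 0` marks a nuisance
#' feature. Observed values add a patient-level random intercept
#' (`patient_sd`) and visit-level noise (`noise_sd`).
#'
#' @param table data.frame with columns `subtype` (integer), `feature`
#'   (character), `baseline`, `shift`, `onset`, `noise_sd`, `patient_sd`,
#'   and optionally `two_sided` (logical, default `FALSE`). For a
#'   two-sided feature, `shift` is a derangement magnitude: each engaged
#'   patient drifts in one direction, chosen at random per patient, so
#'   the feature's marginal distribution stays centred on its baseline
#'   (emulating analytes whose terminal derangement can go either way,
#'   like sodium or potassium).
#' @return A validated `trajectory_params` object.
#' @export
trajectory_params <- function(table) {
  needed <- c("subtype", "feature", "baseline", "shift", "onset",
              "noise_sd", "patient_sd")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols))
    stop("trajectory table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!"two_sided" %in% names(table)) table$two_sided <- FALSE
  needed <- c(needed, "two_sided")
  if (any(table$noise_sd < 0) || any(table$patient_sd < 0))
    stop("noise_sd and patient_sd must be non-negative")
  if (any(table$onset < 0)) stop("onset must be non-negative")
  tab <- table[order(table$subtype, table$feature), needed, drop = FALSE]
  rownames(tab) <- NULL
  # every (subtype, feature) pair exactly once
  key <- paste(tab$subtype, tab$feature)
  if (anyDuplicated(key)) stop("duplicate (subtype, feature) rows")
  structure(list(table = tab,
                 subtypes = sort(unique(tab$subtype)),
                 features = sort(unique(tab$feature))),
            class = "trajectory_params")
}

# Linear terminal-drift ramp: 0 until onset, then linear to 1 at death.
ramp <- function(t, onset) {
  if (any(t < 0)) stop("days before death must be non-negative")
  if (onset == 0) return(as.numeric(t == 0))
  pmax(0, 1 - t / onset)
}

#' Latent mean trajectory of one analyte
#'
#' Deterministic mean value of feature `feature` for subtype `subtype` at
#' `t` days before death: `baseline + shift * ramp(t; onset)`.
#'
#' @param params a [trajectory_params()] object.
#' @param subtype subtype label (integer).
#' @param feature feature name.
#' @param t days before death (vectorized, non-negative).
#' @return numeric vector of latent means.
#' @export
latent_mean <- function(params, subtype, feature, t) {
  stopifnot(inherits(params, "trajectory_params"))
  tab <- params$table
  row <- tab[tab$subtype == subtype & tab$feature == feature, ]
  if (nrow(row) != 1)
    stop(sprintf("no trajectory parameters for subtype %s, feature %s",
                 subtype, feature))
  row$baseline + row$shift * ramp(t, row$onset)
}

#' Default drift-cohort trajectory parameters
#'
#' The package's reference simulation: 22 lab-like analytes over K = 3
#' latent subtypes.
#'
#' * BUN drifts for every subtype as the late-onset archetype: flat until
#'   30 days before death, then rising sharply.
#' * Each subtype engages four one-sided drivers with staggered onsets
#'   (90-150 days before death), so the mortality signal decays with
#'   distance from death. The engagement patterns of albumin, CRP and LDH
#'   sketch classic terminal portraits -- subtype 1 LDH/transaminase-driven
#'   with preserved albumin, subtype 2 albumin-driven with minimal
#'   inflammation, subtype 3 a cachexia-like falling-albumin/high-CRP
#'   combination. One-sided shifts are 0.85 analyte units against a
#'   1.25-unit between-patient spread, so the day-1 marginals of any two
#'   subtypes overlap heavily for every single feature (two-sample
#'   separation AUC below 0.75) while the joint drift structure still
#'   identifies the subtype.
#' * Each subtype also engages three two-sided derangement drivers
#'   (subtype 1: sodium, calcium, glucose; 2: potassium, magnesium,
#'   phosphate; 3: platelets, white cells, urate) whose direction is
#'   random per patient, keeping their marginals centred while coupling
#'   deviation magnitude to the outcome.
#' * The remaining analytes (chloride, MCV, amylase) are pure nuisance.
#'
#' Scales are loosely calibrated to adult reference intervals; the shapes
#' (linear ramps, Gaussian noise) are simulation choices, not estimates
#' from any real cohort.
#'
#' @param n_subtypes number of subtypes (1 to 3 supported by the preset).
#' @return a [trajectory_params()] object.
#' @export
terminal_drift_params <- function(n_subtypes = 3) {
  stopifnot(n_subtypes >= 1, n_subtypes <= 3)
  # feature, baseline, unit scale u (between-patient sd = u, noise sd = u/2)
  feat <- data.frame(
    feature = c("alb", "crp", "ldh", "bun",
                "ast", "ca", "hgb", "ua", "alt",
                "tp", "na", "cre", "k", "plt",
                "wbc", "glu", "pho", "mg", "tbil",
                "cl", "mcv", "amy"),
    baseline = c(4.0, 1.0, 220, 18,
                 35, 9.2, 11.5, 5.0, 28,
                 6.8, 139, 0.9, 4.2, 230,
                 7.0, 105, 3.4, 2.1, 0.9,
                 103, 91, 70),
    u = c(0.40, 3.0, 150, 15,
          40, 0.6, 1.4, 1.8, 30,
          0.7, 3.5, 0.5, 0.45, 80,
          3.5, 35, 0.8, 0.35, 1.2,
          3.5, 5, 40),
    stringsAsFactors = FALSE
  )
  # BUN is the one driver shared by every subtype: the late-onset
  # archetype, flat until 30 days before death, then rising sharply, with
  # a tight between-patient spread (0.5 u) so its terminal excursion
  # dwarfs inter-individual variation.
  #
  # One-sided drivers drift only for the subtypes that "engage" them
  # (shift 1 u against a between-patient sd of 1.25 u, so every engaged /
  # not-engaged day-1 marginal still overlaps, separation AUC ~ 0.71).
  # The engagement patterns of the three major analytes sketch classic
  # terminal portraits: subtype 1 is LDH/transaminase-driven with
  # preserved albumin, subtype 2 is albumin-driven with minimal
  # inflammation, subtype 3 combines falling albumin with high CRP (the
  # cachexia-like pattern).
  #
  # Two-sided drivers model analytes whose terminal derangement can go
  # either way (dysnatremia, dyskalemia, ...): each engaged patient
  # deviates by 2.2 u in a random direction, so the day-1 marginal stays
  # centred on baseline (separation AUC ~ 0.5) while deviation magnitude
  # is strongly outcome-coupled -- structure a mortality model captures
  # but raw-value geometry does not.
  one_sided <- list(
    `1` = data.frame(feature = c("crp", "ldh", "ast", "alt"),
                     dir = c(1, 1, 1, 1),
                     onset = c(120, 90, 135, 100)),
    `2` = data.frame(feature = c("alb", "ldh", "cre", "tp"),
                     dir = c(-1, 1, 1, -1),
                     onset = c(150, 90, 135, 100)),
    `3` = data.frame(feature = c("alb", "crp", "tbil", "hgb"),
                     dir = c(-1, 1, 1, -1),
                     onset = c(150, 120, 135, 100))
  )
  two_sided <- list(
    `1` = data.frame(feature = c("na", "ca", "glu"), onset = c(110, 70, 55)),
    `2` = data.frame(feature = c("k", "mg", "pho"), onset = c(110, 70, 55)),
    `3` = data.frame(feature = c("plt", "wbc", "ua"), onset = c(110, 70, 55))
  )
  rows <- list()
  for (z in seq_len(n_subtypes)) {
    tab <- feat
    tab$subtype <- z
    tab$shift <- 0
    tab$onset <- 0
    tab$patient_sd <- tab$u
    tab$two_sided <- FALSE
    i <- match("bun", tab$feature)
    tab$shift[i] <- 1.1 * tab$u[i]
    tab$onset[i] <- 30
    tab$patient_sd[i] <- 0.8 * tab$u[i]
    ez <- one_sided[[as.character(z)]]
    i <- match(ez$feature, tab$feature)
    tab$shift[i] <- 0.85 * tab$u[i] * ez$dir
    tab$onset[i] <- ez$onset
    ez <- two_sided[[as.character(z)]]
    i <- match(ez$feature, tab$feature)
    tab$shift[i] <- 2.2 * tab$u[i]
    tab$onset[i] <- ez$onset
    rows[[z]] <- tab
  }
  tab <- do.call(rbind, rows)
  # spreads and sidedness are per-feature properties, identical across
  # subtypes: overlap of engaged vs not-engaged marginals depends on them
  os_feats <- unique(unlist(lapply(one_sided, `[[`, "feature")))
  ts_feats <- unique(unlist(lapply(two_sided, `[[`, "feature")))
  u_of <- feat$u[match(tab$feature, feat$feature)]
  tab$patient_sd[tab$feature %in% os_feats] <- 1.25 * u_of[tab$feature %in% os_feats]
  tab$patient_sd[tab$feature %in% ts_feats] <- 0.6 * u_of[tab$feature %in% ts_feats]
  tab$two_sided <- tab$feature %in% ts_feats
  tab$noise_sd <- 0.5 * tab$u
  trajectory_params(tab[, c("subtype", "feature", "baseline", "shift",
                            "onset", "noise_sd", "patient_sd", "two_sided")])
}

#' Default per-feature missingness for the drift preset
#'
#' Driver analytes are almost always measured when a panel is drawn (1%
#' event-level missingness); the three nuisance analytes are ordered less
#' reliably (15%), which exercises the downstream missingness filter.
#'
#' @return named numeric vector of per-feature missing rates.
#' @export
terminal_drift_missing_rates <- function() {
  p <- terminal_drift_params(1)
  rates <- setNames(rep(0.01, length(p$features)), p$features)
  rates[c("cl", "mcv", "amy")] <- 0.15
  rates
}

#' Sample laboratory visit schedules
#'
#' Draws per-patient visit days on the days-before-death axis. The first
#' visit falls within 2 days of death and successive gaps are drawn from
#' `{g - 1, g, g + 1}` with probabilities (0.35, 0.45, 0.20), giving a
#' median gap of `g = median_visit_gap`.
#'
#' @param spec a [cohort_spec()].
#' @param n number of schedules to draw (defaults to `spec$n_patients`).
#' @return list of integer vectors, each strictly decreasing in
#'   days-before-death within `[0, observation_window]`.
#' @export
sample_visit_days <- function(spec, n = spec$n_patients) {
  stopifnot(inherits(spec, "cohort_spec"))
  g <- spec$median_visit_gap
  gaps <- pmax(1L, c(g - 1L, g, g + 1L))
  W <- spec$observation_window
  out <- vector("list", n)
  max_gaps <- ceiling(W / min(gaps)) + 1L
  for (i in seq_len(n)) {
    first <- sample(0:2, 1L)
    steps <- sample(gaps, max_gaps, replace = TRUE, prob = c(0.35, 0.45, 0.20))
    days <- first + c(0L, cumsum(steps))
    days <- days[days <= W]
    out[[i]] <- sort(unique(days), decreasing = TRUE)
  }
  out
}

# Multinomial subtype assignment.
sample_subtypes <- function(spec) {
  sample(seq_len(spec$n_subtypes), spec$n_patients, replace = TRUE,
         prob = spec$mixing_proportions)
}

#' Generate a synthetic decedent cohort
#'
#' Simulates the long-format laboratory event table together with its
#' ground truth. Each visit value is
#' `latent_mean(subtype, feature, t) + patient intercept + noise`, and each
#' (visit, feature) event is independently dropped with the feature's
#' missing rate. The whole draw is reproducible from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param params a [trajectory_params()] covering all subtypes in `spec`;
#'   defaults to the package's drift preset.
#' @param missing_rates optional named per-feature missing rates overriding
#'   `spec$missing_rate`.
#' @return A list of class `cohort` with elements `events` (data.frame:
#'   `patient_id`, `days_before_death`, `parameter`, `value`), `truth`
#'   (data.frame: `patient_id`, `subtype`), `intercepts` (patients x
#'   features matrix of random intercepts), `spec`, `params`.
#' @export
generate_cohort <- function(spec, params = terminal_drift_params(spec$n_subtypes),
                            missing_rates = NULL) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(params, "trajectory_params"))
  if (!setequal(params$subtypes, seq_len(spec$n_subtypes)))
    stop("trajectory params must cover subtypes 1..K exactly")
  features <- params$features
  P <- length(features)

  rates <- setNames(rep(spec$missing_rate[1], P), features)
  if (length(spec$missing_rate) > 1 && !is.null(names(spec$missing_rate))) {
    common <- intersect(names(spec$missing_rate), features)
    rates[common] <- spec$missing_rate[common]
  }
  if (!is.null(missing_rates)) {
    common <- intersect(names(missing_rates), features)
    rates[common] <- missing_rates[common]
  }

  set.seed(spec$seed)
  subtype <- sample_subtypes(spec)
  visits <- sample_visit_days(spec)
  intercepts <- matrix(rnorm(spec$n_patients * P), spec$n_patients, P)
  sds <- vapply(features, function(f)
    params$table$patient_sd[params$table$subtype == 1 & params$table$feature == f][1],
    numeric(1))
  intercepts <- sweep(intercepts, 2, sds, `*`)
  colnames(intercepts) <- features
  # per-patient drift direction for two-sided derangement features
  signs <- matrix(sample(c(-1, 1), spec$n_patients * P, replace = TRUE),
                  spec$n_patients, P, dimnames = list(NULL, features))
  ts <- vapply(features, function(f)
    isTRUE(params$table$two_sided[params$table$subtype == 1 &
                                    params$table$feature == f][1]),
    logical(1))
  signs[, !ts] <- 1

  pid <- sprintf("P%05d", seq_len(spec$n_patients))
  nv <- lengths(visits)
  idx <- rep.int(seq_len(spec$n_patients), nv)
  day <- unlist(visits, use.names = FALSE)
  z <- subtype[idx]

  tab <- params$table
  blocks <- vector("list", P)
  for (j in seq_len(P)) {
    f <- features[j]
    rowz <- tab[tab$feature == f, ]
    rowz <- rowz[match(seq_len(spec$n_subtypes), rowz$subtype), ]
    mu <- rowz$baseline[z]
    on <- rowz$onset[z]
    sh <- rowz$shift[z]
    rmp <- ifelse(on == 0, as.numeric(day == 0), pmax(0, 1 - day / pmax(on, 1e-12)))
    val <- mu + signs[idx, j] * sh * rmp + intercepts[idx, j] +
      rnorm(length(day), sd = rowz$noise_sd[1])
    keep <- runif(length(day)) >= rates[f]
    blocks[[j]] <- data.frame(patient_id = pid[idx[keep]],
                              days_before_death = day[keep],
                              parameter = f,
                              value = val[keep],
                              stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, blocks)
  events <- events[order(events$patient_id, -events$days_before_death,
                         events$parameter), ]
  rownames(events) <- NULL

  structure(list(events = events,
                 truth = data.frame(patient_id = pid, subtype = subtype,
                                    stringsAsFactors = FALSE),
                 intercepts = `rownames<-`(intercepts, pid),
                 drift_signs = `rownames<-`(signs, pid),
                 spec = spec, params = params),
            class = "cohort")
}

#' Verify marginal overlap between planted subtypes
#'
#' For each feature, computes the resampled day-`day` value per patient and
#' the two-sample separation AUC for every pair of subtypes. Used to check
#' the generator precondition that raw single-feature marginals overlap
#' (max AUC < 0.75) even though subtypes differ in joint drift structure.
#'
#' @param cohort a [generate_cohort()] result.
#' @param day day before death at which to compare (default 1).
#' @param window_days moving-average window for the comparison.
#' @return data.frame with `feature` and `max_pairwise_auc`.
#' @export
subtype_separation_auc <- function(cohort, day = 1, window_days = 5) {
  stopifnot(inherits(cohort, "cohort"))
  pm <- resample_cohort(cohort$events, window_days = window_days,
                        max_day = day + window_days)
  vals <- extract_day_matrix(pm, day)
  z <- cohort$truth$subtype[match(pm$patient_ids, cohort$truth$patient_id)]
  pairs <- utils::combn(sort(unique(z)), 2, simplify = FALSE)
  out <- vapply(colnames(vals), function(f) {
    max(vapply(pairs, function(pr) {
      a <- vals[z == pr[1], f]
      b <- vals[z == pr[2], f]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (!length(a) || !length(b)) return(0.5)
      auc <- auroc(c(rep(0, length(a)), rep(1, length(b))), c(a, b))
      max(auc, 1 - auc)
    }, numeric(1)))
  }, numeric(1))
  data.frame(feature = colnames(vals), max_pairwise_auc = unname(out),
             stringsAsFactors = FALSE)
}
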