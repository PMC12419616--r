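#' Build a pipeline configuration
#'
#' Assembles, with defaults, the single configuration object that drives
#' [run_pipeline()]. Every stage's randomness descends from `seed`.
#' Configurations round-trip through YAML via [write_config()] /
#' [read_config()].
#'
#' @param input either `list(type = "synthetic", n_patients = ..., ...)`
#'   (fields forwarded to [cohort_spec()]) or
#'   `list(type = "csv", events = "<path>", deaths = "<path or NULL>")`.
#' @param preprocess window width, alignment and coverage threshold.
#' @param labeling horizons, negative day and the `min_observed`
#'   availability rule.
#' @param modeling boosting and cross-validation options.
#' @param behavior correct-positive threshold.
#' @param embedding method, missingness cap and method parameters.
#' @param stratify k range (or fixed k) and test significance level.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input = list(type = "synthetic", n_patients = 300),
                            preprocess = list(),
                            labeling = list(),
                            modeling = list(),
                            behavior = list(),
                            embedding = list(),
                            stratify = list(),
                            seed = 1) {
  cfg <- list(
    input = modifyList(list(type = "synthetic"), input),
    preprocess = modifyList(list(window_days = 5, align = "centered",
                                 min_patient_fraction = 0.5), preprocess),
    labeling = modifyList(list(horizons = c(1, 15, 30, 45, 60, 75, 90),
                               negative_day = 168, min_observed = 1), labeling),
    modeling = modifyList(list(nrounds = 100, search_budget = 0, folds = 5,
                               test_fraction = 0.2,
                               validation_fraction_of_train = 0.2), modeling),
    behavior = modifyList(list(threshold = 0.5, top_k = 10), behavior),
    embedding = modifyList(list(method = "umap", max_missing = 0.10,
                                params = list()), embedding),
    stratify = modifyList(list(k_range = 2:8, k = NULL, alpha = 0.01,
                               focus = NULL), stratify),
    seed = as.integer(seed)
  )
  # canonical form: unset options are absent, not NULL, so configurations
  # survive YAML serialization unchanged
  cfg <- lapply(cfg, function(x)
    if (is.list(x)) x[!vapply(x, is.null, logical(1))] else x)
  validate_config(cfg)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

validate_config <- function(cfg) {
  lb <- cfg$labeling
  if (any(lb$horizons < 1) || any(lb$horizons >= lb$negative_day))
    stop("horizons must lie in [1, negative_day)")
  if (anyDuplicated(lb$horizons)) stop("duplicate horizons")
  if (!cfg$input$type %in% c("synthetic", "csv"))
    stop("input type must be 'synthetic' or 'csv'")
  if (cfg$embedding$max_missing <= 0 || cfg$embedding$max_missing > 1)
    stop("embedding max_missing must be in (0, 1]")
  if (cfg$stratify$alpha <= 0 || cfg$stratify$alpha >= 1)
    stop("stratify alpha must be in (0, 1)")
  invisible(TRUE)
}

#' Write / read a pipeline configuration as YAML
#'
#' @param cfg a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(input = raw$input %||% list(), preprocess = raw$preprocess %||% list(),
                  labeling = raw$labeling %||% list(), modeling = raw$modeling %||% list(),
                  behavior = raw$behavior %||% list(), embedding = raw$embedding %||% list(),
                  stratify = raw$stratify %||% list(), seed = raw$seed %||% 1)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes simulate/ingest, preprocessing, labeling, model training,
#' attribution and behavior estimation, embedding, and stratification in
#' order, writing every tabular artifact as CSV plus a JSON run manifest
#' (config hash, stage timings, artifact paths and md5 hashes, package
#' versions, warnings). Re-running with an identical configuration into a
#' directory holding a complete previous run returns that run's manifest
#' unchanged unless `force = TRUE`.
#'
#' @param config a [pipeline_config()].
#' @param output_dir directory for artifacts (created if needed).
#' @param force recompute even if a config-compatible run exists.
#' @return the run manifest (list), invisibly also written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, output_dir, force = FALSE) {
  validate_config(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(output_dir, "manifest.json")
  chash <- config_hash(config)
  if (!force && file.exists(manifest_path)) {
    prev <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    if (identical(prev$config_hash, chash) &&
        all(file.exists(file.path(output_dir, unlist(prev$artifacts))))) {
      message("config-compatible run found; reusing cached artifacts")
      return(invisible(prev))
    }
  }
  t0 <- Sys.time()
  timings <- c()
  artifacts <- list()
  warnings_log <- character()
  seed <- config$seed
  tick <- function(stage, start) {
    timings[[stage]] <<- round(as.numeric(Sys.time() - start, units = "secs"), 3)
  }
  emit <- function(name, writer) {
    path <- file.path(output_dir, name)
    writer(path)
    artifacts[[sub("\\.csv$|\\.yml$", "", name)]] <<- name
    path
  }

  ## 1. input -------------------------------------------------------------
  st <- Sys.time()
  if (config$input$type == "synthetic") {
    spec_args <- config$input[setdiff(names(config$input), "type")]
    spec_args$seed <- spec_args$seed %||% derive_seed(seed, "simulate")
    spec <- do.call(cohort_spec, spec_args)
    cohort <- generate_cohort(spec, missing_rates = terminal_drift_missing_rates())
    events <- cohort$events
    emit("events.csv", function(p) write.csv(events, p, row.names = FALSE))
    emit("ground_truth.csv",
         function(p) write.csv(cohort$truth, p, row.names = FALSE))
  } else {
    events <- read.csv(config$input$events, stringsAsFactors = FALSE)
    if (!"days_before_death" %in% names(events)) {
      deaths <- read.csv(config$input$deaths, stringsAsFactors = FALSE)
      events <- align_events_to_death(events, deaths)
    }
  }
  tick("input", st)

  ## 2. preprocess --------------------------------------------------------
  st <- Sys.time()
  events <- withCallingHandlers(
    dedup_first_per_day(events),
    warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  cov <- coverage_filter(events, config$preprocess$min_patient_fraction)
  events <- events[events$parameter %in% cov$parameters &
                     !events$patient_id %in% cov$excluded_patients, ]
  max_day <- max(config$labeling$negative_day, 90)
  set <- resample_cohort(events, window_days = config$preprocess$window_days,
                         max_day = max_day, align = config$preprocess$align)
  used_days <- sort(unique(c(config$labeling$horizons,
                             config$labeling$negative_day)))
  emit("resampled_states.csv",
       function(p) write_patient_matrices(set, p, days = used_days))
  tick("preprocess", st)

  ## 3. label + 4. train --------------------------------------------------
  st <- Sys.time()
  fam <- train_model_family(
    set, horizons = config$labeling$horizons,
    negative_day = config$labeling$negative_day,
    min_observed = config$labeling$min_observed,
    nrounds = config$modeling$nrounds,
    search_budget = config$modeling$search_budget,
    folds = config$modeling$folds,
    test_fraction = config$modeling$test_fraction,
    validation_fraction_of_train = config$modeling$validation_fraction_of_train,
    seed = derive_seed(seed, "modeling"))
  emit("model_metrics.csv",
       function(p) write.csv(fam$metrics, p, row.names = FALSE))
  splits <- do.call(rbind, lapply(names(fam$splits), function(h)
    cbind(horizon = as.integer(h), fam$splits[[h]])))
  emit("split_plan.csv", function(p) write.csv(splits, p, row.names = FALSE))
  tick("train", st)

  ## 5. attribution + behaviors -------------------------------------------
  st <- Sys.time()
  thr <- config$behavior$threshold
  panels <- lapply(names(fam$models), function(h)
    attribute_panel(fam$models[[h]], fam$datasets[[h]], fam$splits[[h]],
                    use = "test"))
  names(panels) <- names(fam$models)
  cp_panels <- lapply(panels, select_correct_positives, threshold = thr)
  bm <- behavior_matrix(cp_panels)
  emit("behavior_matrix.csv", function(p) write_behavior_matrix(bm, p))
  day1_key <- as.character(min(fam$metrics$horizon[fam$metrics$n_patients > 0]))
  rk <- rank_and_proportions(bm, horizon = as.integer(day1_key),
                             k = min(config$behavior$top_k, length(bm$features)),
                             focus = config$stratify$focus)
  emit("top_features.csv", function(p) write.csv(rk$top, p, row.names = FALSE))
  emit("attribution_proportions.csv",
       function(p) write.csv(rk$proportions, p, row.names = FALSE))
  tick("behaviors", st)

  ## 6. embedding ---------------------------------------------------------
  st <- Sys.time()
  emb <- tryCatch({
    mfres <- missingness_filter(set, horizons = fam$metrics$horizon,
                                max_missing = config$embedding$max_missing)
    stacked <- build_state_matrices(set, panels, mfres$features, threshold = thr)
    ev <- embed_state_variants(stacked, method = config$embedding$method,
                               params = config$embedding$params,
                               seed = derive_seed(seed, "embedding"))
    emit("embedding_coords.csv",
         function(p) write.csv(ev$coords, p, row.names = FALSE))
    emit("embedding_scores.csv", function(p)
      write.csv(data.frame(variant = names(ev$scores),
                           temporal_separation = as.numeric(ev$scores)),
                p, row.names = FALSE))
    ev
  }, error = function(e) {
    warnings_log <<- c(warnings_log, paste("embedding skipped:",
                                           conditionMessage(e)))
    NULL
  })
  tick("embedding", st)

  ## 7. stratification ----------------------------------------------------
  st <- Sys.time()
  day1_cp <- cp_panels[[day1_key]]
  # one row per patient: a patient can appear once per horizon only, and
  # the day-1 panel already holds at most one positive row per patient
  res_shap <- cluster_and_select_k(day1_cp, k_range = config$stratify$k_range,
                                   k = config$stratify$k, space = "attribution")
  raw_day1 <- extract_day_matrix(set, as.integer(day1_key))[day1_cp$patient_id, ,
                                                            drop = FALSE]
  raw_ok <- complete.cases(raw_day1)
  res_raw <- cluster_and_select_k(raw_day1[raw_ok, , drop = FALSE],
                                  k_range = config$stratify$k_range,
                                  k = config$stratify$k, standardize = TRUE,
                                  space = "raw-value")
  emit("subtype_labels.csv", function(p)
    write.csv(rbind(data.frame(patient_id = names(res_shap$labels),
                               space = "attribution",
                               subtype = as.integer(res_shap$labels)),
                    data.frame(patient_id = names(res_raw$labels),
                               space = "raw-value",
                               subtype = as.integer(res_raw$labels))),
              p, row.names = FALSE))
  emit("cluster_selection.csv", function(p)
    write.csv(rbind(cbind(space = "attribution", res_shap$selection),
                    cbind(space = "raw-value", res_raw$selection)),
              p, row.names = FALSE))
  labs <- data.frame(patient_id = rownames(raw_day1), raw_day1,
                     check.names = FALSE, stringsAsFactors = FALSE)
  summ <- withCallingHandlers(
    subtype_summary_and_tests(res_shap$labels, labs,
                              alpha = config$stratify$alpha),
    warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  emit("subtype_lab_summary.csv",
       function(p) write.csv(summ$lab_summary, p, row.names = FALSE))
  if (!is.null(summ$tests))
    emit("subtype_tests.csv",
         function(p) write.csv(summ$tests, p, row.names = FALSE))
  if (!is.null(summ$pairwise))
    emit("subtype_tests_pairwise.csv",
         function(p) write.csv(summ$pairwise, p, row.names = FALSE))
  sb <- subtype_behaviors(res_shap$labels, cp_panels)
  for (g in names(sb))
    emit(sprintf("behavior_matrix_subtype%s.csv", g),
         local({gg <- g; function(p) write_behavior_matrix(sb[[gg]], p)}))
  tick("stratify", st)

  ## 8. manifest ----------------------------------------------------------
  emit("config.yml", function(p) write_config(config, p))
  files <- unlist(artifacts)
  hashes <- unname(tools::md5sum(file.path(output_dir, files)))
  manifest <- list(
    config_hash = chash,
    seed = seed,
    created = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    stage_seconds = as.list(timings),
    artifacts = as.list(setNames(files, names(artifacts))),
    artifact_md5 = as.list(setNames(hashes, files)),
    horizon_sizes = setNames(as.list(fam$metrics$n_patients),
                             fam$metrics$horizon),
    versions = list(shapdyn = as.character(utils::packageVersion("shapdyn")),
                    xgboost = as.character(utils::packageVersion("xgboost")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    warnings = warnings_log
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
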