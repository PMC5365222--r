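#' Run the full modelling pipeline
#'
#' End-to-end flow: read and validate the inputs, build derived
#' features on the training cohort, run branched CAFS searches over the
#' feature space, fit the final member models, combine them into a
#' weighted ensemble (equal weights, or a random-initialisation weight
#' search), fit the risk-to-time-of-event map on observed deaths, and
#' score the resulting predictions. All artefacts - risk and TTE CSVs,
#' member model JSONs, search traces, score report and a reproducibility
#' manifest - are written under `out_dir`.
#'
#' @param cohort_file,schema_file cohort CSV and covariate tag map.
#' @param lesion_file optional lesion CSV.
#' @param recipe feature recipe (list or YAML path); `NULL` skips
#'   feature derivation.
#' @param feature_space covariate names searched by CAFS (default: the
#'   recipe's derived features).
#' @param initial_specs list of initial [model_spec()]s, one CAFS
#'   branch each.
#' @param config a [search_config()].
#' @param out_dir output directory (created if needed).
#' @param search_ensemble_weights if `TRUE`, run [search_weights()];
#'   otherwise use equal weights.
#' @param n_weight_init random weight initialisations when searching.
#' @param test_cohort_file,test_lesion_file optional held-out cohort
#'   scored instead of the training data.
#' @return the run manifest, invisibly; side effect: files in
#'   `out_dir`.
#' @export
run_pipeline <- function(cohort_file, schema_file, lesion_file = NULL,
                         recipe = NULL, feature_space = NULL,
                         initial_specs = list(model_spec()),
                         config = search_config(),
                         out_dir = "cafsurv_run",
                         search_ensemble_weights = FALSE,
                         n_weight_init = 100,
                         test_cohort_file = NULL,
                         test_lesion_file = NULL) {
  t0 <- Sys.time()
  for (f in c(cohort_file, schema_file, lesion_file, test_cohort_file,
              test_lesion_file)) {
    if (!is.null(f) && !file.exists(f))
      stop("input file not found: ", f, call. = FALSE)
  }
  if (is.character(recipe)) recipe <- read_recipe(recipe)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  schema <- read_schema(schema_file)
  cohort <- read_cohort(cohort_file, schema)
  lesions <- if (!is.null(lesion_file)) read_lesions(lesion_file)

  stage <- "features"
  transformers <- NULL
  if (!is.null(recipe)) {
    fb <- build_features(recipe, cohort, lesions)
    cohort <- fb$cohort
    transformers <- fb$transformers
    if (is.null(feature_space)) feature_space <- transformers$derived
  }
  if (is.null(feature_space))
    feature_space <- names(attr(cohort, "schema"))

  stage <- "cafs"
  fits <- branch_search(initial_specs, cohort, feature_space, config)
  if (!length(fits)) stop("pipeline stage `cafs`: no branch succeeded",
                          call. = FALSE)
  members <- lapply(fits, function(f) fit_cox(f$spec, cohort))
  members <- Filter(function(m) m$converged, members)
  if (!length(members))
    stop("pipeline stage `cafs`: no final model converged", call. = FALSE)

  stage <- "ensemble"
  if (length(members) >= 2 && search_ensemble_weights) {
    ws <- search_weights(members, cohort, config, n_init = n_weight_init)
    weights <- ws$weights
  } else {
    weights <- rep(1 / length(members), length(members))
  }
  ens <- ensemble_model(members, weights)

  stage <- "predict"
  eval_cohort <- cohort
  if (!is.null(test_cohort_file)) {
    tc <- read_cohort(test_cohort_file, schema)
    tl <- if (!is.null(test_lesion_file)) read_lesions(test_lesion_file)
    eval_cohort <- if (!is.null(transformers))
      apply_features(transformers, tc, tl) else tc
  }
  risk <- ensemble_risk(ens, eval_cohort)
  tte_map <- fit_tte_map(ensemble_risk(ens, cohort),
                         as_surv_outcome(cohort))
  tte <- predict_tte(tte_map, risk)

  stage <- "score"
  report <- score_predictions(risk, as_surv_outcome(eval_cohort),
                              config$grid, predicted_days = tte)

  # write artefacts
  paths <- c(risk = file.path(out_dir, "risk.csv"),
             tte = file.path(out_dir, "tte.csv"),
             report = file.path(out_dir, "score_report.json"),
             trace = file.path(out_dir, "search_trace.json"),
             manifest = file.path(out_dir, "manifest.json"))
  write.csv(data.frame(patient_id = eval_cohort$patient_id, risk = risk),
            paths["risk"], row.names = FALSE)
  write.csv(data.frame(patient_id = eval_cohort$patient_id,
                       predicted_days = tte),
            paths["tte"], row.names = FALSE)
  for (i in seq_along(members)) {
    mp <- file.path(out_dir, sprintf("model_%02d.json", i))
    write_cox_model(members[[i]], mp)
    paths[sprintf("model_%02d", i)] <- mp
  }
  jsonlite::write_json(
    list(iAUC = report$iAUC, c_index = report$c_index,
         rmse_days = report$rmse_days, auc_at = as.list(report$auc_at)),
    paths["report"], auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    lapply(fits, function(f) lapply(unclass(f$trace), function(it)
      list(iteration = it$iteration, action = it$action,
           chosen = it$chosen, rationale = it$rationale,
           n_candidates = nrow(it$candidates)))),
    paths["trace"], auto_unbox = TRUE)

  inputs <- c(cohort_file, schema_file, lesion_file, test_cohort_file,
              test_lesion_file)
  manifest <- list(
    package_version = as.character(utils::packageVersion("cafsurv")),
    seed = config$seed,
    config_hash = digest_obj(config),
    input_digests = as.list(tools::md5sum(inputs)),
    ensemble_weights = ens$weights,
    member_specs = vapply(members, function(m) format(m$spec), ""),
    outputs = as.list(paths),
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

digest_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(x), collapse = ""), f)
  unname(tools::md5sum(f))
}
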