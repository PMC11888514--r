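#' Write / read a cohort as plain CSV tables
#'
#' A cohort directory holds `participants.csv`, `urine_samples.csv`,
#' `self_reports.csv` and (when present) `events.csv`, with the column layouts
#' produced by [generate_cohort()].
#'
#' @param cohort a `flavanol_cohort`.
#' @param dir output directory (created if needed).
#' @return `write_cohort` invisibly returns `dir`; `read_cohort` returns a
#'   `flavanol_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tb in c("participants", "urine_samples", "self_reports", "events")) {
    if (!is.null(cohort[[tb]]))
      utils::write.csv(cohort[[tb]], file.path(dir, paste0(tb, ".csv")),
                       row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  rd <- function(f) {
    path <- file.path(dir, paste0(f, ".csv"))
    if (!file.exists(path)) return(NULL)
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  p <- rd("participants")
  if (is.null(p)) stop(sprintf("no participants.csv under %s", dir))
  p$arm <- factor(p$arm, levels = c("placebo", "intervention"))
  if ("sex" %in% names(p)) p$sex <- factor(p$sex, levels = c("male", "female"))
  if ("smoking" %in% names(p))
    p$smoking <- factor(p$smoking, levels = c("never", "ever", "current"))
  if ("cohort" %in% names(p)) p$cohort <- factor(p$cohort, levels = c("other", "WHI"))
  u <- rd("urine_samples")
  if (!is.null(u))
    u$visit <- factor(u$visit, levels = c("baseline", "year1", "year2", "year3"))
  s <- rd("self_reports")
  if (!is.null(s)) s$status <- factor(s$status, levels = selfreport_levels())
  e <- rd("events")
  if (!is.null(e)) e$endpoint <- factor(e$endpoint, levels = endpoint_levels())
  structure(list(participants = p, urine_samples = u, self_reports = s, events = e),
            class = "flavanol_cohort")
}

#' Configuration for an end-to-end pipeline run
#'
#' Exactly one threshold source must be active: the standard profile
#' (`"cosmos_default"`), derivation from a calibration CSV
#' (`"derive_from_calibration"`, requires `calibration`), or explicit values
#' (`"explicit"`, requires `thresholds = c(t_gvlm, t_srem)`).
#'
#' @param input directory of cohort CSVs, or `NULL` to simulate.
#' @param simulate a [cohort_params()] used when `input` is `NULL`;
#'   `"table1_fixture"` selects the deterministic benchmark cohort.
#' @param threshold_source one of `"cosmos_default"`,
#'   `"derive_from_calibration"`, `"explicit"`.
#' @param thresholds numeric `c(t_gvlm, t_srem)` for `"explicit"`.
#' @param calibration path to a calibration CSV (`dose`, `concentration`,
#'   `biomarker` with values `gvlm`/`srem`) for `"derive_from_calibration"`.
#' @param dose,level,interval_kind threshold-derivation settings.
#' @param models model ids for the analysis stage.
#' @param endpoints endpoints to analyse.
#' @param sweep `NULL` to skip the sweep stage, else a list with `grid_gvlm`
#'   and `grid_srem`.
#' @param seed seed recorded in the manifest and used for simulation.
#' @param out_dir output directory.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, simulate = cohort_params(),
                            threshold_source = c("cosmos_default",
                                                 "derive_from_calibration",
                                                 "explicit"),
                            thresholds = NULL, calibration = NULL,
                            dose = 500, level = 0.95,
                            interval_kind = "prediction",
                            models = 2, endpoints = endpoint_levels(),
                            sweep = NULL, seed = 1L, out_dir = tempfile("flavatrial_run_")) {
  threshold_source <- match.arg(threshold_source)
  if (threshold_source == "explicit" &&
      (is.null(thresholds) || length(thresholds) != 2 || any(thresholds <= 0)))
    stop("`thresholds` must be two positive values when threshold_source = \"explicit\"")
  if (threshold_source == "derive_from_calibration" && is.null(calibration))
    stop("`calibration` path is required when threshold_source = \"derive_from_calibration\"")
  structure(list(input = input, simulate = simulate,
                 threshold_source = threshold_source, thresholds = thresholds,
                 calibration = calibration, dose = dose, level = level,
                 interval_kind = interval_kind, models = models,
                 endpoints = endpoints, sweep = sweep, seed = seed,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort acquisition (load or simulate), threshold
#' resolution, participant classification and tabulation, the
#' ITT / per-protocol / biomarker Cox contrasts (when events are available),
#' the model-ladder sensitivity table, and an optional threshold sweep.
#' Results are written as CSV/JSON under `config$out_dir` together with a
#' manifest recording the package version, seed, a content hash of the
#' configuration, per-stage status and row counts. A stage failure is recorded
#' in the manifest and downstream stages are skipped; the manifest is always
#' written.
#'
#' @param config a [pipeline_config()].
#' @return the manifest (list), invisibly; its `stages` entry maps stage name
#'   to status (`"ok"`, `"skipped"`, `"failed: <message>"`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "flavatrial",
    version = as.character(utils::packageVersion("flavatrial")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    stages = list(), rows = list()
  )
  failed <- FALSE
  stage <- function(name, expr) {
    if (failed) { manifest$stages[[name]] <<- "skipped"; return(NULL) }
    tryCatch({
      val <- force(expr)
      manifest$stages[[name]] <<- "ok"
      val
    }, error = function(e) {
      manifest$stages[[name]] <<- paste0("failed: ", conditionMessage(e))
      failed <<- TRUE
      NULL
    })
  }

  cohort <- stage("cohort", {
    if (!is.null(config$input)) read_cohort(config$input)
    else if (identical(config$simulate, "table1_fixture")) table1_fixture()
    else {
      prm <- as.list(unclass(config$simulate))
      prm$seed <- config$seed
      generate_cohort(do.call(cohort_params, prm))
    }
  })
  if (!is.null(cohort)) {
    manifest$rows$participants <- nrow(cohort$participants)
    manifest$rows$urine_samples <- nrow(cohort$urine_samples)
  }

  thresholds <- stage("thresholds", {
    switch(config$threshold_source,
      cosmos_default = cosmos_thresholds(),
      explicit = threshold_pair(config$thresholds[1], config$thresholds[2]),
      derive_from_calibration = {
        cal <- utils::read.csv(config$calibration, stringsAsFactors = FALSE)
        tg <- derive_threshold(
          fit_dose_response(cal[cal$biomarker == "gvlm", ]),
          dose = config$dose, level = config$level,
          interval_kind = config$interval_kind)
        ts <- derive_threshold(
          fit_dose_response(cal[cal$biomarker == "srem", ]),
          dose = config$dose, level = config$level,
          interval_kind = config$interval_kind)
        threshold_pair(as.numeric(tg), as.numeric(ts), level = config$level,
                       interval_kind = config$interval_kind)
      })
  })

  cls <- stage("classify", {
    cl <- classify_participants(cohort$urine_samples, cohort$participants, thresholds)
    tab <- tabulate_classification(cl, cohort$participants, cohort$urine_samples)
    utils::write.csv(as.data.frame(tab), file.path(config$out_dir, "table1.csv"),
                     row.names = FALSE)
    adh <- adherence_summary(cl, cohort$self_reports)
    jsonlite::write_json(
      list(table1 = as.data.frame(tab), adherence = adh,
           thresholds = list(t_gvlm = thresholds$t_gvlm, t_srem = thresholds$t_srem)),
      file.path(config$out_dir, "classification.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    cl
  })

  has_events <- !is.null(cohort$events)
  contrasts_tab <- if (has_events) stage("analyze", {
    tab <- run_contrasts(cohort, cls, contrasts = c("itt", "pp", "biomarker"),
                         models = config$models, endpoints = config$endpoints)
    utils::write.csv(as.data.frame(tab), file.path(config$out_dir, "table2.csv"),
                     row.names = FALSE)
    ladder <- model_ladder(cohort, cls, endpoints = config$endpoints)
    utils::write.csv(as.data.frame(ladder), file.path(config$out_dir, "table3.csv"),
                     row.names = FALSE)
    manifest$rows$contrast_cells <- nrow(tab)
    tab
  }) else { manifest$stages$analyze <- "skipped (no events)"; NULL }

  if (has_events && !is.null(config$sweep)) {
    stage("sweep", {
      sw <- sweep_thresholds(cohort, config$sweep$grid_gvlm, config$sweep$grid_srem,
                             endpoints = config$endpoints,
                             model = config$models[1])
      utils::write.csv(as.data.frame(sw), file.path(config$out_dir, "sweep.csv"),
                       row.names = FALSE)
      manifest$rows$sweep_cells <- nrow(sw)
      sw
    })
  } else if (!is.null(config$sweep)) manifest$stages$sweep <- "skipped"

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest[setdiff(names(manifest), c("started", "finished"))],
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(manifest, list(classifications = cls, contrasts = contrasts_tab)))
}
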