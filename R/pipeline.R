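#' Assemble a pipeline configuration
#'
#' Bundles everything one run needs: either a synthetic [sealing_scenario()]
#' or a directory of real track files, the evaluation times, the statistical
#' options and the seed.  Configurations can also be loaded from YAML/JSON
#' via [read_pipeline_config()].
#'
#' @param scenario a [sealing_scenario()], or `NULL` when `tracks_dir` is
#'   given.
#' @param tracks_dir directory of track files in the [write_tracks()]
#'   dialect (used instead of simulation when non-`NULL`).
#' @param evaluation_times minutes at which the bending angle is scored.
#' @param ranks rank handling for the ANOVA, see [rm_anova_two_way()].
#' @param alpha significance level recorded in the report.
#' @param seed integer seed; overrides the scenario's seed so one number
#'   controls the whole run.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = sealing_scenario(),
                            tracks_dir = NULL,
                            evaluation_times = c(1, 5, 10, 20, 40, 55),
                            ranks = c("global", "none", "per-effect"),
                            alpha = 0.05,
                            seed = 1L) {
  ranks <- match.arg(ranks)
  if (is.null(scenario) && is.null(tracks_dir))
    stopf("provide a scenario or a tracks_dir")
  if (!is.null(scenario)) {
    if (!inherits(scenario, "sealing_scenario"))
      stopf("'scenario' must come from sealing_scenario()")
    scenario$seed <- as.integer(seed)
  }
  check_scalar(alpha, "alpha", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  structure(list(scenario = scenario, tracks_dir = tracks_dir,
                 evaluation_times = evaluation_times, ranks = ranks,
                 alpha = alpha, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML or JSON file
#'
#' Recognised top-level keys: `scenario` (fields of [sealing_scenario()],
#' with `conditions` a list of `{condition, gamma_inf, tau}` entries),
#' `tracks_dir`, `evaluation_times`, `ranks`, `alpha`, `seed`.
#'
#' @param path configuration file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  scenario <- NULL
  if (!is.null(cfg$scenario)) {
    sc <- cfg$scenario
    if (!is.null(sc$conditions) && !is.data.frame(sc$conditions))
      sc$conditions <- do.call(rbind, lapply(sc$conditions, as.data.frame))
    scenario <- do.call(sealing_scenario, sc)
  }
  pipeline_config(scenario = scenario,
                  tracks_dir = cfg$tracks_dir,
                  evaluation_times = cfg$evaluation_times %||%
                    (scenario$evaluation_times %||% c(1, 5, 10, 20, 40, 55)),
                  ranks = cfg$ranks %||% "global",
                  alpha = cfg$alpha %||% 0.05,
                  seed = cfg$seed %||% scenario$seed %||% 1L)
}

#' Score tracked leaves into a repeated-measures table
#'
#' Runs the kinematics on every track series and samples the relative
#' bending angle at the evaluation times, assembling the long-format
#' subject x condition x time table that feeds the inference.
#'
#' @param tracks named list of [track_series()]; each must carry `leaf_id`
#'   and `condition` attributes.
#' @param times_min evaluation times, minutes.
#' @return data frame `subject, condition, time_min, gamma_deg`.
#' @export
tracks_to_rm_table <- function(tracks, times_min = c(1, 5, 10, 20, 40, 55)) {
  nt <- length(times_min)
  rows <- lapply(names(tracks), function(id) {
    tr <- tracks[[id]]
    smp <- sample_at_times(track_angles(tr), times_min)
    fast_df(subject = rep(attr(tr, "leaf_id") %||% id, nt),
            condition = rep(attr(tr, "condition") %||% NA_character_, nt),
            time_min = smp$requested_min,
            gamma_deg = smp$gamma_deg)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_rm_table(out)
  out
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the wound-sealing analysis pipeline end to end
#'
#' Generates (or ingests) tracked-point series, converts them to relative
#' bending angles, samples the evaluation times, summarises the
#' condition x time medians, and runs the rank-based repeated-measures
#' inference with sphericity diagnostics and Bonferroni pairwise tests.
#' Deterministic for a fixed configuration and seed.
#'
#' @param config a [pipeline_config()] (or a [sealing_scenario()], which is
#'   wrapped with defaults).
#' @param out_dir optional output directory; when given, the per-leaf angle
#'   tables, the median table, the report (JSON + text) and a run manifest
#'   are written there.
#' @return list: `rm_table`, `medians` (condition x time median
#'   `gamma_deg`), `anova` ([rm_anova_two_way()] result), `pairwise`
#'   (condition and time tables), `truth` (synthetic runs only), `manifest`.
#' @export
#' @examples
#' res <- run_pipeline(pipeline_config(sealing_scenario(n_subjects = 4), seed = 3))
#' res$anova
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (inherits(config, "sealing_scenario"))
    config <- pipeline_config(scenario = config, seed = config$seed)
  if (!inherits(config, "pipeline_config"))
    stopf("'config' must come from pipeline_config()")
  input_files <- character(0)
  truth <- NULL
  if (!is.null(config$tracks_dir)) {
    tracks <- run_stage("read_tracks", {
      input_files <- list.files(config$tracks_dir, pattern = "\\.csv$",
                                full.names = TRUE)
      read_tracks(config$tracks_dir)
    })
  } else {
    sim <- run_stage("synthgen", simulate_tracks(config$scenario))
    tracks <- sim$tracks
    truth <- sim$truth
  }
  rm_table <- run_stage("kinematics",
                        tracks_to_rm_table(tracks, config$evaluation_times))
  medians <- run_stage("summary", {
    agg <- stats::aggregate(gamma_deg ~ condition + time_min, data = rm_table,
                            FUN = stats::median)
    names(agg)[3] <- "median_gamma_deg"
    agg[order(agg$condition, agg$time_min), ]
  })
  anova <- run_stage("anova",
                     rm_anova_two_way(rm_table, ranks = config$ranks))
  ranked <- if (config$ranks == "none") rm_table else rank_transform(rm_table)
  pairwise <- run_stage("pairwise", list(
    condition = pairwise_bonferroni(ranked, "condition"),
    time = pairwise_bonferroni(ranked, "time_min")))
  manifest <- run_stage("manifest",
                        run_manifest(config, input_files))
  results <- list(rm_table = rm_table, medians = medians, anova = anova,
                  pairwise = pairwise, truth = truth, manifest = manifest)
  if (!is.null(out_dir)) {
    run_stage("write", {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_rm_table(rm_table, file.path(out_dir, "bending_angles.csv"))
      write_delim_meta(medians, file.path(out_dir, "medians.csv"),
                       meta = list(units = "median_gamma_deg in degrees"))
      write_report(results, out_dir)
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
    })
  }
  results
}

#' Build a run manifest
#'
#' Records the package version, the seed, an md5 hash of the canonical JSON
#' form of the configuration, checksums of any input files, and a timestamp,
#' so that any run can be reproduced exactly from its manifest.
#'
#' @param config a [pipeline_config()].
#' @param input_files files read by the run.
#' @return named list.
#' @export
run_manifest <- function(config, input_files = character(0)) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg$scenario <- if (!is.null(cfg$scenario)) unclass(cfg$scenario)
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  checksums <- if (length(input_files))
    as.list(tools::md5sum(input_files)) else list()
  list(package = "phylloseal",
       version = as.character(utils::packageVersion("phylloseal")),
       seed = config$seed,
       config_md5 = unname(tools::md5sum(tmp)),
       input_md5 = checksums,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}
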