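# Pipeline orchestration: read -> resolve -> filter -> summarize -> error
# rates -> EVI covariates -> hierarchical fit -> post-processing, with a run
# manifest and a run-local log. Inputs are either file paths, in-memory data
# frames, a generator preset name, or a counts-only table (model skipped).

.log_line <- function(log_path, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
  message(msg)
  if (!is.null(log_path)) cat(msg, "\n", file = log_path, append = TRUE)
}

.file_digest <- function(paths) {
  paths <- paths[!is.na(paths) & file.exists(paths)]
  if (!length(paths)) return(list())
  as.list(tools::md5sum(paths))
}

.config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yml")
  on.exit(unlink(tf))
  yaml::write_yaml(cfg, tf)
  unname(tools::md5sum(tf))
}

#' Run the full yearling-proportion analysis pipeline
#'
#' Executes every stage over the supplied inputs and writes a report
#' directory: species summary and yearling tables (CSV), age-error rates
#' (CSV), station-year EVI covariates (CSV), hierarchical-model draws (CSV)
#' and summaries (JSON), habitat-group coefficient summaries and the
#' coefficient meta-regression (JSON), plus `manifest.json` (config hash,
#' seed, input digests, per-stage row counts, collected warnings) and
#' `run.log`. Stage outputs are pure functions of (inputs, config, seed), so
#' the manifest suffices to reproduce a run.
#'
#' @param captures capture data.frame or CSV path; ignored when `preset` or
#'   `counts` is given.
#' @param evi_cells EVI cell data.frame or CSV path (long format).
#' @param preset name of a [scenario_presets()] entry (or a `sim_config`) to
#'   simulate inputs instead of reading them.
#' @param counts counts-only species table (columns `species_code`, `n_SY`,
#'   `n_ASY`, `n_AHY`, optionally `error_rate`, `error_n`); only the derived
#'   yearling/aging statistics are produced and the model stage is skipped.
#' @param out_dir output directory (created if needed); `NULL` for none.
#' @param seed integer seed controlling simulation and model fitting.
#' @param n_years study years used for the target-species filter (derived
#'   from the data when NULL).
#' @param min_mean_per_year species-inclusion threshold (default 20).
#' @param skip_fit skip the model stage (automatic for `counts` input).
#' @param fit_args list of overrides passed to [fit_yearling_model()]
#'   (e.g. `list(chains = 2, iter = 500, warmup = 500)`).
#' @return the run manifest (class `run_manifest`), invisibly containing all
#'   stage results in `$results`.
#' @export
run_pipeline <- function(captures = NULL, evi_cells = NULL, preset = NULL,
                         counts = NULL, out_dir = NULL, seed = 1,
                         n_years = NULL, min_mean_per_year = 20,
                         skip_fit = FALSE, fit_args = list()) {
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  log_path <- if (!is.null(out_dir)) file.path(out_dir, "run.log") else NULL
  warnings_seen <- character(0)
  note_warn <- function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  stage <- function(name, expr) {
    .log_line(log_path, "stage: ", name)
    tryCatch(withCallingHandlers(expr, warning = note_warn),
             error = function(e) abort("stage '", name, "' failed: ",
                                       conditionMessage(e)))
  }
  manifest <- list(seed = seed, stages = list(), outputs = character(0),
                   package_version = as.character(utils::packageVersion("yearlingr")))
  results <- list()
  input_paths <- character(0)

  if (!is.null(counts)) {
    if (is.character(counts)) { input_paths <- counts; counts <- read.csv(counts) }
    skip_fit <- TRUE
    results$summary <- counts
    results$yearling <- stage("yearling_stats", {
      yt <- data.frame(species_code = counts$species_code,
                       error_rate = if ("error_rate" %in% names(counts))
                         counts$error_rate else NA_real_,
                       n_eligible = if ("error_n" %in% names(counts))
                         counts$error_n else NA_integer_,
                       yearling_proportion = yearling_proportion(counts$n_SY,
                                                                 counts$n_ASY))
      yt
    })
    results$community <- stage("community_stats", list(
      mean_yearling_proportion = community_mean_proportion(
        results$yearling$yearling_proportion),
      pooled_yearling_proportion = pooled_yearling_proportion(counts$n_SY,
                                                              counts$n_ASY),
      percent_aged = percent_aged(sum(counts$n_SY), sum(counts$n_ASY),
                                  sum(counts$n_AHY)),
      mean_error_rate = if ("error_rate" %in% names(counts))
        community_mean_error(counts$error_rate) else NA_real_))
    manifest$stages$counts <- list(n_species = nrow(counts))
  } else {
    if (!is.null(preset)) {
      cfg <- if (inherits(preset, "sim_config")) preset
             else scenario_presets()[[preset]]
      if (is.null(cfg)) abort("unknown preset: ", preset)
      sim <- stage("simulate", simulate_study(cfg, seed))
      captures <- sim$captures
      evi_cells <- sim$evi$cells
      results$truth <- sim$truth
      manifest$config_hash <- .config_hash(unclass(cfg))
      if (is.null(n_years)) n_years <- cfg$n_years
    } else {
      if (is.character(captures)) {
        input_paths <- c(input_paths, captures)
        captures <- stage("read_captures", read_captures(captures))
      }
      if (is.character(evi_cells)) {
        input_paths <- c(input_paths, evi_cells)
        evi_cells <- stage("read_evi", read_evi_cells(evi_cells))
      }
    }
    if (is.null(captures)) abort("no capture input supplied")
    if (is.null(n_years)) n_years <- length(unique(captures$year))

    inds <- stage("resolve_year_unique", resolve_year_unique(captures))
    target <- stage("filter_target_species",
                    filter_target_species(inds, n_years, min_mean_per_year))
    inds_t <- inds[inds$species_code %in% target, , drop = FALSE]
    results$individuals <- inds_t
    results$summary <- stage("summarize_species", summarize_species(inds_t))
    results$errors <- stage("age_error_rates", {
      er <- age_error_rates(captures)
      er[er$species_code %in% target, , drop = FALSE]
    })
    results$yearling <- stage("yearling_table",
                              yearling_table(results$summary, results$errors))
    results$community <- stage("community_stats", list(
      mean_yearling_proportion = community_mean_proportion(
        results$yearling$yearling_proportion),
      pooled_yearling_proportion = pooled_yearling_proportion(
        results$summary$n_SY, results$summary$n_ASY),
      percent_aged = percent_aged(sum(results$summary$n_SY),
                                  sum(results$summary$n_ASY),
                                  sum(results$summary$n_AHY)),
      mean_error_rate = community_mean_error(results$errors)))
    manifest$stages$captures <- list(n_records = nrow(captures),
                                     n_year_unique = nrow(inds),
                                     n_target_species = length(target))

    if (!is.null(evi_cells)) {
      results$station_evi <- stage("station_year_evi",
                                   station_year_evi(evi_cells))
      results$profiles <- stage("species_evi_profiles",
                                species_evi_profiles(inds_t,
                                                     results$station_evi,
                                                     target))
      manifest$stages$evi <- list(n_station_years = nrow(results$station_evi))
      if (!skip_fit) {
        md <- stage("build_model_data",
                    build_model_data(inds_t, results$station_evi, target))
        fit <- stage("fit_yearling_model", do.call(fit_yearling_model,
          c(list(data = md, seed = seed), fit_args)))
        results$model_data <- md
        results$fit <- fit
        results$groups <- stage("group_coefficient_summary",
                                group_coefficient_summary(fit, results$profiles))
        results$meta <- stage("coefficient_meta_regression",
                              coefficient_meta_regression(fit, results$profiles))
        manifest$stages$fit <- list(n_obs = fit$flags$n_obs,
                                    n_missing = fit$flags$n_missing,
                                    converged = fit$flags$converged)
      }
    }
  }

  if (!is.null(out_dir)) {
    wr <- function(obj, file, writer) {
      p <- file.path(out_dir, file)
      writer(obj, p)
      manifest$outputs <<- c(manifest$outputs, p)
    }
    wcsv <- function(o, p) write.csv(o, p, row.names = FALSE)
    wjson <- function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE,
                                                 digits = NA, pretty = TRUE,
                                                 na = "null")
    if (!is.null(results$summary)) wr(results$summary, "species_summary.csv", wcsv)
    if (!is.null(results$errors)) wr(results$errors, "age_error_rates.csv", wcsv)
    if (!is.null(results$yearling)) wr(results$yearling, "yearling_table.csv", wcsv)
    if (!is.null(results$community)) wr(results$community, "community_stats.json", wjson)
    if (!is.null(results$station_evi)) wr(results$station_evi, "station_year_evi.csv", wcsv)
    if (!is.null(results$profiles)) wr(results$profiles, "species_evi_profiles.csv", wcsv)
    if (!is.null(results$fit)) {
      wr(as.data.frame(posterior_matrix(results$fit)), "posterior_draws.csv", wcsv)
      wr(results$fit$summary, "model_summary.json", wjson)
      wr(results$groups, "group_summary.json", wjson)
      wr(list(coefficients = results$meta$coefficients,
              r_squared = results$meta$r_squared), "meta_regression.json", wjson)
    }
  }

  manifest$input_digests <- .file_digest(input_paths)
  manifest$warnings <- warnings_seen
  if (length(warnings_seen))
    .log_line(log_path, "collected ", length(warnings_seen), " warning(s)")
  if (!is.null(out_dir)) {
    mf <- manifest
    jsonlite::write_json(mf, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, na = "null")
    manifest$outputs <- c(manifest$outputs, file.path(out_dir, "manifest.json"))
  }
  manifest$results <- results
  .log_line(log_path, "pipeline complete")
  invisible(structure(manifest, class = "run_manifest"))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run (seed ", x$seed, ")\n", sep = "")
  for (s in names(x$stages))
    cat("  ", s, ": ", paste(names(x$stages[[s]]), unlist(x$stages[[s]]),
                             sep = "=", collapse = ", "), "\n", sep = "")
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}
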