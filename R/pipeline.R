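#' Default end-to-end pipeline configuration
#'
#' @param seed global seed (per-stage draws derive from it).
#' @param synth list of [synth_config()] overrides, or `NULL` to read real
#'   input files from `inputs` instead.
#' @param inputs list of file paths (`locations`, `flows`, `stringency`,
#'   `reference`) plus `hub_id`; ignored when `synth` is given.
#' @param models character vector among `"gravity-exp"`, `"gravity-pow"`,
#'   `"radiation"`, `"cgm-exp"`, `"cgm-pow"`.
#' @param directions which star directions to evaluate.
#' @param gravity_fit_scope `"per-day"` or `"global"`.
#' @param p1_end last day of evaluation period P1.
#' @param synchrony list: `windows`, plus (synthetic runs only) `scale` and
#'   `noise_sd_fraction` of the constructed reference series.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            synth = list(),
                            inputs = NULL,
                            models = c("gravity-exp", "gravity-pow",
                                       "radiation", "cgm-exp", "cgm-pow"),
                            directions = c("incoming", "outgoing"),
                            gravity_fit_scope = "per-day",
                            p1_end = "2020-03-15",
                            synchrony = list(windows = c(5, 10, 15, 20, 25),
                                             scale = 0.85,
                                             noise_sd_fraction = 0.05)) {
  known <- c("gravity-exp", "gravity-pow", "radiation", "cgm-exp", "cgm-pow")
  if (!all(models %in% known)) {
    mf_abort("mobiflux_config_error",
             paste0("unknown model(s): ",
                    paste(setdiff(models, known), collapse = ", ")))
  }
  structure(list(seed = as.integer(seed), synth = synth, inputs = inputs,
                 models = models, directions = directions,
                 gravity_fit_scope = gravity_fit_scope,
                 p1_end = as.Date(p1_end), synchrony = synchrony),
            class = "pipeline_config")
}

read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

resolve_pipeline_inputs <- function(config) {
  if (!is.null(config$synth)) {
    sc <- do.call(synth_config, c(config$synth,
                                  list(seed = config$seed)))
    world <- generate_world(sc)
    sim <- simulate_flows(world, seed = sc$seed + 1L, direction = "both")
    ref <- generate_reference_series(
      sim$panel, scale = config$synchrony$scale %||% 0.85,
      noise_sd_fraction = config$synchrony$noise_sd_fraction %||% 0.05,
      seed = sc$seed + 2L, direction = "incoming")
    list(locations = world$locations, dist = world$dist,
         stringency = world$stringency, flows = sim$panel,
         reference = ref, truth = sim$truth, synthetic = TRUE)
  } else {
    ins <- config$inputs
    if (is.null(ins$locations) || is.null(ins$flows) || is.null(ins$hub_id)) {
      mf_abort("mobiflux_config_error",
               "inputs must provide locations, flows and hub_id")
    }
    if (any(grepl("^cgm", config$models)) && is.null(ins$stringency)) {
      mf_abort("mobiflux_config_error",
               "a cgm model is requested but no stringency panel is configured")
    }
    locations <- load_locations(ins$locations, hub_id = ins$hub_id)
    list(locations = locations, dist = distance_matrix(locations),
         stringency = if (!is.null(ins$stringency))
           load_stringency(ins$stringency) else NULL,
         flows = load_flows(ins$flows, hub_id = ins$hub_id),
         reference = if (!is.null(ins$reference))
           load_reference(ins$reference) else NULL,
         truth = NULL, synthetic = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fit_and_predict <- function(model, observed, data, config) {
  switch(model,
    "gravity-exp" = ,
    "gravity-pow" = {
      kind <- if (model == "gravity-exp") "exponential" else "power"
      fits <- fit_gravity(observed, data$locations, kind,
                          scope = config$gravity_fit_scope, dist = data$dist)
      predict_gravity_panel(observed, data$locations, fits, data$dist)
    },
    "radiation" = predict_radiation_panel(observed, data$locations,
                                          dist = data$dist),
    "cgm-exp" = ,
    "cgm-pow" = {
      kind <- if (model == "cgm-exp") "exponential" else "power"
      design <- build_design(observed, data$locations, data$stringency,
                             kind = kind, dist = data$dist)
      cgm_predict(cgm_fit(design), design)
    })
}

#' Run the full modelling pipeline into an output directory
#'
#' Orchestrates synth (or file loading) -> model fitting -> prediction ->
#' period-split evaluation -> synchrony analysis, writing `summary.csv`,
#' `daily_metrics.csv`, `synchrony.json`, per-model prediction CSVs, the
#' input data (for synthetic runs) and a run manifest. Deterministic given
#' the config: rerunning with the same config yields byte-identical
#' summaries. Inputs are never mutated; everything is written under
#' `out_dir`.
#'
#' @param config a [pipeline_config()], or path to a YAML file of its
#'   fields.
#' @param out_dir output directory (created; must not contain a previous
#'   `summary.csv`).
#' @return (invisibly) list with `summary`, `daily`, `synchrony`, `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (any(grepl("^cgm", config$models)) && is.null(config$synth) &&
      is.null(config$inputs$stringency)) {
    mf_abort("mobiflux_config_error",
             "a cgm model is requested but no stringency panel is configured")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data <- resolve_pipeline_inputs(config)

  data_dir <- file.path(out_dir, "data")
  dir.create(data_dir, showWarnings = FALSE)
  write_locations(data$locations, file.path(data_dir, "locations.csv"))
  write_flows(data$flows, file.path(data_dir, "flows.csv"))
  if (!is.null(data$stringency)) {
    write_stringency(data$stringency, file.path(data_dir, "stringency.csv"))
  }
  if (!is.null(data$reference)) {
    ref <- data$reference
    ref$date <- format(ref$date, "%Y-%m-%d")
    write.csv(ref, file.path(data_dir, "reference.csv"),
              row.names = FALSE, quote = FALSE)
  }

  daily_all <- list()
  summary_all <- list()
  for (direction in config$directions) {
    observed <- flow_direction(data$flows, direction)
    message(sprintf("[pipeline] direction=%s: %d observed records",
                    direction, nrow(observed)))
    preds <- lapply(setNames(config$models, config$models), function(m) {
      message(sprintf("[pipeline] %s/%s: fit + predict", direction, m))
      p <- fit_and_predict(m, observed, data, config)
      out <- p
      out$flow <- sprintf("%.6f", out$flow)
      out$date <- format(out$date, "%Y-%m-%d")
      write.csv(out, file.path(out_dir, paste0("pred_", m, "_",
                                               direction, ".csv")),
                row.names = FALSE, quote = FALSE)
      p
    })
    ev <- evaluate_models(preds, observed, p1_end = config$p1_end)
    ev$daily$direction <- direction
    ev$summary$direction <- direction
    daily_all[[direction]] <- ev$daily
    summary_all[[direction]] <- ev$summary
  }
  daily <- do.call(rbind, daily_all)
  summary <- do.call(rbind, summary_all)
  rownames(daily) <- rownames(summary) <- NULL
  summary <- summary[c("direction", "model", "mu_cpc", "max_cpc", "min_cpc",
                       "mu_cpc_p1", "mu_cpc_p2", "mu_ig")]
  num <- vapply(summary, is.numeric, logical(1))
  summary_out <- summary
  summary_out[num] <- lapply(summary_out[num], function(x) sprintf("%.6f", x))
  write.csv(summary_out, file.path(out_dir, "summary.csv"),
            row.names = FALSE, quote = FALSE)
  daily_out <- daily
  daily_out$date <- format(daily_out$date, "%Y-%m-%d")
  daily_out$cpc <- sprintf("%.6f", daily_out$cpc)
  daily_out$ig <- sprintf("%.6f", daily_out$ig)
  write.csv(daily_out, file.path(out_dir, "daily_metrics.csv"),
            row.names = FALSE, quote = FALSE)

  sync <- NULL
  if (!is.null(data$reference)) {
    agg <- aggregate_daily_total(data$flows, "incoming")
    common <- intersect(format(agg$date, "%Y-%m-%d"),
                        format(data$reference$date, "%Y-%m-%d"))
    a <- agg[format(agg$date, "%Y-%m-%d") %in% common, ]
    b <- data$reference[format(data$reference$date, "%Y-%m-%d") %in% common, ]
    ws <- config$synchrony$windows %||% c(5, 10, 15, 20, 25)
    ws <- ws[ws <= nrow(a)]  # windows longer than the series are skipped
    sync <- local_synchrony(a, b, window_sizes = ws)
    jsonlite::write_json(
      list(rho_g = sync$rho_g, windows = sync$windows),
      file.path(out_dir, "synchrony.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }

  manifest <- list(
    command = "run_pipeline",
    package_version = as.character(packageVersion("mobiflux")),
    seed = config$seed,
    models = config$models,
    directions = config$directions,
    gravity_fit_scope = config$gravity_fit_scope,
    p1_end = format(config$p1_end, "%Y-%m-%d"),
    synthetic = data$synthetic,
    input_digests = as.list(tools::md5sum(
      list.files(data_dir, full.names = TRUE))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(summary = summary, daily = daily, synchrony = sync,
                 out_dir = out_dir))
}
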