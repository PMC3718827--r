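# End-to-end orchestration: simulate (or load) inputs, build the envelope,
# fit and validate the maximum-entropy model under both background modes,
# project the warming scenarios, and account areas per region — all from
# one flat config with per-stage seeds derived from a single global seed.

#' Pipeline run configuration
#'
#' Exactly one of `input_paths` (a list with `stack_dir`, `occurrences`,
#' `regions`) or `synthetic` (a [synthetic_config()]) must be supplied.
#'
#' @param synthetic a [synthetic_config()], or `NULL`.
#' @param input_paths list of input file paths, or `NULL`.
#' @param truth a [truth_spec()] for synthetic runs.
#' @param scenario a [scenario_spec()].
#' @param train_fraction,replicates validation settings.
#' @param n_background background points per mode (field default 10000).
#' @param buffer_km bias-mode buffer radius (default 20 km).
#' @param beta regularization multiplier.
#' @param n_regions synthetic region count.
#' @param seed global seed; every stage seed is derived from it.
#' @param out_dir output directory.
#' @return list of class `RunConfig`.
#' @export
run_config <- function(synthetic = synthetic_config(), input_paths = NULL,
                       truth = truth_spec(), scenario = scenario_spec(),
                       train_fraction = 0.75, replicates = 10,
                       n_background = 10000, buffer_km = 20, beta = 1.0,
                       n_regions = 4, seed = 1, out_dir = tempfile("run_")) {
  if (is.null(synthetic) == is.null(input_paths))
    stop("exactly one of synthetic config or input paths must be given")
  structure(list(synthetic = synthetic, input_paths = input_paths,
                 truth = truth, scenario = scenario,
                 train_fraction = train_fraction, replicates = replicates,
                 n_background = n_background, buffer_km = buffer_km,
                 beta = beta, n_regions = n_regions, seed = seed,
                 out_dir = out_dir),
            class = "RunConfig")
}

# deterministic polynomial string hash (no digest dependency)
string_hash <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 131 + c) %% 2147483647
  sprintf("%010d", h)
}

file_hash <- function(path) {
  string_hash(paste(readLines(path, warn = FALSE), collapse = "\n"))
}

load_stack_dir <- function(dir) {
  cont <- c("temperature", "bathymetry", "slope", "salinity",
            "current_speed")
  layers <- list()
  for (nm in cont)
    layers[[nm]] <- read_raster(file.path(dir, paste0(nm, ".asc")))
  layers$landscape <- read_raster(file.path(dir, "landscape.asc"),
                                  categorical = TRUE)
  land_path <- file.path(dir, "land_mask.asc")
  land <- if (file.exists(land_path))
    read_raster(land_path)$values > 0
  else NULL
  layer_stack(layers, land_mask = land)
}

write_stack_dir <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(stack$layers))
    write_raster(stack$layers[[nm]], file.path(dir, paste0(nm, ".asc")))
  land <- first_layer(stack)
  land$values <- matrix(as.numeric(stack$land_mask),
                        nrow(land$values), ncol(land$values))
  land$nodata_mask <- matrix(FALSE, nrow(land$values), ncol(land$values))
  write_raster(land, file.path(dir, "land_mask.asc"))
  invisible(dir)
}

#' Run the full suitability analysis
#'
#' Stages, in order: data (synthetic generation or loading), envelope
#' analysis, background sampling and model fitting for both the global and
#' the 20 km-bias mode, replicate cross-validation, warming-scenario
#' projection of the global model across the configured epochs, and area
#' accounting (band/category areas per region and epoch, percent-loss
#' table, envelope-vs-model comparison). All outputs plus a reproducibility
#' manifest are written under `config$out_dir`.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages?
#' @return the manifest, invisibly; side effect: files under
#'   `config$out_dir`.
#' @export
run_all <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message("[run_all] ", ...)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  say("stage: data")
  if (!is.null(config$synthetic)) {
    # every stage seed derives from the one global seed
    config$synthetic$seed <- derive_seed(config$seed, "synthetic")
    stack <- stage("data", generate_environment(config$synthetic,
                                                config$truth))
    occ <- stage("data", generate_occurrences(stack, config$truth,
                                              config$synthetic))
    regions <- stage("data", generate_regions(config$synthetic,
                                              config$n_regions))
    write_stack_dir(stack, file.path(out, "stack"))
    write_occurrences(occ, file.path(out, "occurrences.csv"))
    write_regions(regions, file.path(out, "regions.geojson"))
  } else {
    stack <- stage("data", load_stack_dir(config$input_paths$stack_dir))
    occ <- stage("data", read_occurrences(config$input_paths$occurrences))
    regions <- stage("data", read_regions(config$input_paths$regions))
  }
  occ <- filter_to_coverage(occ, stack)

  say("stage: envelope")
  env <- stage("envelope", build_envelope(stack, occ))
  emask <- stage("envelope", envelope_mask(stack, env))
  jsonlite::write_json(
    list(continuous_ranges = env$continuous_ranges,
         preferred_landscape = env$preferred_landscape,
         provenance = env$provenance,
         area_km2 = attr(emask, "area_km2")),
    file.path(out, "envelope.json"), auto_unbox = TRUE, digits = NA)
  write_raster(emask, file.path(out, "envelope_mask.asc"))

  say("stage: maxent")
  models <- list()
  for (mode in c("global", "bias")) {
    bg <- stage("maxent", sample_background(
      stack, occ, n = config$n_background, mode = mode,
      buffer_km = config$buffer_km,
      seed = derive_seed(config$seed, paste0("bg_", mode))))
    models[[mode]] <- stage("maxent", maxent_fit(
      extract_values(stack, occ), extract_values(stack, bg),
      beta = config$beta))
    write_model(models[[mode]], file.path(out,
                                          paste0("model_", mode, ".json")))
  }

  say("stage: validate")
  report <- stage("validate", cross_validate(
    occ, stack, fraction = config$train_fraction,
    replicates = config$replicates, seed = config$seed,
    n_background = config$n_background, buffer_km = config$buffer_km,
    beta = config$beta))
  utils::write.csv(report$replicates,
                   file.path(out, "validation_replicates.csv"),
                   row.names = FALSE)
  utils::write.csv(report$summary, file.path(out, "validation_summary.csv"),
                   row.names = FALSE)

  say("stage: scenarios + accounting")
  sc <- config$scenario
  epochs <- c(sc$baseline_year, sc$epochs)
  tables <- list()
  for (yr in epochs) {
    dT <- temperature_increment(sc, yr)
    st <- stage("scenario", apply_scenario(stack, dT))
    suit <- stage("scenario", maxent_project(models$global, st))
    write_raster(suit, file.path(out, paste0("suitability_", yr, ".asc")))
    tables[[as.character(yr)]] <- stage("assess",
                                        band_areas(suit, regions, yr))
  }
  area_tab <- do.call(rbind, tables)
  utils::write.csv(area_tab, file.path(out, "areas.csv"),
                   row.names = FALSE)
  losses <- stage("assess", loss_table(tables, as.character(epochs[1])))
  utils::write.csv(losses, file.path(out, "ms_loss.csv"), row.names = FALSE)
  cmp <- stage("assess", overlap_stats(
    emask, maxent_project(models$global, stack)))
  jsonlite::write_json(unclass(cmp), file.path(out, "comparison.json"),
                       auto_unbox = TRUE, digits = NA)

  say("stage: manifest")
  cfg_json <- jsonlite::toJSON(
    config[setdiff(names(config), "out_dir")],
    auto_unbox = TRUE, digits = NA, force = TRUE)
  files <- sort(setdiff(list.files(out, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    config_hash = string_hash(as.character(cfg_json)),
    seed = config$seed,
    stage_seeds = list(
      environment = derive_seed(config$seed, "environment"),
      occurrences = derive_seed(config$seed, "occurrences"),
      bg_global = derive_seed(config$seed, "bg_global"),
      bg_bias = derive_seed(config$seed, "bg_bias")),
    package_version = as.character(utils::packageVersion("reefsuit")),
    outputs = stats::setNames(
      lapply(files, function(f) file_hash(file.path(out, f))), files))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("done: ", out)
  invisible(manifest)
}
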