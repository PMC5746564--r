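#' Read a pipeline run configuration
#'
#' YAML or JSON file with the schema (all blocks optional, defaults in
#' parentheses):
#'
#' ```yaml
#' seed: 1            # master seed
#' alpha: 0.05        # significance level of the KW gate
#' out_dir: runs/demo # output directory
#' rf:                # forest parameters
#'   ntree: 250
#'   nodesize: 5
#' study:
#'   regions: {region_A: 3, region_B: 3, region_C: 3, region_D: 3}
#'   template: demo   # demo | recovery | null, or a landscape block
#'   beta_sd: 0.1
#'   n_zones_jitter: 10
#' ```
#'
#' A custom `template` block carries the [landscape_spec()] fields, with
#' `covariates` as a list of `{name, kind, ...}` entries.
#'
#' @param path configuration file (`.yaml`/`.yml`/`.json`).
#' @return a named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  cfg$seed <- cfg$seed %||% 1L
  cfg$alpha <- cfg$alpha %||% 0.05
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop_config("alpha must lie in (0, 1)")
  cfg$out_dir <- cfg$out_dir %||% "dasyrf_run"
  cfg$rf <- utils::modifyList(list(ntree = 250, mtry = NULL, nodesize = 5),
                              cfg$rf %||% list())
  class(cfg) <- "run_config"
  cfg
}

config_template <- function(cfg) {
  tpl <- cfg$study$template %||% "demo"
  if (is.character(tpl)) {
    return(switch(tpl,
                  demo = landscape_demo(),
                  recovery = landscape_recovery(),
                  "null" = landscape_null(),
                  stop_config("unknown study template: ", tpl)))
  }
  covs <- lapply(tpl$covariates, function(cv) do.call(covariate_def, cv))
  landscape_spec(grid_rows = tpl$grid_rows, grid_cols = tpl$grid_cols,
                 n_zones = tpl$n_zones, covariates = covs,
                 effect_weights = unlist(tpl$effect_weights %||% list()),
                 intercept = tpl$intercept %||% 7,
                 noise_sd = tpl$noise_sd %||% 0.25,
                 pixel_area = tpl$pixel_area %||% 0.01,
                 nodata_frac = tpl$nodata_frac %||% 0,
                 smoothness = tpl$smoothness %||% 4)
}

config_study <- function(cfg) {
  regions <- unlist(cfg$study$regions %||%
                      list(region_A = 3, region_B = 3,
                           region_C = 3, region_D = 3))
  generate_study(regions, config_template(cfg),
                 perturb = list(
                   beta_sd = cfg$study$beta_sd %||% 0,
                   region_beta_mult = cfg$study$region_beta_mult,
                   n_zones_jitter = cfg$study$n_zones_jitter %||% 0L),
                 seed = cfg$seed)
}

#' Simulate a study and write the bundles to disk
#'
#' @param config a `run_config` (or path to one).
#' @param verbose log progress.
#' @return the list of generated countries, invisibly.
#' @export
cmd_simulate <- function(config, verbose = TRUE) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  study <- config_study(cfg)
  for (cty in study) {
    dir <- file.path(cfg$out_dir, "countries", cty$country)
    write_country(cty, dir)
    if (verbose) message("wrote ", dir)
  }
  invisible(study)
}

#' Fit, select and map one country bundle
#'
#' Runs [pop_model()] on one synthetic country and writes the three
#' mapping artifacts: the model summary JSON, the population grid (ESRI
#' ASCII, nodata -1) and the importance/selection CSV
#' (`covariate,per_inc_mse,n_trees_used,iteration`).
#'
#' @param cty a `synthetic_country`.
#' @param cfg a `run_config`.
#' @param seed per-country seed (default: derived from `cfg$seed`).
#' @param verbose log progress.
#' @return the fitted `pop_model`, invisibly.
#' @export
cmd_fit_map <- function(cty, cfg, seed = NULL, verbose = TRUE) {
  seed <- seed %||% cfg$seed
  fit <- pop_model(cty$stack, cty$zones, cty$census,
                   ntree = cfg$rf$ntree, mtry = cfg$rf$mtry,
                   nodesize = cfg$rf$nodesize, seed = seed)
  dir <- file.path(cfg$out_dir, "models", cty$country)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  model_summary(fit, file.path(dir, "model_summary.json"))
  pop <- predict(fit, type = "population")
  write_ascii_grid(pop, file.path(dir, "population.asc"),
                   cellsize = sqrt(cty$stack$pixel_area) * 1000,
                   nodata = -1)
  if (!is.null(fit$trace))
    write.csv(as.data.frame(fit$trace),
              file.path(dir, "selection_trace.csv"), row.names = FALSE)
  write.csv(as.data.frame(fit$importance),
            file.path(dir, "importance.csv"), row.names = FALSE)
  if (verbose)
    message(sprintf("%s: %d final covariates, variance explained %.1f%%",
                    cty$country, length(fit$forest$covariates),
                    fit$forest$variance_explained))
  invisible(fit)
}

#' Run the full pipeline: simulate, fit, map, standardize, compare
#'
#' End-to-end orchestration over a whole synthetic study: country
#' generation, per-country model fitting and dasymetric mapping, WIR
#' standardization, and the hierarchy of Kruskal-Wallis / Dunn designs.
#' Per-country seeds fan out deterministically from the master seed, so a
#' rerun with the same configuration is bit-identical.
#'
#' @param config a `run_config`, a path to one, or `NULL` for the packaged
#'   demo configuration.
#' @param write write artifacts under `config$out_dir` (set `FALSE` for
#'   in-memory runs).
#' @param verbose log progress.
#' @return list with `study`, `models`, `wir` (the pooled `wir_table`)
#'   and `reports` (a `design_report_set`).
#' @export
run_pipeline <- function(config = NULL, write = TRUE, verbose = TRUE) {
  cfg <- if (is.character(config)) read_run_config(config)
         else config %||% structure(list(seed = 1L, alpha = 0.05,
                                         out_dir = "dasyrf_run",
                                         rf = list(ntree = 250,
                                                   mtry = NULL,
                                                   nodesize = 5)),
                                    class = "run_config")
  study <- config_study(cfg)
  seeds <- derive_seeds(cfg$seed, length(study) + 1L)
  models <- list()
  for (i in seq_along(study)) {
    cty <- study[[i]]
    models[[cty$country]] <-
      if (write) cmd_fit_map(cty, cfg, seed = seeds[i], verbose = verbose)
      else pop_model(cty$stack, cty$zones, cty$census,
                     ntree = cfg$rf$ntree, mtry = cfg$rf$mtry,
                     nodesize = cfg$rf$nodesize, seed = seeds[i])
  }
  regions <- vapply(study, `[[`, character(1), "region")
  names(regions) <- vapply(study, `[[`, character(1), "country")
  wir <- wir_from_models(models, regions)
  reports <- run_all_designs(wir, alpha = cfg$alpha)
  if (write) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_wir_csv(wir, file.path(cfg$out_dir, "wir_table.csv"))
    write_reports(reports, cfg$out_dir)
  }
  list(study = study, models = models, wir = wir, reports = reports)
}

write_reports <- function(reports, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(kw_summary(reports), file.path(dir, "kw_summary.csv"),
            row.names = FALSE)
  write.csv(pairwise_summary(reports),
            file.path(dir, "dunn_pairwise.csv"), row.names = FALSE)
  jsonlite::write_json(kw_summary(reports),
                       file.path(dir, "kw_summary.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  txt <- character()
  for (r in reports) {
    if (is.null(r$dunn)) next
    txt <- c(txt, sprintf("design %s [%s]: chi-squared = %.3f, d.f. = %d, p = %.3g",
                          r$design, scope_string(r$scope),
                          r$kw$statistic, r$kw$df, r$kw$p.value),
             utils::capture.output(print(format_dunn_table(r),
                                         quote = FALSE)), "")
  }
  writeLines(txt, file.path(dir, "pairwise_tables.txt"))
  invisible(dir)
}

#' Re-analyse an external per-covariate importance table
#'
#' The comparison stage as a standalone entry point: reads a CSV with
#' columns `country,region,covariate,per_inc_mse` (one row per covariate
#' of each country's final model), standardizes covariate names into
#' variable classes, computes per-country WIR, and runs the global,
#' inter-regional and intra-regional designs, writing the pooled WIR
#' table, the KW summaries and the Holm-corrected pairwise tables.
#'
#' @param path importance CSV.
#' @param out_dir output directory (`NULL` for in-memory only).
#' @param alpha significance level for the KW gates.
#' @param aggregate see [run_design()].
#' @param map covariate class map.
#' @return list with `wir` and `reports`.
#' @export
reanalyze <- function(path, out_dir = NULL, alpha = 0.05,
                      aggregate = c("none", "country-median"),
                      map = default_class_map()) {
  aggregate <- match.arg(aggregate)
  imp <- read_importance_csv(path)
  wir <- assemble_study_table(imp, map = map)
  reports <- run_all_designs(wir, alpha = alpha, aggregate = aggregate)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_wir_csv(wir, file.path(out_dir, "wir_table.csv"))
    write_reports(reports, out_dir)
  }
  list(wir = wir, reports = reports)
}
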