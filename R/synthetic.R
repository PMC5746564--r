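#' Generate a synthetic country
#'
#' Builds the full test bundle for one country: the covariate stack, the
#' zone map, a true log-density surface
#' `log density = beta_0 + sum_k beta_k z(covariate_k) + eps`,
#' `eps ~ N(0, sigma^2)` i.i.d. per pixel (with `z()` the per-covariate
#' standardization to zero mean / unit variance over valid pixels,
#' categorical covariates entering through their standardized level codes),
#' and a census table obtained by zonal integration of the density surface
#' with half-to-even rounding to integer counts.  Deterministic given the
#' spec seed.
#'
#' @param spec a [landscape_spec()].
#' @param country,region labels attached to the census table.
#' @return an object of class `synthetic_country` with fields `stack`,
#'   `zones`, `census` (columns `unit_id,count,region,country`),
#'   `true_log_density`, `asr_km` (square root of the mean zone area, the
#'   average spatial resolution of the census geography), `region`,
#'   `country` and `spec`.
#' @export
generate_country <- function(spec, country = "country_1", region = "region_1") {
  stopifnot(inherits(spec, "landscape_spec"))
  stack <- generate_covariate_stack(spec)
  if (!any(stack$mask)) stop_config("all-nodata grid: cannot generate a country")
  zones <- partition_zones(spec)
  set.seed(spec_seeds(spec)[4L])
  valid <- which(stack$mask)
  tld <- matrix(NA_real_, spec$grid_rows, spec$grid_cols)
  lin <- rep(spec$intercept, length(valid))
  for (nm in names(stack$grids)) {
    v <- stack$grids[[nm]][valid]
    s <- sd(v)
    z <- if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
    lin <- lin + spec$effect_weights[[nm]] * z
  }
  if (spec$noise_sd > 0) lin <- lin + rnorm(length(valid), 0, spec$noise_sd)
  tld[valid] <- lin
  pixel_pop <- exp(tld) * spec$pixel_area
  zs <- zonal_sum(pixel_pop, zones)
  census <- data.frame(unit_id = as.integer(names(zs)),
                       count = round(zs),  # round() is half-to-even
                       region = region, country = country,
                       row.names = NULL)
  census <- census[order(census$unit_id), ]
  rownames(census) <- NULL
  asr_km <- sqrt(length(valid) * spec$pixel_area / spec$n_zones)
  structure(list(stack = stack, zones = zones, census = census,
                 true_log_density = tld, asr_km = asr_km,
                 region = region, country = country, spec = spec),
            class = "synthetic_country")
}

#' @export
print.synthetic_country <- function(x, ...) {
  cat(sprintf("synthetic_country '%s' (%s): %d zones, %d x %d px, %s people, ASR %.3g km\n",
              x$country, x$region, nrow(x$census), x$spec$grid_rows,
              x$spec$grid_cols, format(sum(x$census$count), big.mark = ","),
              x$asr_km))
  invisible(x)
}

# per-zone sum of a pixel grid (NA pixels outside zones ignored)
zonal_sum <- function(m, zones) {
  ok <- !is.na(zones) & !is.na(m)
  vapply(split(m[ok], zones[ok]), sum, numeric(1))
}

#' Generate a multi-country, multi-region synthetic study
#'
#' Emulates a regional study design (e.g. 4 regions x 8 countries): each
#' country gets its own spec derived from the template by redrawing the
#' seed and applying the perturbation rules, with region labels attached.
#' Deterministic given `seed`.
#'
#' @param n_countries_per_region named integer vector, region label ->
#'   number of countries.
#' @param template a [landscape_spec()] used for every country.
#' @param perturb list of perturbation rules:
#'   * `beta_sd`: log-normal multiplicative jitter applied per country to
#'     every nonzero effect weight (0 = coefficients identical across
#'     countries, the exchangeable null);
#'   * `region_beta_mult`: named list, region -> named multipliers applied
#'     to selected effect weights (plants inter-regional differences);
#'   * `n_zones_jitter`: +/- range of a uniform integer jitter on the
#'     number of zones.
#' @param seed master seed.
#' @return list of [generate_country()] objects.
#' @export
generate_study <- function(n_countries_per_region, template,
                           perturb = list(), seed = 1L) {
  if (length(n_countries_per_region) < 1L ||
      is.null(names(n_countries_per_region)))
    stop_config("n_countries_per_region must be a named vector with >= 1 region")
  stopifnot(inherits(template, "landscape_spec"))
  beta_sd <- perturb$beta_sd %||% 0
  rmult <- perturb$region_beta_mult %||% list()
  zj <- perturb$n_zones_jitter %||% 0L
  set.seed(seed)
  out <- list()
  for (region in names(n_countries_per_region)) {
    for (i in seq_len(n_countries_per_region[[region]])) {
      sp <- template
      sp$seed <- sample.int(.seed_max, 1L)
      if (beta_sd > 0)
        sp$effect_weights <- sp$effect_weights *
          exp(rnorm(length(sp$effect_weights), 0, beta_sd))
      if (!is.null(rmult[[region]])) {
        m <- rmult[[region]]
        sp$effect_weights[names(m)] <- sp$effect_weights[names(m)] * m
      }
      if (zj > 0)
        sp$n_zones <- max(1L, sp$n_zones + sample(-zj:zj, 1L))
      country <- sprintf("%s_c%02d", region, i)
      out[[country]] <- generate_country(sp, country = country,
                                         region = region)
    }
  }
  out
}

#' Write a synthetic country bundle to disk
#'
#' Grids go out as ESRI ASCII rasters (covariates and true log density as
#' floating point, zones as integers) and the census as CSV with columns
#' `unit_id,count,region,country`.
#'
#' @param country a `synthetic_country`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_country <- function(country, dir) {
  stopifnot(inherits(country, "synthetic_country"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cs <- sqrt(country$stack$pixel_area) * 1000  # metres
  for (nm in names(country$stack$grids))
    write_ascii_grid(country$stack$grids[[nm]],
                     file.path(dir, paste0(nm, ".asc")), cellsize = cs)
  write_ascii_grid(country$zones, file.path(dir, "zones.asc"), cellsize = cs)
  write_ascii_grid(country$true_log_density,
                   file.path(dir, "true_log_density.asc"), cellsize = cs)
  write.csv(country$census, file.path(dir, "census.csv"), row.names = FALSE)
  invisible(dir)
}
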