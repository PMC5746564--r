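#' Packaged study designs
#'
#' Three ready-made landscape specifications used throughout the examples
#' and tests:
#'
#' * `landscape_demo()` — the demo country: 40 x 40 pixels, 150 zones,
#'   8 covariates of mixed kinds, three of them drivers of the density
#'   surface (night-time lights, an urban extent, elevation) plus weaker
#'   secondary effects.
#' * `landscape_recovery()` — the structure-recovery benchmark: 60 x 60
#'   pixels, 300 zones, 3 planted drivers (`lights_at_night`,
#'   `urban_extent`, `elevation`) and 7 zero-coefficient noise covariates;
#'   used to check that iterative selection keeps the planted drivers on
#'   top of the importance ranking.
#' * `landscape_null()` — the calibration landscape: 20 x 20 pixels,
#'   40 zones, 5 covariates with modest coefficients; used with
#'   [study_null()] where every region shares identical coefficients, so
#'   inter-regional tests should reject at about the nominal rate.
#'
#' Intercepts are on the log persons-per-km^2 scale (7 ~ 1100 /km^2,
#' typical of densely settled census units); pixels are 0.01 km^2 (100 m
#' analog).
#'
#' @param seed integer seed.
#' @return a [landscape_spec()].
#' @export
landscape_demo <- function(seed = 1L) {
  landscape_spec(
    grid_rows = 40, grid_cols = 40, n_zones = 150,
    covariates = list(
      covariate_def("lights_at_night", "smooth-field"),
      covariate_def("urban_extent", "binary-extent", coverage = 0.12),
      covariate_def("elevation", "smooth-field", smoothness = 6),
      covariate_def("slope", "derived-gradient", source = "elevation"),
      covariate_def("dist_roads", "distance-to-feature", n_features = 3),
      covariate_def("dist_water", "distance-to-feature", n_features = 2),
      covariate_def("cultivated", "binary-extent", coverage = 0.3),
      covariate_def("vegetation", "binary-extent", coverage = 0.4)),
    effect_weights = c(lights_at_night = 1.2, urban_extent = 1.0,
                       elevation = -0.7, dist_roads = -0.5,
                       dist_water = -0.2, cultivated = 0.3),
    intercept = 7, noise_sd = 0.25, seed = seed)
}

#' @rdname landscape_demo
#' @export
landscape_recovery <- function(seed = 1L) {
  landscape_spec(
    grid_rows = 60, grid_cols = 60, n_zones = 300,
    covariates = list(
      covariate_def("lights_at_night", "smooth-field"),
      covariate_def("urban_extent", "binary-extent", coverage = 0.12),
      covariate_def("elevation", "smooth-field", smoothness = 6),
      covariate_def("slope", "derived-gradient"),
      covariate_def("dist_roads", "distance-to-feature", n_features = 3),
      covariate_def("dist_water", "distance-to-feature", n_features = 2),
      covariate_def("cultivated", "binary-extent", coverage = 0.3),
      covariate_def("vegetation", "binary-extent", coverage = 0.4),
      covariate_def("precipitation", "smooth-field", smoothness = 8),
      covariate_def("dist_schools", "distance-to-feature",
                    n_features = 5)),
    effect_weights = c(lights_at_night = 1.2, urban_extent = 1.0,
                       elevation = -0.8),
    intercept = 7, noise_sd = 0.2, seed = seed)
}

#' @rdname landscape_demo
#' @export
landscape_null <- function(seed = 1L) {
  landscape_spec(
    grid_rows = 20, grid_cols = 20, n_zones = 40,
    covariates = list(
      covariate_def("urban_extent", "binary-extent", coverage = 0.15),
      covariate_def("dist_roads", "distance-to-feature", n_features = 2),
      covariate_def("elevation", "smooth-field", smoothness = 3),
      covariate_def("dist_water", "distance-to-feature", n_features = 1),
      covariate_def("vegetation", "binary-extent", coverage = 0.35),
      covariate_def("precipitation", "smooth-field", smoothness = 5),
      covariate_def("cultivated", "binary-extent", coverage = 0.3),
      covariate_def("dist_schools", "distance-to-feature",
                    n_features = 3)),
    effect_weights = c(urban_extent = 0.8, dist_roads = -0.5,
                       elevation = -0.4, dist_water = -0.3,
                       vegetation = 0.2, precipitation = -0.2,
                       cultivated = 0.3, dist_schools = -0.2),
    intercept = 7, noise_sd = 0.3, seed = seed)
}

#' Packaged multi-country studies
#'
#' `study_demo()` is the end-to-end demonstration study (4 regions x 3
#' countries on [landscape_demo()], mild between-country coefficient
#' jitter).  `study_null()` is the exchangeable-null study (4 regions x 8
#' countries on [landscape_null()], identical coefficients everywhere),
#' matching the 32-country / 4-region design of the comparative analysis
#' it emulates.
#'
#' @param seed master seed.
#' @param n_countries countries per region.
#' @param region_beta_mult optional named list region -> named coefficient
#'   multipliers (plants an inter-regional difference; see
#'   [generate_study()]).
#' @return list of `synthetic_country` bundles.
#' @export
study_demo <- function(seed = 1L, n_countries = 3) {
  generate_study(
    stats::setNames(rep(n_countries, 4),
                    c("region_A", "region_B", "region_C", "region_D")),
    landscape_demo(),
    perturb = list(beta_sd = 0.1, n_zones_jitter = 10L),
    seed = seed)
}

#' @rdname study_demo
#' @export
study_null <- function(seed = 1L, n_countries = 8,
                       region_beta_mult = NULL) {
  generate_study(
    stats::setNames(rep(n_countries, 4),
                    c("region_A", "region_B", "region_C", "region_D")),
    landscape_null(),
    perturb = list(beta_sd = 0,
                   region_beta_mult = region_beta_mult),
    seed = seed)
}
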