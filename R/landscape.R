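#' Covariate definition for the synthetic landscape generator
#'
#' Describes one synthetic covariate grid.  Kinds mirror the usual
#' geospatial predictor families used in dasymetric population modelling:
#' binary extents (e.g. urban masks), distances to linear features (roads,
#' rivers), smooth environmental fields (night-time light intensity,
#' elevation, precipitation), gradient magnitudes derived from a smooth
#' field (slope) and categorical surfaces (land cover).
#'
#' @param name covariate name; also used downstream for class standardization.
#' @param kind one of `"binary-extent"`, `"distance-to-feature"`,
#'   `"smooth-field"`, `"derived-gradient"`, `"categorical"`.
#' @param coverage fraction of valid pixels covered by a binary extent.
#' @param n_features number of random polyline features for
#'   distance-to-feature covariates.
#' @param smoothness Gaussian smoothing radius (pixels) of the underlying
#'   random field; `NULL` uses the landscape default.
#' @param source for `"derived-gradient"`, the name of the smooth-field
#'   covariate to differentiate; `NULL` draws a private latent field.
#' @param n_levels number of classes for categorical covariates.
#' @export
covariate_def <- function(name,
                          kind = c("smooth-field", "binary-extent",
                                   "distance-to-feature", "derived-gradient",
                                   "categorical"),
                          coverage = 0.15, n_features = 3, smoothness = NULL,
                          source = NULL, n_levels = 4) {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_config("covariate 'name' must be a non-empty string")
  structure(list(name = name, kind = kind, coverage = coverage,
                 n_features = n_features, smoothness = smoothness,
                 source = source, n_levels = n_levels),
            class = "covariate_def")
}

.known_kinds <- c("binary-extent", "distance-to-feature", "smooth-field",
                  "derived-gradient", "categorical")

#' Landscape specification for synthetic countries
#'
#' Defines the synthetic country used by [generate_country()]: grid size,
#' pixel area, number of admin zones, the covariate set and the
#' log-density-generating model
#' `log density = intercept + sum_k beta_k * z(covariate_k) + noise`,
#' where `z()` standardizes each covariate to zero mean and unit variance
#' over valid pixels and the noise is i.i.d. Gaussian on the log scale
#' (multiplicative on the density scale, keeping densities positive).
#'
#' @param grid_rows,grid_cols grid dimensions (pixels).
#' @param n_zones number of administrative zones (`>= 1`, at most the
#'   number of valid pixels).
#' @param covariates list of [covariate_def()] objects.
#' @param effect_weights named numeric vector of coefficients `beta_k`;
#'   every name must match a covariate.  Covariates without an entry get
#'   `beta = 0`.
#' @param intercept intercept `beta_0` on the log-density scale
#'   (`log` persons per km^2).
#' @param noise_sd standard deviation of the log-scale noise (`>= 0`).
#' @param pixel_area pixel area in km^2 (default `0.01`, a 100 m analog).
#' @param nodata_frac fraction of the grid masked out as nodata
#'   (contiguous blob, e.g. water body); 0 disables.
#' @param smoothness default Gaussian smoothing radius (pixels) for random
#'   fields.
#' @param seed integer RNG seed; the whole bundle is deterministic given it.
#' @return an object of class `landscape_spec`.
#' @export
landscape_spec <- function(grid_rows, grid_cols, n_zones, covariates,
                           effect_weights = numeric(), intercept = 7,
                           noise_sd = 0.25, pixel_area = 0.01,
                           nodata_frac = 0, smoothness = 4, seed = 1L) {
  if (grid_rows < 1 || grid_cols < 1) stop_config("grid dimensions must be positive")
  if (n_zones < 1 || n_zones > grid_rows * grid_cols)
    stop_config("n_zones must be in [1, grid_rows * grid_cols]")
  if (noise_sd < 0) stop_config("noise_sd must be >= 0")
  if (pixel_area <= 0) stop_config("pixel_area must be > 0")
  if (inherits(covariates, "covariate_def")) covariates <- list(covariates)
  nm <- vapply(covariates, function(cv) cv$name, character(1))
  if (anyDuplicated(nm)) stop_config("duplicate covariate names")
  kinds <- vapply(covariates, function(cv) cv$kind, character(1))
  if (!all(kinds %in% .known_kinds))
    stop_config("unknown covariate kind: ",
                paste(setdiff(kinds, .known_kinds), collapse = ", "))
  if (length(effect_weights) &&
      (is.null(names(effect_weights)) ||
       !all(names(effect_weights) %in% nm)))
    stop_config("every effect_weights name must match a covariate")
  beta <- stats::setNames(numeric(length(nm)), nm)
  beta[names(effect_weights)] <- effect_weights
  names(covariates) <- nm
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 n_zones = as.integer(n_zones), covariates = covariates,
                 effect_weights = beta, intercept = intercept,
                 noise_sd = noise_sd, pixel_area = pixel_area,
                 nodata_frac = nodata_frac, smoothness = smoothness,
                 seed = as.integer(seed)),
            class = "landscape_spec")
}

#' @export
print.landscape_spec <- function(x, ...) {
  cat(sprintf("landscape_spec: %d x %d pixels, %d zones, %d covariates, sigma = %.3g, seed = %d\n",
              x$grid_rows, x$grid_cols, x$n_zones, length(x$covariates),
              x$noise_sd, x$seed))
  invisible(x)
}

# fixed fan-out of the spec seed: [1] nodata mask, [2] covariate grids,
# [3] zone partition, [4] log-density noise
spec_seeds <- function(spec) derive_seeds(spec$seed, 4L)

# Gaussian blur of a matrix via row/column band-weight matrices (exact
# separable kernel with edge renormalization); grids are small enough that
# the O(n^3) products are negligible.
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  band <- function(n) {
    w <- dnorm(abs(outer(seq_len(n), seq_len(n), "-")), sd = sigma)
    w / rowSums(w)
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

smooth_field <- function(nr, nc, sigma) {
  gauss_smooth(matrix(rnorm(nr * nc), nr, nc), sigma)
}

# random-walk polylines rasterized onto the grid, then a Euclidean
# distance transform (km)
distance_feature_grid <- function(nr, nc, n_features, cell_km) {
  feat <- matrix(FALSE, nr, nc)
  len <- round(0.5 * (nr + nc))
  for (f in seq_len(n_features)) {
    r <- sample.int(nr, 1L)
    c <- sample.int(nc, 1L)
    for (s in seq_len(len)) {
      feat[r, c] <- TRUE
      r <- min(max(r + sample(-1:1, 1L), 1L), nr)
      c <- min(max(c + sample(-1:1, 1L), 1L), nc)
    }
  }
  feature_distance_cpp(feat) * cell_km
}

gen_nodata_mask <- function(spec) {
  nr <- spec$grid_rows; nc <- spec$grid_cols
  mask <- matrix(TRUE, nr, nc)
  if (spec$nodata_frac > 0) {
    set.seed(spec_seeds(spec)[1L])
    f <- smooth_field(nr, nc, spec$smoothness)
    mask <- f >= quantile(f, spec$nodata_frac)
  }
  mask
}

#' Generate the covariate stack of a synthetic country
#'
#' Realizes every covariate of the spec as a grid: binary extents are
#' thresholded smooth random fields (blob processes), distance covariates
#' are Euclidean distance transforms of randomly placed polyline features,
#' smooth fields are Gaussian-smoothed white noise, derived gradients are
#' gradient magnitudes of a named smooth field, categorical surfaces are
#' quantile-binned smooth fields.  Bit-identical for identical seeds.
#'
#' @param spec a [landscape_spec()].
#' @return a [covariate_stack()].
#' @export
generate_covariate_stack <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  nr <- spec$grid_rows; nc <- spec$grid_cols
  mask <- gen_nodata_mask(spec)
  set.seed(spec_seeds(spec)[2L])
  cell_km <- sqrt(spec$pixel_area)
  grids <- list(); kinds <- character(); levels <- list()
  fields <- list()  # smooth fields kept for derived gradients
  for (cv in spec$covariates) {
    sigma <- cv$smoothness %||% spec$smoothness
    g <- switch(cv$kind,
      "smooth-field" = {
        f <- smooth_field(nr, nc, sigma)
        fields[[cv$name]] <- f
        f
      },
      "binary-extent" = {
        f <- smooth_field(nr, nc, sigma)
        v <- f[mask]
        (f >= quantile(v, 1 - cv$coverage)) * 1
      },
      "distance-to-feature" =
        distance_feature_grid(nr, nc, cv$n_features, cell_km),
      "derived-gradient" = {
        src <- if (is.null(cv$source)) smooth_field(nr, nc, sigma)
               else fields[[cv$source]]
        if (is.null(src))
          stop_config("derived-gradient source '", cv$source,
                      "' is not an earlier smooth-field covariate")
        gx <- cbind(src[, 2L, drop = FALSE] - src[, 1L, drop = FALSE],
                    (src[, -(1:2), drop = FALSE] -
                       src[, seq_len(nc - 2L), drop = FALSE]) / 2,
                    src[, nc, drop = FALSE] - src[, nc - 1L, drop = FALSE])
        gy <- rbind(src[2L, , drop = FALSE] - src[1L, , drop = FALSE],
                    (src[-(1:2), , drop = FALSE] -
                       src[seq_len(nr - 2L), , drop = FALSE]) / 2,
                    src[nr, , drop = FALSE] - src[nr - 1L, , drop = FALSE])
        sqrt(gx^2 + gy^2)
      },
      "categorical" = {
        f <- smooth_field(nr, nc, sigma)
        qs <- quantile(f[mask], probs = seq_len(cv$n_levels - 1L) / cv$n_levels)
        g <- matrix(1L, nr, nc)
        for (q in qs) g <- g + (f > q)
        levels[[cv$name]] <- seq_len(cv$n_levels)
        g
      },
      stop_config("unknown covariate kind: ", cv$kind))
    grids[[cv$name]] <- g
    kinds[cv$name] <- switch(cv$kind, "binary-extent" = "binary",
                             "categorical" = "categorical", "continuous")
  }
  covariate_stack(grids, mask = mask, kinds = kinds, levels = levels,
                  pixel_area = spec$pixel_area)
}

#' Partition the grid into administrative zones
#'
#' Nearest-seed (Voronoi-on-grid) partition of the valid pixels into
#' exactly `n_zones` non-empty labels `1..n_zones`, giving irregular,
#' size-heterogeneous units resembling administrative boundaries.
#'
#' @param spec a [landscape_spec()].
#' @return a [zone_map()].
#' @export
partition_zones <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  mask <- gen_nodata_mask(spec)
  valid <- which(mask)
  if (spec$n_zones > length(valid))
    stop_config("n_zones exceeds the number of valid pixels")
  set.seed(spec_seeds(spec)[3L])
  seeds <- sample(valid, spec$n_zones)
  nr <- spec$grid_rows
  sr <- (seeds - 1L) %% nr + 1L
  sc <- (seeds - 1L) %/% nr + 1L
  pr <- (valid - 1L) %% nr + 1L
  pc <- (valid - 1L) %/% nr + 1L
  # squared Euclidean distance pixel x seed; ties break to the lowest label
  d2 <- outer(pr, sr, "-")^2 + outer(pc, sc, "-")^2
  lab <- max.col(-d2, ties.method = "first")
  z <- matrix(NA_integer_, nr, spec$grid_cols)
  z[valid] <- lab
  zone_map(z)
}
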