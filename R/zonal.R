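#' Zonal covariate summaries
#'
#' Aggregates the pixel-level covariate stack to the administrative-unit
#' level: continuous covariates by the mean over valid pixels, binary
#' covariates by the covered proportion, categorical covariates by the
#' per-level proportions (columns `name@level`).  Units with zero valid
#' pixels are dropped with a warning.
#'
#' @param stack a [covariate_stack()].
#' @param zones a [zone_map()] aligned to the stack.
#' @return data.frame with `unit_id`, `n_pixels` and one column per
#'   (expanded) covariate.
#' @export
zonal_summarize <- function(stack, zones) {
  stopifnot(inherits(stack, "covariate_stack"))
  if (!identical(dim(zones), c(stack$nrow, stack$ncol)))
    stop_config("stack and zone map are not aligned")
  zl <- sort(unique(zones[!is.na(zones)]))
  ok <- !is.na(zones) & stack$mask
  zf <- factor(zones[ok], levels = zl)
  npx <- as.integer(table(zf))
  out <- data.frame(unit_id = zl, n_pixels = npx)
  for (nm in names(stack$grids)) {
    v <- stack$grids[[nm]][ok]
    if (stack$kinds[[nm]] == "categorical") {
      for (lev in stack$levels[[nm]]) {
        out[[cat_col(nm, lev)]] <-
          as.numeric(tapply((v == lev) * 1, zf, mean))
      }
    } else {
      out[[nm]] <- as.numeric(tapply(v, zf, mean))
    }
  }
  empty <- out$n_pixels == 0L
  if (any(empty)) {
    warning(sprintf("dropping %d unit(s) with zero valid pixels: %s",
                    sum(empty), paste(out$unit_id[empty], collapse = ", ")))
    out <- out[!empty, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

cat_col <- function(name, level) paste0(name, "@", level)

# expanded feature-column names of a stack (shared by zonal and pixel views)
stack_feature_names <- function(stack) {
  unlist(lapply(names(stack$grids), function(nm) {
    if (stack$kinds[[nm]] == "categorical")
      cat_col(nm, stack$levels[[nm]])
    else nm
  }), use.names = FALSE)
}

# pixel-level design matrix over valid pixels for the requested (expanded)
# feature columns; categorical grids become one-hot indicators
pixel_design <- function(stack, features) {
  valid <- which(stack$mask)
  avail <- stack_feature_names(stack)
  missing <- setdiff(features, avail)
  if (length(missing))
    stop_config("stack is missing covariate grid(s): ",
                paste(missing, collapse = ", "))
  X <- matrix(NA_real_, length(valid), length(features),
              dimnames = list(NULL, features))
  for (f in features) {
    if (f %in% names(stack$grids)) {
      X[, f] <- stack$grids[[f]][valid]
    } else {
      base <- sub("@[^@]*$", "", f)
      lev <- as.integer(sub("^.*@", "", f))
      X[, f] <- (stack$grids[[base]][valid] == lev) * 1
    }
  }
  list(X = X, valid = valid)
}

#' Per-unit log population density response
#'
#' Density is `count / (pixel_area * n_pixels)` (persons per km^2); the
#' response is `log(density + density_floor)`, the floor keeping
#' zero-count units finite.
#'
#' @param census data.frame with at least `unit_id` and `count`.
#' @param zones a [zone_map()].
#' @param pixel_area pixel area in km^2.
#' @param density_floor additive density floor (km^-2) inside the log.
#' @param mask optional logical validity mask; zone pixels outside it do
#'   not count towards the unit area.
#' @return data.frame `unit_id, n_pixels, area_km2, density, response`.
#' @export
make_response <- function(census, zones, pixel_area, density_floor = 1e-8,
                          mask = NULL) {
  if (any(census$count < 0)) stop_config("negative census counts")
  zz <- zones
  if (!is.null(mask)) zz[!mask] <- NA_integer_
  npx <- table(factor(zz[!is.na(zz)], levels = census$unit_id))
  npx <- as.integer(npx)
  if (any(is.na(match(census$unit_id, unique(zz[!is.na(zz)])))) ||
      any(npx == 0L)) {
    drop <- census$unit_id[npx == 0L]
    if (length(drop) == nrow(census))
      stop_config("no census unit has any pixels in the zone map")
    warning(sprintf("dropping %d census unit(s) with zero pixels: %s",
                    length(drop), paste(drop, collapse = ", ")))
    keep <- npx > 0L
    census <- census[keep, , drop = FALSE]
    npx <- npx[keep]
  }
  area <- npx * pixel_area
  density <- census$count / area
  data.frame(unit_id = census$unit_id, n_pixels = npx, area_km2 = area,
             density = density, response = log(density + density_floor),
             row.names = NULL)
}

#' Admin-unit training table
#'
#' Joins the zonal covariate summaries with the log-density response into
#' the table the forest is trained on.
#'
#' @inheritParams zonal_summarize
#' @inheritParams make_response
#' @return a data.frame of class `zonal_table` with columns `unit_id`,
#'   `area_km2`, `response` and one column per covariate; the covariate
#'   column names are kept in `attr(, "covariates")`.
#' @export
zonal_table <- function(stack, zones, census, density_floor = 1e-8) {
  zs <- zonal_summarize(stack, zones)
  resp <- make_response(census, zones, stack$pixel_area,
                        density_floor = density_floor, mask = stack$mask)
  tab <- merge(resp[, c("unit_id", "area_km2", "response")], zs,
               by = "unit_id", sort = TRUE)
  covs <- setdiff(names(zs), c("unit_id", "n_pixels"))
  if (any(!is.finite(tab$response)))
    stop_config("non-finite response after flooring; check census counts")
  structure(tab, covariates = covs, pixel_area = stack$pixel_area,
            class = c("zonal_table", "data.frame"))
}
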