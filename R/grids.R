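#' Covariate stack
#'
#' A named set of aligned 2-D covariate grids sharing one nodata mask, the
#' pixel-level predictor container of the package.  Grids are numeric
#' matrices (row 1 = northern edge); invalid pixels are `NA` in every grid
#' and `FALSE` in the mask.
#'
#' @param grids named list of numeric matrices of identical dimension.
#' @param mask logical matrix, `TRUE` where pixels are valid; defaults to
#'   all pixels valid.
#' @param kinds named character vector giving the statistical kind of each
#'   grid: `"continuous"`, `"binary"` or `"categorical"`.  Binary grids are
#'   summarized as proportions, categorical grids are expanded into
#'   per-level indicators.
#' @param levels named list of integer level sets for categorical grids.
#' @param pixel_area area of one pixel in km^2.
#' @return an object of class `covariate_stack`.
#' @export
covariate_stack <- function(grids, mask = NULL, kinds = NULL, levels = NULL,
                            pixel_area = 0.01) {
  if (length(grids) == 0 || is.null(names(grids)) || any(names(grids) == ""))
    stop_config("'grids' must be a non-empty named list of matrices")
  dims <- lapply(grids, dim)
  if (length(unique(dims)) != 1L)
    stop_config("all covariate grids must share the same dimension")
  d <- dims[[1L]]
  if (is.null(mask)) mask <- matrix(TRUE, d[1L], d[2L])
  if (!identical(dim(mask), d))
    stop_config("mask dimension does not match the grids")
  if (is.null(kinds)) {
    kinds <- vapply(grids, function(g) {
      v <- g[mask]
      v <- v[!is.na(v)]
      if (length(v) && all(v %in% c(0, 1))) "binary" else "continuous"
    }, character(1))
  }
  kinds <- kinds[names(grids)]
  grids <- lapply(grids, function(g) { g[!mask] <- NA_real_; g })
  structure(list(grids = grids, mask = mask, kinds = kinds,
                 levels = levels %||% list(), pixel_area = pixel_area,
                 nrow = d[1L], ncol = d[2L]),
            class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  cat(sprintf("covariate_stack: %d grids, %d x %d pixels (%.0f%% valid), %.4g km^2/pixel\n",
              length(x$grids), x$nrow, x$ncol, 100 * mean(x$mask),
              x$pixel_area))
  cat("  covariates:", paste(sprintf("%s [%s]", names(x$grids), x$kinds),
                             collapse = ", "), "\n")
  invisible(x)
}

#' @export
names.covariate_stack <- function(x) names(x$grids)

#' Zone map
#'
#' Integer grid of administrative-unit labels `1..n_zones`; `NA` marks
#' nodata pixels.
#'
#' @param m integer matrix of zone labels (NA = nodata).
#' @return an object of class `zone_map`.
#' @export
zone_map <- function(m) {
  storage.mode(m) <- "integer"
  labs <- sort(unique(m[!is.na(m)]))
  if (length(labs) == 0L) stop_config("zone map contains no labelled pixels")
  structure(m, class = c("zone_map", "matrix"), n_zones = length(labs))
}

#' @export
print.zone_map <- function(x, ...) {
  cat(sprintf("zone_map: %d x %d pixels, %d zones\n",
              nrow(x), ncol(x), attr(x, "n_zones")))
  invisible(x)
}

#' Write a grid as an ESRI ASCII raster
#'
#' Plain-text single-band raster interchange (`ncols/nrows/xllcorner/...`
#' header followed by rows from the northern edge), readable by standard
#' GIS software.
#'
#' @param m numeric or integer matrix (row 1 = northern edge).
#' @param path output file path.
#' @param cellsize cell edge length (map units).
#' @param xll,yll lower-left corner coordinates.
#' @param nodata value written for `NA` cells.
#' @export
write_ascii_grid <- function(m, path, cellsize = 1, xll = 0, yll = 0,
                             nodata = -9999) {
  hdr <- c(sprintf("ncols %d", ncol(m)),
           sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.10g", xll),
           sprintf("yllcorner %.10g", yll),
           sprintf("cellsize %.10g", cellsize),
           sprintf("NODATA_value %.10g", nodata))
  mm <- m
  mm[is.na(mm)] <- nodata
  rows <- apply(mm, 1L, function(r) paste(format(r, trim = TRUE,
                                                 digits = 10),
                                          collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path file path.
#' @return numeric matrix with `NA` for nodata cells and attributes
#'   `cellsize`, `xll`, `yll`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  body <- lines[i:length(lines)]
  vals <- lapply(body, function(l)
    as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1L]]))
  m <- do.call(rbind, vals)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  if (nrow(m) != hdr$nrows || ncol(m) != hdr$ncols)
    stop("ASCII grid body does not match its header dimensions")
  attr(m, "cellsize") <- hdr$cellsize
  attr(m, "xll") <- hdr$xllcorner
  attr(m, "yll") <- hdr$yllcorner
  m
}
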