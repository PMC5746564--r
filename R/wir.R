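#' Covariate class map
#'
#' Ordered mapping from covariate-name patterns to the 18 standardized
#' variable classes (land-cover classes, land-use classes, urban extents
#' and proxies, populated places, transportation networks,
#' climatic/environmental, facilities and services, places and POIs,
#' water features, and a "no data" bookkeeping class).  Matching is
#' case-insensitive regular-expression search on whitespace-normalized
#' names; the first matching row wins, so more specific patterns come
#' first.  The map ships as an editable CSV (`pattern,class`) so users can
#' extend the synonym list.
#'
#' @param path CSV file with columns `pattern` and `class`; default: the
#'   map shipped with the package.
#' @return data.frame of class `class_map` with columns `pattern`, `class`.
#' @export
read_class_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "covariate_classes.csv",
                                package = "dasyrf")
  map <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("pattern", "class") %in% names(map)))
    stop_config("class map needs columns 'pattern' and 'class'")
  class(map) <- c("class_map", "data.frame")
  map
}

#' @rdname read_class_map
#' @export
default_class_map <- function() read_class_map()

#' The closed vocabulary of standardized variable classes
#'
#' @return character vector of the 18 class labels.
#' @export
variable_classes <- function() c(
  "natural/semi-natural vegetation land cover",
  "cultivated/managed land cover",
  "natural bare surfaces land cover",
  "artificial surface land cover",
  "no data",
  "residential land use",
  "non-residential land use",
  "protected land use",
  "general classified land use",
  "urban/suburban extents",
  "built environment and urban/suburban proxies",
  "classified populated place",
  "transportation networks",
  "climatic/environmental",
  "facilities and services",
  "places and POIs",
  "rivers/waterbodies/waterways",
  "populated place")

normalize_name <- function(x) {
  x <- tolower(x)
  x <- gsub("[._-]+", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Standardize covariate names into variable classes
#'
#' @param name character vector of covariate names.
#' @param map a class map from [read_class_map()].
#' @param warn warn about unmatched names (classified `"unclassified"`).
#' @return character vector of class labels.
#' @export
classify_covariate <- function(name, map = default_class_map(),
                               warn = TRUE) {
  if (any(!nzchar(name))) stop_config("empty covariate name")
  nn <- normalize_name(name)
  out <- rep("unclassified", length(nn))
  done <- logical(length(nn))
  for (i in seq_len(nrow(map))) {
    hit <- !done & grepl(map$pattern[i], nn, ignore.case = TRUE)
    out[hit] <- map$class[i]
    done <- done | hit
  }
  if (warn && any(!done))
    warning("unclassified covariate name(s): ",
            paste(unique(name[!done]), collapse = ", "))
  out
}

#' Weighted importance rank (WIR) for one country
#'
#' Ranks the country's covariates by descending Per.Inc.m.s.e. (rank 1 =
#' most important; ties get average ranks) and rescales the rank by the
#' number of covariates in the final model: `wir = (rank - 1) / (n - 1)`,
#' so the most important covariate scores 0 and the least important 1.  A
#' single-covariate model scores 0.
#'
#' @param importance an `importance_table` (or any data.frame with
#'   `covariate` and `per_inc_mse`).
#' @return the input with `rank` and `wir` columns appended.
#' @export
compute_wir <- function(importance) {
  imp <- as.data.frame(importance)
  if (!all(c("covariate", "per_inc_mse") %in% names(imp)))
    stop_config("importance table needs 'covariate' and 'per_inc_mse'")
  if (nrow(imp) < 1L) stop_config("empty importance table")
  if (any(is.na(imp$per_inc_mse)))
    stop_config("NaN/NA Per.Inc.m.s.e. in importance table")
  n <- nrow(imp)
  r <- rank(-imp$per_inc_mse, ties.method = "average")
  imp$rank <- r
  imp$wir <- if (n == 1L) 0 else (r - 1) / (n - 1)
  imp
}

#' Assemble the pooled study WIR table
#'
#' Concatenates per-country importance tables into one standardized table
#' with class labels and WIR attached.  Rows classified `"unclassified"`
#' or `"no data"` are retained but flagged `tested = FALSE` and excluded
#' from the hypothesis tests downstream.
#'
#' @param importances either a named list (country -> importance table)
#'   plus `regions`, or a single long data.frame with columns
#'   `country, region, covariate, per_inc_mse`.
#' @param regions named character vector, country -> region (only for the
#'   list form).
#' @param map class map, see [read_class_map()].
#' @return data.frame of class `wir_table` with columns
#'   `country, region, covariate, class, per_inc_mse, rank, wir, tested`.
#' @export
assemble_study_table <- function(importances, regions = NULL,
                                 map = default_class_map()) {
  if (is.data.frame(importances)) {
    need <- c("country", "region", "covariate", "per_inc_mse")
    if (!all(need %in% names(importances)))
      stop_config("long importance table needs columns ",
                  paste(need, collapse = ", "))
    long <- importances[, need]
  } else {
    if (is.null(names(importances)))
      stop_config("per-country importance list must be named by country")
    miss <- setdiff(names(importances), names(regions))
    if (length(miss))
      stop_config("country without region assignment: ",
                  paste(miss, collapse = ", "))
    long <- do.call(rbind, lapply(names(importances), function(cn) {
      imp <- as.data.frame(importances[[cn]])
      data.frame(country = cn, region = unname(regions[[cn]]),
                 covariate = imp$covariate,
                 per_inc_mse = imp$per_inc_mse)
    }))
  }
  if (any(is.na(long$region)) || any(!nzchar(long$region)))
    stop_config("country without region assignment")
  parts <- lapply(split(long, long$country), compute_wir)
  tab <- do.call(rbind, parts)
  rownames(tab) <- NULL
  tab$class <- classify_covariate(tab$covariate, map)
  tab$tested <- !(tab$class %in% c("unclassified", "no data"))
  tab <- tab[order(tab$region, tab$country, tab$rank),
             c("country", "region", "covariate", "class", "per_inc_mse",
               "rank", "wir", "tested")]
  rownames(tab) <- NULL
  class(tab) <- c("wir_table", "data.frame")
  tab
}

#' Build the study WIR table from fitted models
#'
#' Convenience wrapper: takes the per-country [pop_model()] fits of a
#' synthetic study and assembles the pooled WIR table from their final
#' importance tables.
#'
#' @param models named list (country -> `pop_model`).
#' @param regions named character vector, country -> region.
#' @inheritParams assemble_study_table
#' @return a `wir_table`.
#' @export
wir_from_models <- function(models, regions, map = default_class_map()) {
  assemble_study_table(lapply(models, `[[`, "importance"),
                       regions = regions, map = map)
}

#' Read / write WIR and importance tables as CSV
#'
#' `read_importance_csv()` reads a per-covariate importance table with
#' columns `country,region,covariate,per_inc_mse` (the supplementary-data
#' style interchange format); `write_wir_csv()` / `read_wir_csv()` round-
#' trip the assembled `wir_table`.
#'
#' @param path CSV path.
#' @export
read_importance_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("country", "region", "covariate", "per_inc_mse")
  if (!all(need %in% names(x)))
    stop_config("importance CSV needs columns ",
                paste(need, collapse = ","))
  if (!is.numeric(x$per_inc_mse))
    stop_config("per_inc_mse must be numeric")
  x[, need]
}

#' @rdname read_importance_csv
#' @param table a `wir_table`.
#' @export
write_wir_csv <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_importance_csv
#' @export
read_wir_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("country", "region", "covariate", "class", "per_inc_mse",
            "rank", "wir", "tested")
  if (!all(need %in% names(x)))
    stop_config("WIR CSV needs columns ", paste(need, collapse = ","))
  class(x) <- c("wir_table", "data.frame")
  x
}
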