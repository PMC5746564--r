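test_that("canonical covariate names map to their variable classes", {
  expect_identical(classify_covariate("lights at night imagery"),
                   "built environment and urban/suburban proxies")
  expect_identical(classify_covariate("elevation and slope"),
                   "climatic/environmental")
  expect_identical(classify_covariate("schools"),
                   "facilities and services")
  expect_identical(classify_covariate("LU residential"),
                   "residential land use")
  expect_identical(classify_covariate("LU industrial"),
                   "non-residential land use")
  expect_identical(classify_covariate("LC water"),
                   "rivers/waterbodies/waterways")
  expect_identical(classify_covariate("LC urban areas"),
                   "artificial surface land cover")
  expect_identical(classify_covariate("OSM POIs"), "places and POIs")
  expect_identical(classify_covariate("populated place gazetteer"),
                   "populated place")
  expect_identical(classify_covariate("city town village hierarchy"),
                   "classified populated place")
  # generator tags pass through the same map
  expect_identical(classify_covariate("lights_at_night"),
                   "built environment and urban/suburban proxies")
  expect_identical(classify_covariate("dist_roads"),
                   "transportation networks")
  expect_identical(classify_covariate("urban_extent"),
                   "urban/suburban extents")
  expect_true(all(classify_covariate(
    c("lights at night", "no data", "elevation")) %in%
      variable_classes()))
})

test_that("classification is total, deterministic and soft-fails", {
  expect_warning(cls <- classify_covariate("quux_frobnicator"),
                 "unclassified")
  expect_identical(cls, "unclassified")
  nm <- c("Lights At Night", "lights_at_night", "lights-at-night")
  expect_length(unique(classify_covariate(nm)), 1L)
})

test_that("WIR endpoints, midpoints and ties follow the rank rule", {
  imp <- data.frame(covariate = c("a", "b", "c"),
                    per_inc_mse = c(10, 5, 1))
  w <- compute_wir(imp)
  expect_equal(w$wir, c(0, 0.5, 1))
  expect_equal(w$rank, c(1, 2, 3))

  # single covariate
  w1 <- compute_wir(data.frame(covariate = "a", per_inc_mse = -3))
  expect_identical(w1$wir, 0)

  # average-rank ties
  wt <- compute_wir(data.frame(covariate = c("a", "b", "c"),
                               per_inc_mse = c(5, 5, 1)))
  expect_equal(wt$rank, c(1.5, 1.5, 3))
  expect_equal(wt$wir, c(0.25, 0.25, 1))

  expect_error(compute_wir(data.frame(covariate = "a",
                                      per_inc_mse = NaN)), "NaN")
})

test_that("wir is in [0,1] and decreasing in importance for random tables", {
  set.seed(40)
  for (r in 1:20) {
    n <- sample(2:12, 1)
    imp <- data.frame(covariate = paste0("c", seq_len(n)),
                      per_inc_mse = round(rnorm(n), sample(0:2, 1)))
    w <- compute_wir(imp)
    expect_true(all(w$wir >= 0 & w$wir <= 1))
    # endpoints are exact when the extreme value is not tied
    # (average ranks pull tied extremes inwards, e.g. {5,5,1})
    if (sum(imp$per_inc_mse == max(imp$per_inc_mse)) == 1)
      expect_equal(min(w$wir), 0)
    if (sum(imp$per_inc_mse == min(imp$per_inc_mse)) == 1 &&
        length(unique(imp$per_inc_mse)) > 1)
      expect_equal(max(w$wir), 1)
    o <- order(-w$per_inc_mse)
    expect_true(all(diff(w$wir[o]) >= 0))
  }
})

test_that("study tables pool countries with class labels and flags", {
  imps <- list(
    alpha = data.frame(covariate = c("lights_at_night", "dist_roads",
                                     "no_data"),
                       per_inc_mse = c(40, 10, 2)),
    beta = data.frame(covariate = c("elevation", "dist_water"),
                      per_inc_mse = c(20, -1)))
  tab <- assemble_study_table(imps,
                              regions = c(alpha = "west", beta = "east"))
  expect_s3_class(tab, "wir_table")
  expect_identical(nrow(tab), 5L)
  expect_setequal(unique(tab$region), c("west", "east"))
  expect_false(tab$tested[tab$covariate == "no_data"])
  # per-country minimum WIR is zero
  expect_equal(as.numeric(tapply(tab$wir, tab$country, min)), c(0, 0))
  expect_error(assemble_study_table(imps, regions = c(alpha = "west")),
               "region")
})

test_that("WIR tables survive a CSV round trip", {
  imps <- list(a = data.frame(covariate = c("x1", "x2"),
                              per_inc_mse = c(3.25, -0.5)))
  tab <- suppressWarnings(
    assemble_study_table(imps, regions = c(a = "r1")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_wir_csv(tab, path)
  back <- read_wir_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))
})
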