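test_that("a flat generating model yields the closed-form census", {
  # sigma = 0, all beta = 0: every pixel has density exp(b0)
  sp <- landscape_spec(6, 6, 4, covariate_def("a", "smooth-field"),
                       intercept = 5, noise_sd = 0, seed = 2)
  cty <- generate_country(sp)
  npx <- table(as.vector(cty$zones))
  expected <- round(exp(5) * sp$pixel_area * as.numeric(npx))
  expect_identical(as.numeric(cty$census$count), expected)
  expect_true(all(abs(cty$true_log_density - 5) < 1e-12, na.rm = TRUE))
})

test_that("a planted binary driver shifts log density by its standardized contrast", {
  sp <- landscape_spec(10, 10, 4,
                       covariate_def("urban", "binary-extent",
                                     coverage = 0.2),
                       effect_weights = c(urban = 2), intercept = 6,
                       noise_sd = 0, seed = 4)
  cty <- generate_country(sp)
  u <- cty$stack$grids$urban
  z <- (u - mean(u)) / sd(u)  # the generator's standardization
  gap_expected <- 2 * (max(z) - min(z))
  tld <- cty$true_log_density
  gap <- mean(tld[u == 1]) - mean(tld[u == 0])
  expect_equal(gap, gap_expected, tolerance = 1e-12)
})

test_that("census counts conserve the integrated density surface", {
  sp <- landscape_spec(15, 12, 9, list(
    covariate_def("lights", "smooth-field"),
    covariate_def("urban", "binary-extent")),
    effect_weights = c(lights = 1, urban = 0.5),
    noise_sd = 0.4, nodata_frac = 0.1, seed = 8)
  cty <- generate_country(sp)
  pix <- exp(cty$true_log_density) * sp$pixel_area
  for (i in seq_len(nrow(cty$census))) {
    zi <- cty$census$unit_id[i]
    expect_identical(cty$census$count[i],
                     round(sum(pix[which(cty$zones == zi)])))
  }
  expect_equal(sum(cty$census$count),
               sum(round(dasyrf:::zonal_sum(pix, cty$zones))))
  expect_gt(cty$asr_km, 0)
})

test_that("studies have the requested region structure and are reproducible", {
  tpl <- landscape_null()
  study <- generate_study(c(north = 2, south = 2), tpl, seed = 5)
  expect_length(study, 4L)
  expect_setequal(vapply(study, `[[`, "", "region"),
                  c("north", "south"))
  study2 <- generate_study(c(north = 2, south = 2), tpl, seed = 5)
  expect_identical(serialize(study, NULL), serialize(study2, NULL))
  # 4 regions x 8 countries, the full comparative design
  study32 <- study_null(seed = 1)
  expect_length(study32, 32L)
  expect_length(unique(vapply(study32, `[[`, "", "region")), 4L)
  expect_error(generate_study(integer(), tpl), "region")
})

test_that("region multipliers perturb only the targeted region", {
  study <- study_null(seed = 3, n_countries = 1,
                      region_beta_mult = list(
                        region_B = c(dist_water = 3)))
  betas <- lapply(study, function(cty) cty$spec$effect_weights)
  expect_equal(betas$region_B_c01[["dist_water"]],
               3 * betas$region_A_c01[["dist_water"]])
  expect_equal(betas$region_A_c01[["urban_extent"]],
               betas$region_C_c01[["urban_extent"]])
})

test_that("country bundles round-trip through the on-disk format", {
  dir <- withr::local_tempdir()
  cty <- generate_country(landscape_null(seed = 12))
  write_country(cty, dir)
  strip <- function(m) matrix(as.numeric(m), nrow(m))
  z <- read_ascii_grid(file.path(dir, "zones.asc"))
  expect_equal(strip(z), strip(cty$zones))
  expect_equal(attr(z, "cellsize"), 100)  # metres, the 100 m analog
  cen <- read.csv(file.path(dir, "census.csv"))
  expect_equal(cen$count, cty$census$count)
  g <- read_ascii_grid(file.path(dir, "elevation.asc"))
  expect_equal(strip(g), strip(cty$stack$grids$elevation),
               tolerance = 1e-9)
})
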