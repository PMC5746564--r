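test_that("binary-extent covariates are 0/1 blob masks", {
  sp <- landscape_spec(4, 4, 2,
                       covariate_def("urban", "binary-extent",
                                     coverage = 0.25),
                       seed = 3)
  st <- generate_covariate_stack(sp)
  v <- st$grids$urban[st$mask]
  expect_true(all(v %in% c(0, 1)))
  expect_identical(st$kinds[["urban"]], "binary")
})

test_that("distance to an everywhere-present feature is zero", {
  # a degenerate walk covering all pixels: emulate via the low-level
  # transform directly
  d <- dasyrf:::feature_distance_cpp(matrix(TRUE, 3, 3))
  expect_true(all(d == 0))
  # and no feature at all yields NA
  expect_true(all(is.na(dasyrf:::feature_distance_cpp(matrix(FALSE, 2, 2)))))
})

test_that("stack generation is bit-identical under one seed", {
  sp <- landscape_spec(12, 10, 5, list(
    covariate_def("lights", "smooth-field"),
    covariate_def("urban", "binary-extent"),
    covariate_def("dist_roads", "distance-to-feature"),
    covariate_def("slope", "derived-gradient"),
    covariate_def("landcover", "categorical", n_levels = 3)),
    seed = 11)
  expect_identical(serialize(generate_covariate_stack(sp), NULL),
                   serialize(generate_covariate_stack(sp), NULL))
})

test_that("unknown covariate kinds are rejected at spec time", {
  expect_error(covariate_def("x", "mystery-kind"), "arg")
  cd <- covariate_def("x", "smooth-field")
  cd$kind <- "mystery-kind"
  expect_error(landscape_spec(4, 4, 2, list(cd)), "unknown covariate kind")
})

test_that("effect weights must name existing covariates", {
  expect_error(
    landscape_spec(4, 4, 2, covariate_def("a", "smooth-field"),
                   effect_weights = c(b = 1)),
    "effect_weights")
})

test_that("zone partition covers the grid with the requested labels", {
  # single zone
  sp1 <- landscape_spec(3, 3, 1, covariate_def("a", "smooth-field"),
                        seed = 1)
  z1 <- partition_zones(sp1)
  expect_true(all(z1 == 1L))
  # every pixel its own zone
  sp4 <- landscape_spec(2, 2, 4, covariate_def("a", "smooth-field"),
                        seed = 1)
  z4 <- partition_zones(sp4)
  expect_setequal(as.vector(z4), 1:4)
  # 50 zones on 100 x 100: exactly 50 non-empty labels
  sp50 <- landscape_spec(100, 100, 50, covariate_def("a", "smooth-field"),
                         seed = 5)
  z50 <- partition_zones(sp50)
  counts <- table(as.vector(z50))
  expect_identical(sort(as.integer(names(counts))), 1:50)
  expect_true(all(counts >= 1L))
  # oversubscribed partitions fail
  expect_error(landscape_spec(2, 2, 5, covariate_def("a", "smooth-field")),
               "n_zones")
})

test_that("zone partitions are contiguous nearest-seed cells", {
  sp <- landscape_spec(30, 30, 12, covariate_def("a", "smooth-field"),
                       seed = 9)
  z <- partition_zones(sp)
  # each zone's pixels form one 8-connected component (discretized
  # Voronoi cells of a Euclidean metric are convex, hence connected)
  for (lab in 1:12) {
    px <- which(z == lab, arr.ind = TRUE)
    seen <- rep(FALSE, nrow(px))
    seen[1] <- TRUE
    frontier <- 1L
    while (length(frontier)) {
      nxt <- integer()
      for (f in frontier) {
        adj <- which(!seen &
                       pmax(abs(px[, 1] - px[f, 1]),
                            abs(px[, 2] - px[f, 2])) == 1)
        seen[adj] <- TRUE
        nxt <- c(nxt, adj)
      }
      frontier <- nxt
    }
    expect_true(all(seen), label = sprintf("zone %d contiguous", lab))
  }
})
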