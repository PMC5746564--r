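test_that("Kruskal-Wallis matches the hand-ranked example", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  kw <- kruskal_wallis(v, g)
  expect_equal(kw$statistic, 7.2, tolerance = 1e-12)
  expect_identical(kw$df, 2L)
})

test_that("identical groups give a null statistic", {
  kw <- kruskal_wallis(c(1, 2, 1, 2), rep(c("a", "b"), each = 2))
  expect_equal(kw$statistic, 0)
  # all values tied across groups
  kw0 <- kruskal_wallis(rep(5, 6), rep(c("a", "b"), 3))
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p.value, 1)
})

test_that("two-group H is the squared rank-sum z", {
  set.seed(15)
  for (r in 1:10) {
    v <- sample(100, 12)  # no ties
    g <- rep(c("a", "b"), times = c(5, 7))
    kw <- kruskal_wallis(v, g)
    n1 <- 5; n2 <- 7; N <- 12
    W <- sum(rank(v)[g == "a"])
    z <- (W - n1 * (N + 1) / 2) / sqrt(n1 * n2 * (N + 1) / 12)
    expect_equal(kw$statistic, z^2, tolerance = 1e-12)
  }
})

test_that("statistics agree with stats::kruskal.test under heavy ties", {
  set.seed(26)
  for (r in 1:25) {
    k <- sample(2:5, 1)
    sizes <- sample(2:8, k, replace = TRUE)
    v <- sample(1:4, sum(sizes), replace = TRUE)  # many ties
    g <- rep(seq_len(k), times = sizes)
    if (length(unique(v)) == 1) next
    kw <- kruskal_wallis(v, g)
    ref <- kruskal.test(v, factor(g))
    expect_equal(kw$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(kw$p.value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Dunn z matches the hand computation and is antisymmetric", {
  v <- 1:9
  g <- rep(c("a", "b", "c"), each = 3)
  d <- dunn_posthoc(v, g)
  expect_equal(d$Z["a", "c"], -6 / sqrt(5), tolerance = 1e-12)
  expect_equal(d$Z, -t(d$Z))
  # identical groups: all z zero, all corrected p 1
  d0 <- dunn_posthoc(c(1, 2, 1, 2, 1, 2),
                     rep(c("a", "b", "c"), each = 2))
  expect_true(all(d0$pairs$z == 0))
  expect_true(all(d0$pairs$p_holm == 1))
  expect_error(dunn_posthoc(1:3, rep("a", 3)), "two groups")
})

test_that("Holm follows the worked step-down and dominates Bonferroni", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(1, 4)), rep(1, 4))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(33)
  for (r in 1:20) {
    p <- runif(sample(1:8, 1))
    h <- holm_adjust(p)
    expect_equal(h, p.adjust(p, "holm"), tolerance = 1e-15)
    expect_true(all(h <= pmin(length(p) * p, 1) + 1e-15))
    expect_true(all(h >= p))
  }
})

test_that("KW and Dunn match brute force on enumerated integer samples", {
  size_sets <- list(c(2, 2, 2), c(1, 2, 3), c(3, 3), c(2, 4))
  for (sizes in size_sets) {
    g <- rep(seq_along(sizes), times = sizes)
    vals <- as.matrix(expand.grid(rep(list(1:3), sum(sizes))))
    for (i in seq_len(nrow(vals))) {
      v <- vals[i, ]
      kw <- kruskal_wallis(v, g)
      ref <- bf_kruskal(v, g)
      expect_equal(kw$statistic, ref$H, tolerance = 1e-12)
      expect_equal(kw$p.value, ref$p, tolerance = 1e-12)
      d <- dunn_posthoc(v, g)
      refd <- bf_dunn(v, g)
      expect_equal(d$pairs$z, refd$z, tolerance = 1e-12)
      expect_equal(d$pairs$p_holm, refd$p_holm, tolerance = 1e-12)
    }
  }
})

test_that("designs gate Dunn on the KW test and report untestable scopes", {
  tab <- suppressWarnings(assemble_study_table(
    list(a = data.frame(covariate = c("lights_at_night", "dist_roads"),
                        per_inc_mse = c(10, 1)),
         b = data.frame(covariate = c("lights_at_night", "dist_roads"),
                        per_inc_mse = c(9, 2))),
    regions = c(a = "west", b = "west")))
  # two classes, strongly separated but tiny n: KW may or may not gate
  rep1 <- run_design(tab, "global-by-class", alpha = 1e-9)
  expect_null(rep1$dunn)  # gate closed at an absurdly small alpha
  rep2 <- run_design(tab, "global-by-class", alpha = 0.99)
  expect_false(is.null(rep2$dunn))  # gate open at a permissive alpha
  # a single-region table is untestable between regions
  rep3 <- run_design(tab, "inter-regional-by-region",
                     list(class = "transportation networks"))
  expect_true(rep3$untestable)
  expect_match(rep3$note, "fewer than two")
})

test_that("the full design hierarchy runs and summarizes", {
  set.seed(50)
  imps <- list()
  regions <- character()
  for (rg in c("north", "south")) {
    for (i in 1:3) {
      cn <- paste0(rg, i)
      imps[[cn]] <- data.frame(
        covariate = c("lights_at_night", "dist_roads", "elevation",
                      "dist_water"),
        per_inc_mse = rnorm(4, c(30, 10, 20, 2), 2))
      regions[cn] <- rg
    }
  }
  tab <- assemble_study_table(imps, regions = regions)
  reports <- run_all_designs(tab, alpha = 0.05)
  ks <- kw_summary(reports)
  expect_true("global-by-class" %in% ks$design)
  expect_true(all(table(ks$design)[c("inter-regional-by-region")] ==
                    length(unique(tab$class))))
  pw <- pairwise_summary(reports)
  if (nrow(pw)) expect_true(all(pw$p_holm >= pw$p_raw - 1e-15))
  # per-country medians switch collapses rows
  rep_med <- run_design(tab, "global-by-class",
                        aggregate = "country-median")
  expect_lte(rep_med$n, nrow(tab[tab$tested, ]))
})
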