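test_that("degenerate constant response is flagged, not NaN", {
  x <- data.frame(a = runif(20), b = runif(20))
  f <- fit_forest(x, rep(2, 20), ntree = 25, seed = 1)
  expect_equal(f$oob_mse, 0)
  expect_true(f$degenerate)
  expect_true(is.na(f$variance_explained))
  expect_message(variance_explained(f), "undefined")
})

test_that("an exact linear signal is explained almost entirely", {
  set.seed(42)
  for (s in c(11, 23, 37)) {
    set.seed(s)
    x <- data.frame(z = runif(200))
    f <- fit_forest(x, 3 * x$z, ntree = 500, seed = s)
    expect_gt(f$variance_explained, 80)
  }
})

test_that("pure noise has non-positive variance explained on average", {
  ve <- vapply(1:10, function(s) {
    set.seed(s)
    x <- data.frame(a = runif(60), b = runif(60))
    fit_forest(x, rnorm(60), ntree = 100, seed = s)$variance_explained
  }, numeric(1))
  expect_lt(mean(ve), 0)
})

test_that("variance explained is the stated ratio arithmetic", {
  x <- data.frame(a = runif(30))
  y <- rnorm(30)
  f <- fit_forest(x, y, ntree = 50, seed = 2)
  vy <- mean((y - mean(y))^2)
  expect_equal(f$variance_explained, 100 * (1 - f$oob_mse / vy))
  # oob_mse is the average of the per-tree OOB errors
  expect_equal(f$oob_mse, mean(f$tree_oob_mse, na.rm = TRUE))
})

test_that("a covariate used by no tree has importance exactly zero", {
  # mtry = 1 with an overwhelming single predictor leaves the constant
  # covariate unused whenever it offers no valid split
  set.seed(1)
  x <- data.frame(signal = runif(40), flat = rep(1, 40))
  f <- fit_forest(x, 10 * x$signal, ntree = 60, mtry = 2, seed = 1)
  expect_false(any(f$var_used[, "flat"]))
  imp <- oob_permutation_importance(f, seed = 2)
  expect_identical(imp$per_inc_mse[imp$covariate == "flat"], 0)
  expect_identical(imp$n_trees_used[imp$covariate == "flat"], 0L)
})

test_that("planted covariates dominate noise covariates across seeds", {
  wins <- vapply(1:10, function(s) {
    set.seed(s)
    x <- data.frame(planted = runif(200), noise = runif(200))
    y <- 2 * x$planted + rnorm(200, 0, 0.2)
    f <- fit_forest(x, y, ntree = 150, seed = s)
    imp <- oob_permutation_importance(f, seed = s + 1000)
    imp$per_inc_mse[imp$covariate == "planted"] >
      imp$per_inc_mse[imp$covariate == "noise"]
  }, logical(1))
  expect_true(all(wins))
})

test_that("a duplicated response attains the maximum importance", {
  set.seed(7)
  x <- data.frame(a = runif(100), b = runif(100))
  y <- rnorm(100)
  x$oracle <- y
  f <- fit_forest(x, y, ntree = 200, seed = 7)
  imp <- oob_permutation_importance(f, seed = 8)
  expect_identical(imp$covariate[which.max(imp$per_inc_mse)], "oracle")
})

test_that("importance equals an exhaustive tree-by-tree recomputation", {
  # small forest, small sample: re-derive every per-tree OOB error and
  # permuted error with an independent R tree walk and the direct formula
  set.seed(5)
  x <- data.frame(u = runif(8), v = runif(8))
  y <- x$u + rnorm(8, 0, 0.3)
  f <- fit_forest(x, y, ntree = 3, nodesize = 5, seed = 5)
  imp <- oob_permutation_importance(f, seed = 6, detail = TRUE)
  det <- attr(imp, "detail")
  expect_false(is.null(det))
  for (cov in f$covariates) {
    rows <- det[det$covariate == cov, ]
    ratios <- numeric(0)
    if (nrow(rows)) {
      for (r in seq_len(nrow(rows))) {
        b <- rows$tree[r]
        oob <- which(f$inbag[, b] == 0L)
        Xo <- f$x[oob, , drop = FALSE]
        pb <- bf_predict_tree(f$trees[[b]], Xo)
        e_oob <- mean((f$y[oob] - pb)^2)
        expect_equal(e_oob, rows$e_oob[r], tolerance = 1e-12)
        Xp <- Xo
        Xp[, cov] <- Xo[rows$perm[[r]], cov]
        pp <- bf_predict_tree(f$trees[[b]], Xp)
        e_perm <- mean((f$y[oob] - pp)^2)
        expect_equal(e_perm, rows$e_perm[r], tolerance = 1e-12)
        ratios <- c(ratios, (e_perm - e_oob) / e_oob)
      }
    }
    expected <- if (length(ratios)) 100 * mean(ratios) else 0
    expect_equal(imp$per_inc_mse[imp$covariate == cov], expected,
                 tolerance = 1e-12)
  }
})

test_that("forest predictions agree with an independent implementation", {
  skip_if_not_installed("randomForest")
  set.seed(31)
  n <- 150
  x <- data.frame(a = runif(n), b = runif(n), c = runif(n))
  y <- sin(2 * pi * x$a) + 2 * x$b + rnorm(n, 0, 0.1)
  mine <- fit_forest(x, y, ntree = 300, seed = 31)
  ref <- randomForest::randomForest(x, y, ntree = 300)
  grid <- data.frame(a = runif(50), b = runif(50), c = runif(50))
  expect_gt(cor(predict(mine, grid), predict(ref, grid)), 0.97)
  # ensemble OOB predictions track the response comparably
  r2 <- function(pred) 1 - mean((y - pred)^2) / mean((y - mean(y))^2)
  expect_lt(abs(r2(mine$oob_pred) - r2(ref$predicted)), 0.1)
})

test_that("fitting fails fast on invalid inputs", {
  expect_error(fit_forest(data.frame(a = 1:3), 1:3, ntree = 10),
               "too few units")
  x <- data.frame(a = c(1, NA, 3, 4, 5, 6))
  expect_error(fit_forest(x, 1:6, ntree = 10), "missing values")
})
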