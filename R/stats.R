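#' Tie-corrected Kruskal-Wallis test
#'
#' Rank-based k-sample test on joint mid-ranks:
#' `H = [12/(N(N+1)) * sum_j R_j^2/n_j - 3(N+1)] / C` with the tie
#' correction `C = 1 - sum_t (t^3 - t) / (N^3 - N)`; the p-value comes
#' from the chi-squared approximation with `df = k - 1`.  When all values
#' are identical the statistic is defined as 0 (p = 1).
#'
#' @param values numeric vector of observations (here: WIR values).
#' @param groups grouping factor/vector of the same length.
#' @return object of class `kw_test`: `statistic` (H, labelled
#'   chi-squared in the report tables), `df`, `p.value`, `n`,
#'   `group_sizes`.
#' @export
kruskal_wallis <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  if (any(!is.finite(values))) stop_config("non-finite values")
  g <- factor(groups)
  sizes <- table(g)
  if (any(sizes == 0L)) {
    warning("dropping empty group(s): ",
            paste(names(sizes)[sizes == 0L], collapse = ", "))
    g <- droplevels(g)
    sizes <- table(g)
  }
  k <- nlevels(g)
  if (k < 2L) stop_config("need at least two non-empty groups")
  N <- length(values)
  if (N < 3L) stop_config("need at least 3 observations in total")
  r <- rank(values)  # mid-ranks
  Rj <- tapply(r, g, sum)
  H0 <- 12 / (N * (N + 1)) * sum(Rj^2 / as.numeric(sizes)) - 3 * (N + 1)
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- if (C == 0) 0 else H0 / C  # all values tied
  H <- max(H, 0)
  df <- k - 1L
  structure(list(statistic = H, df = df,
                 p.value = if (C == 0) 1 else pchisq(H, df,
                                                    lower.tail = FALSE),
                 n = N, group_sizes = as.integer(sizes),
                 groups = levels(g),
                 method = "Kruskal-Wallis rank sum test (tie-corrected)"),
            class = "kw_test")
}

#' @export
print.kw_test <- function(x, ...) {
  cat(sprintf("%s\n  chi-squared = %.4g, d.f. = %d, p = %.4g  (N = %d, k = %d)\n",
              x$method, x$statistic, x$df, x$p.value, x$n,
              length(x$groups)))
  invisible(x)
}

#' Post hoc Dunn test with Holm's correction
#'
#' Pairwise z-statistics on joint mid-ranks,
#' `Z_ij = (Rbar_i - Rbar_j) / sqrt[(N(N+1)/12 - sum_t(t^3-t)/(12(N-1)))
#' (1/n_i + 1/n_j)]`, with two-sided normal p-values and Holm's step-down
#' correction applied across all pairs of one test family.
#'
#' @inheritParams kruskal_wallis
#' @param alpha significance level recorded in the result.
#' @return object of class `dunn_test`: antisymmetric `Z` matrix and a
#'   `pairs` data.frame (`group_a, group_b, z, p_raw, p_holm`).
#' @export
dunn_posthoc <- function(values, groups, alpha = 0.05) {
  stopifnot(length(values) == length(groups))
  if (any(!is.finite(values))) stop_config("non-finite values")
  g <- droplevels(factor(groups))
  k <- nlevels(g)
  if (k < 2L) stop_config("Dunn test needs at least two groups")
  N <- length(values)
  r <- rank(values)
  Rbar <- tapply(r, g, mean)
  nj <- as.numeric(table(g))
  ties <- table(values)
  s2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  Z <- matrix(0, k, k, dimnames = list(levels(g), levels(g)))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      se <- sqrt(s2 * (1 / nj[i] + 1 / nj[j]))
      z <- if (se == 0) 0 else (Rbar[i] - Rbar[j]) / se
      Z[i, j] <- z
      Z[j, i] <- -z
    }
  }
  iu <- which(upper.tri(Z), arr.ind = TRUE)
  pairs <- data.frame(group_a = levels(g)[iu[, 1L]],
                      group_b = levels(g)[iu[, 2L]],
                      z = Z[iu], row.names = NULL)
  pairs$p_raw <- 2 * pnorm(-abs(pairs$z))
  pairs$p_holm <- holm_adjust(pairs$p_raw)
  structure(list(Z = Z, pairs = pairs, alpha = alpha,
                 groups = levels(g)),
            class = "dunn_test")
}

#' @export
print.dunn_test <- function(x, ...) {
  cat("Dunn post hoc test (Holm-corrected, two-sided):\n")
  print.data.frame(x$pairs, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Holm's step-down multiple-testing correction
#'
#' Sorts the p-values ascending, multiplies the i-th smallest by
#' `m - i + 1`, enforces monotonicity by a running maximum, caps at 1 and
#' returns the adjusted values in the input order.  Uniformly no less
#' powerful than Bonferroni.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
holm_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop_config("p-values must lie in [0, 1]")
  m <- length(p)
  if (m <= 1L) return(p)
  o <- order(p)
  adj <- pmin(cummax((m - seq_len(m) + 1) * p[o]), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Run one comparison design on a WIR table
#'
#' The four hierarchical designs on the pooled WIR table:
#' * `"global-by-class"` — all tested rows, grouped by variable class;
#' * `"inter-regional-by-region"` — rows of one class (`scope$class`),
#'   grouped by region;
#' * `"intra-regional-by-country"` — rows of one region and one class
#'   (`scope$region`, `scope$class`), grouped by country;
#' * `"intra-regional-by-class"` — rows of one region (`scope$region`),
#'   grouped by class.
#'
#' A Kruskal-Wallis test gates the analysis: the post hoc Dunn test (with
#' Holm's correction, at level `alpha`) is run only when the KW test is
#' significant.  Scopes with fewer than two non-empty groups (or fewer
#' than 3 observations) are reported as untestable rather than raising.
#' Rows flagged `tested = FALSE` ("unclassified", "no data") are excluded.
#'
#' @param table a `wir_table` from [assemble_study_table()].
#' @param design one of the four design tags.
#' @param scope list with `class` and/or `region` entries as required by
#'   the design (a bare string is accepted where one entry suffices).
#' @param alpha significance level for the KW gate.
#' @param aggregate `"none"` pools all covariate rows; `"country-median"`
#'   first collapses to one median WIR per country x class.
#' @return object of class `design_report`: `design`, `scope`, `kw`
#'   (a `kw_test` or `NULL`), `dunn` (a `dunn_test` or `NULL`),
#'   `untestable`, `note`.
#' @export
run_design <- function(table,
                       design = c("global-by-class",
                                  "inter-regional-by-region",
                                  "intra-regional-by-country",
                                  "intra-regional-by-class"),
                       scope = NULL, alpha = 0.05,
                       aggregate = c("none", "country-median")) {
  design <- match.arg(design)
  aggregate <- match.arg(aggregate)
  if (is.character(scope))
    scope <- switch(design,
                    "inter-regional-by-region" = list(class = scope),
                    "intra-regional-by-class" = list(region = scope),
                    stop_config("design '", design,
                                "' needs a list scope"))
  tab <- as.data.frame(table)
  tab <- tab[tab$tested, , drop = FALSE]
  if (!is.null(scope$class))
    tab <- tab[tab$class == scope$class, , drop = FALSE]
  if (!is.null(scope$region))
    tab <- tab[tab$region == scope$region, , drop = FALSE]
  need_scope <- switch(design,
                       "global-by-class" = character(),
                       "inter-regional-by-region" = "class",
                       "intra-regional-by-country" = c("region", "class"),
                       "intra-regional-by-class" = "region")
  if (!all(need_scope %in% names(scope)))
    stop_config("design '", design, "' needs scope entries: ",
                paste(need_scope, collapse = ", "))
  groups_by <- switch(design,
                      "global-by-class" = "class",
                      "inter-regional-by-region" = "region",
                      "intra-regional-by-country" = "country",
                      "intra-regional-by-class" = "class")
  if (aggregate == "country-median" && groups_by %in% c("class")) {
    agg <- stats::aggregate(wir ~ country + region + class, data = tab,
                            FUN = median)
    tab <- agg
  }
  rep0 <- structure(list(design = design, scope = scope, kw = NULL,
                         dunn = NULL, untestable = TRUE, alpha = alpha,
                         n = nrow(tab),
                         note = "fewer than two non-empty groups"),
                    class = "design_report")
  if (nrow(tab) < 3L) return(rep0)
  g <- factor(tab[[groups_by]])
  if (nlevels(droplevels(g)) < 2L) return(rep0)
  kw <- kruskal_wallis(tab$wir, g)
  dunn <- NULL
  if (kw$p.value < alpha) dunn <- dunn_posthoc(tab$wir, g, alpha = alpha)
  structure(list(design = design, scope = scope, kw = kw, dunn = dunn,
                 untestable = FALSE, alpha = alpha, n = nrow(tab),
                 note = if (is.null(dunn))
                   "KW not significant; Dunn not run" else ""),
            class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  sc <- if (length(x$scope))
    paste0(" [", paste(unlist(x$scope), collapse = " / "), "]") else ""
  cat(sprintf("design %s%s (n = %d)\n", x$design, sc, x$n))
  if (x$untestable) {
    cat("  untestable:", x$note, "\n")
  } else {
    print(x$kw)
    if (!is.null(x$dunn)) print(x$dunn) else cat(" ", x$note, "\n")
  }
  invisible(x)
}

#' Run the full hierarchy of comparison designs
#'
#' Global test across classes, inter-regional tests per class,
#' intra-regional between-class tests per region, and intra-regional
#' between-country tests per (region, class).
#'
#' @inheritParams run_design
#' @return object of class `design_report_set` (list of `design_report`).
#' @export
run_all_designs <- function(table, alpha = 0.05,
                            aggregate = c("none", "country-median")) {
  aggregate <- match.arg(aggregate)
  tab <- as.data.frame(table)
  tab <- tab[tab$tested, , drop = FALSE]
  classes <- sort(unique(tab$class))
  regions <- sort(unique(tab$region))
  reports <- list(run_design(table, "global-by-class", alpha = alpha,
                             aggregate = aggregate))
  for (cl in classes)
    reports[[length(reports) + 1L]] <-
      run_design(table, "inter-regional-by-region", list(class = cl),
                 alpha = alpha, aggregate = aggregate)
  for (rg in regions)
    reports[[length(reports) + 1L]] <-
      run_design(table, "intra-regional-by-class", list(region = rg),
                 alpha = alpha, aggregate = aggregate)
  for (rg in regions)
    for (cl in sort(unique(tab$class[tab$region == rg])))
      reports[[length(reports) + 1L]] <-
        run_design(table, "intra-regional-by-country",
                   list(region = rg, class = cl), alpha = alpha,
                   aggregate = aggregate)
  structure(reports, class = "design_report_set")
}

#' @export
print.design_report_set <- function(x, ...) {
  cat(sprintf("design_report_set: %d reports (%d testable, %d with Dunn follow-up)\n",
              length(x), sum(!vapply(x, `[[`, TRUE, "untestable")),
              sum(!vapply(x, function(r) is.null(r$dunn), TRUE))))
  invisible(x)
}

scope_string <- function(scope) {
  if (!length(scope)) "all" else paste(unlist(scope), collapse = " / ")
}

#' Tabulate design reports
#'
#' `kw_summary()` gives one row per design/scope with the KW statistic;
#' `pairwise_summary()` gives one row per Dunn pair
#' (`design,scope,group_a,group_b,z,p_raw,p_holm`).
#'
#' @param reports a `design_report_set`.
#' @export
kw_summary <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(design = r$design, scope = scope_string(r$scope),
               n = r$n,
               chi_squared = if (r$untestable) NA_real_ else r$kw$statistic,
               df = if (r$untestable) NA_integer_ else r$kw$df,
               p = if (r$untestable) NA_real_ else r$kw$p.value,
               significant = if (r$untestable) NA else
                 r$kw$p.value < r$alpha,
               untestable = r$untestable, row.names = NULL)
  }))
}

#' @rdname kw_summary
#' @export
pairwise_summary <- function(reports) {
  out <- lapply(reports, function(r) {
    if (is.null(r$dunn)) return(NULL)
    cbind(data.frame(design = r$design, scope = scope_string(r$scope)),
          r$dunn$pairs)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(design = character(), scope = character(),
                      group_a = character(), group_b = character(),
                      z = numeric(), p_raw = numeric(),
                      p_holm = numeric())
  out
}

#' Plain-text pairwise table of one report
#'
#' Formats a significant report's Dunn matrix as `|Z| (p_holm)` cells, the
#' familiar presentation of pairwise rank-test results.
#'
#' @param report a `design_report` with a Dunn follow-up.
#' @return character matrix (rows/columns = groups).
#' @export
format_dunn_table <- function(report) {
  stopifnot(inherits(report, "design_report"))
  if (is.null(report$dunn)) stop_config("report has no Dunn follow-up")
  Z <- report$dunn$Z
  k <- nrow(Z)
  P <- matrix(NA_real_, k, k, dimnames = dimnames(Z))
  for (i in seq_len(nrow(report$dunn$pairs))) {
    pr <- report$dunn$pairs[i, ]
    P[pr$group_a, pr$group_b] <- pr$p_holm
    P[pr$group_b, pr$group_a] <- pr$p_holm
  }
  out <- matrix("-", k, k, dimnames = dimnames(Z))
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j)
    out[i, j] <- sprintf("%.2f (%s)", abs(Z[i, j]),
                         ifelse(P[i, j] < 0.01, "<0.01",
                                sprintf("%.2f", P[i, j])))
  out
}
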