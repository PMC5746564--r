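# Brute-force oracles, written independently of the package internals:
# mid-ranks are built by explicit counting, the test statistics by direct
# transcription of their defining formulas, and tree predictions by a plain
# R walk over the stored node arrays.

bf_midranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n))
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  r
}

bf_kruskal <- function(values, groups) {
  g <- factor(groups)
  N <- length(values)
  r <- bf_midranks(values)
  H0 <- 0
  for (lev in levels(g)) {
    idx <- g == lev
    H0 <- H0 + sum(r[idx])^2 / sum(idx)
  }
  H0 <- 12 / (N * (N + 1)) * H0 - 3 * (N + 1)
  tie <- 0
  for (v in unique(values)) {
    t <- sum(values == v)
    tie <- tie + t^3 - t
  }
  C <- 1 - tie / (N^3 - N)
  if (C == 0) return(list(H = 0, df = nlevels(g) - 1, p = 1))
  H <- H0 / C
  list(H = H, df = nlevels(g) - 1,
       p = pchisq(H, nlevels(g) - 1, lower.tail = FALSE))
}

bf_dunn <- function(values, groups) {
  g <- factor(groups)
  k <- nlevels(g)
  N <- length(values)
  r <- bf_midranks(values)
  tie <- 0
  for (v in unique(values)) {
    t <- sum(values == v)
    tie <- tie + t^3 - t
  }
  s2 <- N * (N + 1) / 12 - tie / (12 * (N - 1))
  out <- NULL
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      a <- g == levels(g)[i]
      b <- g == levels(g)[j]
      se <- sqrt(s2 * (1 / sum(a) + 1 / sum(b)))
      z <- if (se == 0) 0 else (mean(r[a]) - mean(r[b])) / se
      out <- rbind(out, data.frame(group_a = levels(g)[i],
                                   group_b = levels(g)[j], z = z,
                                   p_raw = 2 * (1 - pnorm(abs(z)))))
    }
  }
  out$p_holm <- bf_holm(out$p_raw)
  out
}

bf_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  out <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    a <- min((m - i + 1) * p[ord[i]], 1)
    running <- max(running, a)
    out[ord[i]] <- running
  }
  out
}

# plain R walk through one stored tree (0-based node arrays)
bf_walk_tree <- function(tree, xrow) {
  nd <- 1L
  repeat {
    v <- tree$var[nd]
    if (v < 0L) return(tree$value[nd])
    nd <- if (xrow[v + 1L] <= tree$thr[nd]) tree$left[nd] + 1L
          else tree$right[nd] + 1L
  }
}

bf_predict_tree <- function(tree, X) {
  apply(X, 1L, function(xr) bf_walk_tree(tree, xr))
}

# small aligned stack/zones pair used across tests
toy_stack <- function(grids, ...) covariate_stack(grids, ...)

toy_zones <- function(m) zone_map(m)
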