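# Independent oracle implementations used to cross-check the package.
# Each is written from the mathematical definition, deliberately not sharing
# code paths with the package internals.

# ---- Mamdani FIS oracle ---------------------------------------------------
# Straight-loop implementation: trapezoid memberships evaluated pointwise,
# min-AND, clip, max-aggregate on the discretised consequent, centroid.
oracle_trap <- function(x, p) {
  a <- p[1]; b <- p[2]; cc <- p[3]; d <- p[4]
  if (x < a || x > d) return(0)
  if (x < b) return((x - a) / (b - a))           # b > a guaranteed when x in [a,b)
  if (x <= cc) return(1)
  (d - x) / (d - cc)
}

oracle_fis <- function(config, input) {
  na <- length(config$antecedents)
  input <- pmin(pmax(input, vapply(config$antecedents, function(v) v$universe[1], 0)),
                vapply(config$antecedents, function(v) v$universe[2], 0))
  cons <- config$consequent
  grid <- seq(cons$universe[1], cons$universe[2], by = config$resolution)
  agg <- rep(0, length(grid))
  for (r in config$rules) {
    s <- 1
    for (k in seq_len(na))
      s <- min(s, oracle_trap(input[k], config$antecedents[[k]]$mfs[[r[k]]]))
    if (s <= 0) next
    mf <- cons$mfs[[r[na + 1L]]]
    for (g in seq_along(grid))
      agg[g] <- max(agg[g], min(s, oracle_trap(grid[g], mf)))
  }
  if (all(agg == 0)) return(NA_real_)
  sum(grid * agg) / sum(agg)
}

# ---- Beta-binomial quadrature oracle --------------------------------------
# Posterior with a flat prior on a fine grid; MAP by argmax, equal-tailed
# interval by inverting the trapezoid-rule CDF.
oracle_binom_posterior <- function(k, n, level = 0.95, m = 200001L) {
  p <- seq(0, 1, length.out = m)
  logd <- k * log(p) + (n - k) * log1p(-p)
  logd[p == 0] <- if (k == 0) 0 else -Inf
  logd[p == 1] <- if (k == n) 0 else -Inf
  d <- exp(logd - max(logd, na.rm = TRUE))
  w <- diff(p)
  cdf <- c(0, cumsum((d[-1] + d[-m]) / 2 * w))
  cdf <- cdf / cdf[m]
  a <- (1 - level) / 2
  list(map = p[which.max(d)],
       ci_low = stats::approx(cdf, p, xout = a, ties = "ordered")$y,
       ci_high = stats::approx(cdf, p, xout = 1 - a, ties = "ordered")$y)
}

# Metropolis sampler for the same posterior (independent stochastic route).
oracle_binom_metropolis <- function(k, n, iters = 2e5, seed = 1) {
  set.seed(seed)
  logpost <- function(p) if (p <= 0 || p >= 1) -Inf else
    k * log(p) + (n - k) * log1p(-p)
  sd <- sqrt((k + 1) * (n - k + 1) / ((n + 2)^2 * (n + 3))) * 2.4
  x <- (k + 1) / (n + 2)
  lp <- logpost(x)
  out <- numeric(iters)
  for (i in seq_len(iters)) {
    cand <- x + stats::rnorm(1, 0, sd)
    lc <- logpost(cand)
    if (log(stats::runif(1)) < lc - lp) { x <- cand; lp <- lc }
    out[i] <- x
  }
  out[-seq_len(iters %/% 5)]
}

# ---- Vector Strahler oracle ------------------------------------------------
# Graph-based Strahler order on the mapped network: segments share nodes at
# coincident endpoints; orders propagate from the heads downstream.
oracle_vector_strahler <- function(network, outlet, tol = 1e-6) {
  geoms <- if (inherits(network, "dc_features")) network$geometry else network
  key <- function(pt) paste(round(pt[1] / tol), round(pt[2] / tol))
  ends <- lapply(geoms, function(g) c(key(g[1, ]), key(g[nrow(g), ])))
  nodes <- unique(unlist(ends))
  okey <- key(outlet)
  # orient each segment toward the outlet with a BFS over the node graph
  adj <- list()
  for (i in seq_along(ends)) {
    adj[[ends[[i]][1]]] <- c(adj[[ends[[i]][1]]], i)
    adj[[ends[[i]][2]]] <- c(adj[[ends[[i]][2]]], i)
  }
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[okey] <- 0
  queue <- okey
  while (length(queue)) {
    nd <- queue[1]; queue <- queue[-1]
    for (i in adj[[nd]]) {
      other <- setdiff(ends[[i]], nd)
      if (length(other) == 1 && dist[other] == Inf) {
        dist[other] <- dist[nd] + 1
        queue <- c(queue, other)
      }
    }
  }
  downstream_node <- vapply(ends, function(e)
    e[which.min(dist[e])], character(1))
  # topological pass: a segment's order is 1 at heads; at a junction the
  # Strahler rule applies over incoming segment orders
  ord <- rep(NA_integer_, length(geoms))
  repeat {
    progressed <- FALSE
    for (i in seq_along(geoms)) {
      if (!is.na(ord[i])) next
      upnode <- setdiff(ends[[i]], downstream_node[i])
      if (!length(upnode)) upnode <- ends[[i]][1]
      ins <- setdiff(adj[[upnode]], i)
      ins <- ins[downstream_node[ins] == upnode]
      if (!length(ins)) { ord[i] <- 1L; progressed <- TRUE; next }
      if (any(is.na(ord[ins]))) next
      mx <- max(ord[ins])
      ord[i] <- if (sum(ord[ins] == mx) >= 2L) mx + 1L else mx
      progressed <- TRUE
    }
    if (all(!is.na(ord))) break
    if (!progressed) stop("oracle: network graph is not orientable")
  }
  ord
}

# ---- misc -----------------------------------------------------------------
# tiny well-formed scenario for fast tests
small_scenario <- function(seed = 1, n = 96, tribs = 2, ...) {
  catchment_scenario(grid_shape = c(n, n), n_tributaries = tribs, seed = seed, ...)
}
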