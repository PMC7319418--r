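# Bayesian evaluation of model categories.
#
# For each category the number of "successes" (active reaches, or dammed
# active reaches) out of "trials" (reaches, or active reaches) is modelled
# binomially with a uniform prior. The posterior is then Beta(k+1, n-k+1)
# in closed form, so the Maximum A Posteriori estimate is exactly k/n and
# credible intervals are Beta quantiles — no sampler is needed (the closed
# form is exact for this model; tests cross-check it against a Metropolis
# sampler). Pairwise Bayes factors are summarised from the Monte-Carlo
# posterior distribution of the ratio of category probabilities.

#' Beta-binomial posterior summary for one category
#'
#' Uniform prior; posterior Beta(k+1, n-k+1); MAP = k/n; equal-tailed 95%
#' credible interval from Beta quantiles (highest-posterior-density interval
#' available via `interval = "hpd"`).
#' @param k successes (0 <= k <= n).
#' @param n trials (>= 1).
#' @param level credible level (default 0.95).
#' @param interval "equal-tailed" (default) or "hpd".
#' @return list(map, ci_low, ci_high, alpha, beta).
#' @export
fit_category_binomial <- function(k, n, level = 0.95, interval = c("equal-tailed", "hpd")) {
  interval <- match.arg(interval)
  if (n < 1) stop("n must be at least 1")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  a <- k + 1; b <- n - k + 1
  if (interval == "equal-tailed") {
    lo <- stats::qbeta((1 - level) / 2, a, b)
    hi <- stats::qbeta(1 - (1 - level) / 2, a, b)
  } else {
    # shortest interval containing `level` posterior mass
    f <- function(p) stats::qbeta(p + level, a, b) - stats::qbeta(p, a, b)
    opt <- stats::optimize(f, c(0, 1 - level))
    lo <- stats::qbeta(opt$minimum, a, b)
    hi <- stats::qbeta(opt$minimum + level, a, b)
  }
  list(map = k / n, ci_low = lo, ci_high = hi, alpha = a, beta = b)
}

#' Posterior summaries for a set of category counts
#' @param counts data.frame with columns `category`, `k`, `n`.
#' @param level credible level.
#' @param interval interval type, see [fit_category_binomial()].
#' @return data.frame category, k, n, map, ci_low, ci_high.
#' @export
fit_category_posteriors <- function(counts, level = 0.95,
                                    interval = "equal-tailed") {
  stopifnot(all(c("category", "k", "n") %in% names(counts)))
  res <- lapply(seq_len(nrow(counts)), function(i)
    fit_category_binomial(counts$k[i], counts$n[i], level, interval))
  data.frame(category = counts$category, k = counts$k, n = counts$n,
             map = vapply(res, `[[`, 0, "map"),
             ci_low = vapply(res, `[[`, 0, "ci_low"),
             ci_high = vapply(res, `[[`, 0, "ci_high"),
             stringsAsFactors = FALSE)
}

# mode of the posterior ratio p_i / p_j from Monte-Carlo draws: kernel
# density on the log-ratio scale (Silverman bandwidth), transformed back
# with the Jacobian 1/r
.ratio_map <- function(r) {
  lr <- log(r)
  d <- stats::density(lr, bw = "nrd0", n = 2048)
  fr <- d$y / exp(d$x)           # density of r at exp(d$x)
  exp(d$x[which.max(fr)])
}

#' Pairwise Bayes-factor matrix between category probabilities
#'
#' For each ordered pair (i, j) of categories, draws from the two Beta
#' posteriors, forms the ratio p_i / p_j, and reports the mode of its
#' kernel-density estimate (the MAP Bayes factor) with 2.5/97.5 percentile
#' bounds. Seeded and reproducible. A zero-success category in the
#' denominator is flagged: its upper bound is effectively unbounded.
#' @param posteriors data.frame from [fit_category_posteriors()] (needs
#'   columns category, k, n).
#' @param mc_draws Monte-Carlo draws per pair (>= 1e5).
#' @param seed RNG seed.
#' @return data.frame with numerator, denominator, map, ci_low, ci_high,
#'   unbounded (logical).
#' @export
bayes_factor_matrix <- function(posteriors, mc_draws = 1e5, seed = 1) {
  stopifnot(nrow(posteriors) >= 2L)
  if (mc_draws < 1e5) stop("mc_draws must be at least 1e5")
  cats <- posteriors$category
  with_seed(seed, {
    draws <- lapply(seq_len(nrow(posteriors)), function(i)
      stats::rbeta(mc_draws, posteriors$k[i] + 1,
                   posteriors$n[i] - posteriors$k[i] + 1))
    pairs <- expand.grid(i = seq_along(cats), j = seq_along(cats))
    pairs <- pairs[pairs$i != pairs$j, ]
    res <- lapply(seq_len(nrow(pairs)), function(p) {
      i <- pairs$i[p]; j <- pairs$j[p]
      r <- draws[[i]] / draws[[j]]
      q <- unname(stats::quantile(r, c(0.025, 0.975)))
      list(numerator = cats[i], denominator = cats[j],
           map = .ratio_map(r), ci_low = q[1], ci_high = q[2],
           unbounded = posteriors$k[j] == 0)
    })
    out <- do.call(rbind, lapply(res, as.data.frame))
    rownames(out) <- NULL
    out
  })
}

#' Render a Bayes-factor table as a lower-triangular matrix
#'
#' Rows/columns follow the category order of the posteriors; entries are
#' "MAP [lo, hi]" strings for pairs (row i vs column j, i > j).
#' @param bf output of [bayes_factor_matrix()].
#' @param categories category order.
#' @return character matrix.
#' @export
bayes_factor_table <- function(bf, categories) {
  m <- matrix("", length(categories), length(categories),
              dimnames = list(categories, categories))
  diag(m) <- "1"
  for (r in seq_len(nrow(bf))) {
    i <- match(bf$numerator[r], categories)
    j <- match(bf$denominator[r], categories)
    if (i > j)
      m[i, j] <- sprintf("%.2f [%.2f, %.2f]", bf$map[r], bf$ci_low[r], bf$ci_high[r])
  }
  m
}
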