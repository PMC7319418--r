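# Dam-count modelling: overdispersion diagnostics, zero-inflated negative
# binomial (ZINB) regression of observed dam counts on modelled maximum dams
# per reach, catchment-scale prediction with case-resampling bootstrap
# intervals, and train/test cross-validation across spatial scales.
#
# The ZINB (and the zero-inflated Poisson used for model comparison) are fit
# by direct maximum likelihood (optim/BFGS on the mixture log-likelihood with
# Wald inference from the numerical Hessian). The plain Poisson and negative
# binomial comparators come from stats::glm and MASS::glm.nb.

#' Cameron-Trivedi dispersion test
#'
#' Tests equidispersion (Var = mu) of a Poisson regression against the
#' quadratic alternative Var = mu + alpha * mu^2 via the auxiliary OLS
#' regression of ((y - mu)^2 - y) / mu on mu; one-sided (overdispersion)
#' p-value from the normal limit of the t statistic.
#' @param counts non-negative integer response.
#' @param covariate regressor of the Poisson mean model.
#' @return list(alpha, statistic, p_value, n).
#' @export
dispersion_test <- function(counts, covariate) {
  if (length(counts) < 30) stop("dispersion test needs at least 30 observations")
  if (all(counts == 0)) stop("all counts are zero")
  fit <- stats::glm(counts ~ covariate, family = stats::poisson())
  mu <- stats::fitted(fit)
  z <- ((counts - mu)^2 - counts) / mu
  aux <- stats::lm(z ~ 0 + mu)
  sm <- summary(aux)$coefficients
  stat <- sm[1, "t value"]
  list(alpha = unname(sm[1, "Estimate"]), statistic = unname(stat),
       p_value = stats::pnorm(stat, lower.tail = FALSE), n = length(counts))
}

## -- zero-inflated likelihoods ---------------------------------------------

# negative log-likelihood of the ZINB mixture; pars = (b0, b1, g0, g1, ltheta)
.zinb_nll <- function(pars, y, x, poisson = FALSE) {
  eta_mu <- pars[1] + pars[2] * x
  eta_pi <- pars[3] + pars[4] * x
  mu <- exp(pmin(eta_mu, 30))
  lp0 <- stats::plogis(eta_pi, log.p = TRUE)            # log pi
  lp1 <- stats::plogis(-eta_pi, log.p = TRUE)           # log(1 - pi)
  if (poisson) {
    ld <- stats::dpois(y, mu, log = TRUE)
  } else {
    theta <- exp(pars[5])
    ld <- stats::dnbinom(y, mu = mu, size = theta, log = TRUE)
  }
  z <- y == 0
  ll <- numeric(length(y))
  # y = 0: log(pi + (1-pi) f(0)) via log-sum-exp
  a <- lp0[z]; b <- lp1[z] + ld[z]
  m <- pmax(a, b)
  ll[z] <- m + log(exp(a - m) + exp(b - m))
  ll[!z] <- lp1[!z] + ld[!z]
  -sum(ll)
}

.fit_zi <- function(y, x, poisson = FALSE) {
  pois <- stats::glm(y ~ x, family = stats::poisson())
  p0 <- min(max(mean(y == 0), 0.05), 0.95)
  start <- c(stats::coef(pois), stats::qlogis(p0), 0)
  if (!poisson) start <- c(start, 0)
  npar <- length(start)
  fit <- stats::optim(start, .zinb_nll, y = y, x = x, poisson = poisson,
                      method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  if (fit$convergence != 0) {
    # polish from a Nelder-Mead pass
    nm <- stats::optim(start, .zinb_nll, y = y, x = x, poisson = poisson,
                       control = list(maxit = 2000))
    fit <- stats::optim(nm$par, .zinb_nll, y = y, x = x, poisson = poisson,
                        method = "BFGS", hessian = TRUE,
                        control = list(maxit = 500, reltol = 1e-12))
  }
  if (fit$convergence != 0) {
    # finite-difference gradient at the stalled point, for the error message
    gr <- vapply(seq_along(fit$par), function(k) {
      h <- 1e-6 * max(1, abs(fit$par[k]))
      pp <- fit$par; pp[k] <- pp[k] + h
      (.zinb_nll(pp, y, x, poisson) - fit$value) / h
    }, numeric(1))
    stop("zero-inflated fit did not converge (code ", fit$convergence,
         ", nll = ", signif(fit$value, 8),
         ", gradient = ", paste(signif(gr, 3), collapse = ", "), ")")
  }
  vc <- tryCatch(solve(fit$hessian), error = function(e) matrix(NA, npar, npar))
  se <- sqrt(pmax(diag(vc), 0))
  list(par = fit$par, se = se, vcov = vc, loglik = -fit$value,
       aic = 2 * fit$value + 2 * npar, npar = npar)
}

#' Fit the zero-inflated negative binomial dam-count model
#'
#' Maximum-likelihood ZINB with the modelled maximum dams per reach as the
#' covariate of both the count (log link) and the zero-inflation (logit
#' link) components, fitted on active reaches only. Poisson, negative
#' binomial and zero-inflated Poisson comparators are fitted alongside for
#' the AIC comparison table.
#' @param data data.frame with columns `observed_dams`, `max_dams` and
#'   logical `is_active` (only active rows are used; pass all-active data to
#'   use every row).
#' @param min_active minimum number of active reaches (default 50).
#' @return object of class `zinb_fit`: count/zero coefficients with Wald
#'   standard errors and p-values, dispersion theta, log-likelihood, AIC and
#'   an AIC `comparison` table over {Poisson, NB, ZIP, ZINB}.
#' @export
fit_zinb <- function(data, min_active = 50) {
  stopifnot(all(c("observed_dams", "max_dams") %in% names(data)))
  if ("is_active" %in% names(data)) data <- data[data$is_active, , drop = FALSE]
  y <- data$observed_dams; x <- data$max_dams
  if (length(y) < min_active)
    stop("need at least ", min_active, " active reaches (have ", length(y), ")")
  if (stats::var(x) == 0) stop("covariate does not vary")
  zinb <- .fit_zi(y, x, poisson = FALSE)
  zip <- .fit_zi(y, x, poisson = TRUE)
  pois <- stats::glm(y ~ x, family = stats::poisson())
  nb <- tryCatch(suppressWarnings(MASS::glm.nb(y ~ x)), error = function(e) NULL)
  if (any(zinb$se[3:4] > 25))
    warning("possible separation in the zero component (huge standard errors)")
  cf <- zinb$par
  est <- cf[1:4]
  se <- zinb$se[1:4]
  pz <- 2 * stats::pnorm(-abs(est / se))
  coefs <- data.frame(
    component = c("count", "count", "zero", "zero"),
    term = c("(Intercept)", "max_dams", "(Intercept)", "max_dams"),
    estimate = est, std_error = se, p_value = pz,
    stringsAsFactors = FALSE)
  comparison <- data.frame(
    model = c("Poisson", "NB", "ZIP", "ZINB"),
    df = c(2, 3, 4, 5),
    logLik = c(as.numeric(stats::logLik(pois)),
               if (is.null(nb)) NA else as.numeric(stats::logLik(nb)),
               zip$loglik, zinb$loglik),
    AIC = c(stats::AIC(pois),
            if (is.null(nb)) NA else stats::AIC(nb),
            zip$aic, zinb$aic),
    stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, theta = unname(exp(cf[5])),
                 log_theta_se = zinb$se[5], vcov = zinb$vcov,
                 loglik = zinb$loglik, aic = zinb$aic,
                 comparison = comparison, n = length(y),
                 data = data.frame(observed_dams = y, max_dams = x)),
            class = "zinb_fit")
}

#' @export
print.zinb_fit <- function(x, ...) {
  cat(sprintf("Zero-inflated negative binomial fit (n = %d active reaches)\n", x$n))
  print(x$coefficients, row.names = FALSE, digits = 4)
  cat(sprintf("theta = %.4g, logLik = %.3f, AIC = %.2f\n", x$theta, x$loglik, x$aic))
  cat("\nModel comparison (AIC):\n")
  print(x$comparison, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Predicted dams for reaches under a ZINB fit
#' @param object a `zinb_fit`.
#' @param newdata data.frame with `max_dams`.
#' @param ... unused.
#' @return data.frame with `pi` (structural-zero probability), `mu` (count
#'   mean) and `expected` = (1 - pi) * mu.
#' @export
predict.zinb_fit <- function(object, newdata, ...) {
  cf <- object$coefficients$estimate
  x <- newdata$max_dams
  mu <- exp(cf[1] + cf[2] * x)
  pi0 <- stats::plogis(cf[3] + cf[4] * x)
  data.frame(pi = pi0, mu = mu, expected = (1 - pi0) * mu)
}

#' Catchment-scale dam numbers with bootstrap intervals
#'
#' Expected dams per reach are (1 - pi) * mu under the assumption that every
#' reach is active; totals are summed by capacity category and overall.
#' Confidence intervals come from a case-resampling bootstrap of the active
#' reaches used in the fit: each replicate refits the ZINB and recomputes the
#' totals; percentile bounds are reported. Replicates that fail to converge
#' are dropped (error if more than 10% drop).
#' @param fit a `zinb_fit`.
#' @param reaches data.frame with `max_dams`, `category` and `length_m`.
#' @param bootstrap_reps bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param level confidence level (default 0.95).
#' @return list with `by_category` (data.frame category, expected_dams,
#'   ci_low, ci_high, pct), `total`, `total_ci`, `density_dpkm`,
#'   `density_ci`, `network_km`, `reps_used`.
#' @export
predict_catchment_dams <- function(fit, reaches, bootstrap_reps = 1000,
                                   seed = 1, level = 0.95) {
  stopifnot(inherits(fit, "zinb_fit"),
            all(c("max_dams", "category", "length_m") %in% names(reaches)))
  cats <- levels(factor(reaches$category))
  point <- predict(fit, reaches)$expected
  tot <- sum(point)
  by_cat <- tapply(point, factor(reaches$category, levels = cats), sum, default = 0)
  km <- sum(reaches$length_m) / 1000
  y <- fit$data$observed_dams; x <- fit$data$max_dams
  n <- length(y)
  boot_tot <- matrix(NA_real_, bootstrap_reps, 1 + length(cats))
  with_seed(seed, {
    for (r in seq_len(bootstrap_reps)) {
      idx <- sample.int(n, n, replace = TRUE)
      bf <- tryCatch(.fit_zi(y[idx], x[idx], poisson = FALSE),
                     error = function(e) NULL)
      if (is.null(bf)) next
      cf <- bf$par
      mu <- exp(cf[1] + cf[2] * reaches$max_dams)
      pi0 <- stats::plogis(cf[3] + cf[4] * reaches$max_dams)
      e <- (1 - pi0) * mu
      boot_tot[r, ] <- c(sum(e),
                         tapply(e, factor(reaches$category, levels = cats),
                                sum, default = 0))
    }
  })
  ok <- stats::complete.cases(boot_tot)
  if (mean(!ok) > 0.10)
    stop("more than 10% of bootstrap replicates failed to converge")
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- apply(boot_tot[ok, , drop = FALSE], 2, stats::quantile, probs = qs)
  by_category <- data.frame(
    category = cats,
    expected_dams = as.numeric(by_cat),
    ci_low = ci[1, -1], ci_high = ci[2, -1],
    pct = 100 * as.numeric(by_cat) / tot,
    stringsAsFactors = FALSE)
  list(by_category = by_category, total = tot,
       total_ci = unname(ci[, 1]),
       density_dpkm = tot / km,
       density_ci = unname(ci[, 1]) / km,
       network_km = km, reps_used = sum(ok))
}

#' Cross-validate the dam-count model across spatial scales
#'
#' Repeatedly splits active reaches into training (70%) and test subsets,
#' refits the ZINB on the training data, subsets the test data at every
#' percentile, and compares summed predictions with summed observations.
#' Pooled over all subset points, a zero-intercept regression of observed on
#' predicted sums, the RMSE and the MAE summarise performance.
#' @param data data.frame with `observed_dams`, `max_dams` (active reaches).
#' @param train_frac training fraction (default 0.7).
#' @param n_splits number of random splits (default 1000).
#' @param n_percentile_subsets subsets of the test set per split (default
#'   100, i.e. every percentile).
#' @param seed RNG seed.
#' @return list with `points` (data.frame predicted, observed), `slope`
#'   (zero-intercept regression), `rmse`, `mae`, `n_splits`.
#' @export
cross_validate <- function(data, train_frac = 0.7, n_splits = 1000,
                           n_percentile_subsets = 100, seed = 1) {
  y <- data$observed_dams; x <- data$max_dams
  n <- length(y)
  if (n < 100) stop("cross-validation needs at least 100 active reaches")
  pred <- obs <- list()
  with_seed(seed, {
    for (s in seq_len(n_splits)) {
      tr <- sample.int(n, round(train_frac * n))
      te <- setdiff(seq_len(n), tr)
      fit <- tryCatch(.fit_zi(y[tr], x[tr], poisson = FALSE),
                      error = function(e) NULL)
      if (is.null(fit)) next
      cf <- fit$par
      mu <- exp(cf[1] + cf[2] * x[te])
      pi0 <- stats::plogis(cf[3] + cf[4] * x[te])
      e <- (1 - pi0) * mu
      ps <- os <- numeric(0)
      for (p in seq_len(n_percentile_subsets)) {
        m <- round(p / n_percentile_subsets * length(te))
        if (m < 1) next
        pick <- sample.int(length(te), m)
        ps <- c(ps, sum(e[pick])); os <- c(os, sum(y[te][pick]))
      }
      pred[[length(pred) + 1L]] <- ps
      obs[[length(obs) + 1L]] <- os
    }
  })
  predicted <- unlist(pred); observed <- unlist(obs)
  if (!length(predicted)) stop("no usable cross-validation splits")
  slope <- sum(predicted * observed) / sum(predicted^2)
  err <- predicted - observed
  list(points = data.frame(predicted = predicted, observed = observed),
       slope = slope,
       rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
       n_splits = length(pred))
}
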