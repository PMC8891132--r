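# Bayesian categorical-predictor linear model ("akin to an ANOVA") for age
# at first symptoms by mutation-position group.  Cell-means coding: one
# Normal(0, 100) prior per group mean, half-Normal prior on the residual
# SD, Gaussian likelihood; complete cases only (missing ages dropped).

#' Fit the Bayesian group-mean model of onset age
#'
#' Gaussian likelihood `y_i ~ Normal(mu_g(i), sigma^2)` with independent
#' `Normal(mean_prior_mu, mean_prior_var)` priors on the group means and a
#' half-Normal(scale `sd_prior_scale`) prior on `sigma` (sampled on the
#' log scale). Groups with no observations are still reported, dominated
#' by their prior, with a warning.
#'
#' @param data A data frame with columns `group` and `onset_age_months`
#'   (e.g. the analyzable cohort); missing ages are dropped.
#' @param settings An [mcmc_settings()].
#' @param mean_prior_mu,mean_prior_var Normal prior on each group mean
#'   (default mean 0, variance 100).
#' @param sd_prior_scale Scale of the half-Normal prior on the residual
#'   SD (default 50 months, weak relative to the observed SD of ~13).
#' @param sigma_fixed Optional known residual SD; when given, `sigma` is
#'   held fixed instead of sampled (useful for conjugate cross-checks).
#' @return An object of class `cs_groupmean_fit` with elements `summary`
#'   (per-group posterior medians and 95% credible intervals), `draws`,
#'   `rhat`, `n_obs`, `settings`.
#' @export
fit_group_means <- function(data, settings, mean_prior_mu = 0,
                            mean_prior_var = 100, sd_prior_scale = 50,
                            sigma_fixed = NULL) {
  y <- data$onset_age_months
  g <- factor(as.character(data$group), levels = group_levels)
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- g[keep]
  if (length(y) < 2)
    .cs_error("need at least two non-missing onset ages",
              "csbayes_schema_error")
  n_g <- table(g)
  if (any(n_g == 0))
    warning(sprintf("group(s) with no observations: %s; ",
                    paste(names(n_g)[n_g == 0], collapse = ", ")),
            "their means are prior-dominated", call. = FALSE)
  pm_sd <- sqrt(mean_prior_var)
  fixed <- !is.null(sigma_fixed)

  # Gaussian sufficient statistics per group: the likelihood depends on
  # the data only through (n_g, ybar_g, SS_g), so each evaluation is O(1)
  # in the number of patients
  obs <- which(n_g > 0)
  n_obs_g <- as.numeric(n_g[obs])
  ybar_g <- vapply(group_levels[obs], function(lev) mean(y[g == lev]), 0)
  ss_g <- vapply(group_levels[obs], function(lev) {
    yy <- y[g == lev]
    sum((yy - mean(yy))^2)
  }, 0)
  n_tot <- length(y)

  lp <- function(par) {
    mu <- par[1:3]
    sigma <- if (fixed) sigma_fixed else exp(par[4])
    ll <- -n_tot * log(sigma) - 0.5 * n_tot * log(2 * pi) -
      sum((ss_g + n_obs_g * (ybar_g - mu[obs])^2) / (2 * sigma^2)) +
      sum(dnorm(mu, mean_prior_mu, pm_sd, log = TRUE))
    if (!fixed)
      # half-Normal on sigma, plus the log-scale Jacobian sigma = e^par4
      ll <- ll + dnorm(sigma, 0, sd_prior_scale, log = TRUE) + par[4]
    ll
  }

  means0 <- vapply(group_levels, function(lev) {
    if (n_g[[lev]] > 0) mean(y[g == lev]) else mean_prior_mu
  }, 0)
  base <- if (fixed) means0 else c(means0, log(max(sd(y), 1e-3)))
  init <- .with_seed(settings$seed + 1L,
                     sweep(matrix(rnorm(settings$n_chains * length(base),
                                        sd = 0.2), settings$n_chains),
                           2, base, `+`))
  pnames <- c(paste0("mu_", group_levels), if (!fixed) "log_sigma")
  draws <- run_chains(lp, init, settings, param_names = pnames)
  rhat <- if (settings$n_chains >= 2) gelman_rubin(draws) else
    setNames(rep(NA_real_, length(pnames)), pnames)
  summ <- do.call(rbind, lapply(group_levels, function(lev) {
    s <- summarize_draws(draws, paste0("mu_", lev))
    data.frame(group = lev, n = as.integer(n_g[[lev]]),
               mean = s$median, ci_low = s$ci_low, ci_high = s$ci_high,
               stringsAsFactors = FALSE)
  }))
  structure(list(summary = summ, draws = draws, rhat = rhat,
                 n_obs = length(y), settings = settings),
            class = "cs_groupmean_fit")
}

#' @export
print.cs_groupmean_fit <- function(x, ...) {
  cat(sprintf("Bayesian group-mean model of onset age (n = %d)\n", x$n_obs))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %s: %.1f [%.1f-%.1f] months (n = %d)\n", s$group[i],
                s$mean[i], s$ci_low[i], s$ci_high[i], s$n[i]))
  invisible(x)
}

#' Posterior probability that one group's mean onset exceeds another's
#'
#' Fraction of joint posterior draws with `mu_g1 - mu_g2 > 0`. Comparing
#' a group with itself is degenerate (the difference is identically zero)
#' and returns 0 with attribute `degenerate = TRUE`.
#'
#' @param fit A [fit_group_means()] result.
#' @param g1,g2 Group labels.
#' @return The probability, a number in `[0, 1]`.
#' @export
contrast_prob <- function(fit, g1, g2) {
  stopifnot(inherits(fit, "cs_groupmean_fit"))
  for (g in c(g1, g2))
    if (!g %in% group_levels)
      .cs_error(sprintf("unknown group '%s'", g), "csbayes_lookup_error")
  if (identical(g1, g2)) return(structure(0, degenerate = TRUE))
  d1 <- pooled_draws(fit$draws, paste0("mu_", g1))
  d2 <- pooled_draws(fit$draws, paste0("mu_", g2))
  mean(d1 - d2 > 0)
}
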