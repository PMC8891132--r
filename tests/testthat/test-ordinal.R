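test_that("prior elicitation reproduces the study's variances exactly", {
  p1 <- elicit_normal_prior(0.2, 5)
  expect_equal(round(p1$mu, 3), 0)
  expect_equal(round(p1$sigma2, 3), 0.674)
  p2 <- elicit_normal_prior(0.9, 10)
  expect_equal(round(p2$mu, 3), 1.099)
  expect_equal(round(p2$sigma2, 3), 0.377)
  p3 <- elicit_normal_prior(0.75, 5)
  expect_equal(round(p3$mu, 3), 0.661)
  expect_equal(round(p3$sigma2, 3), 0.234)
  expect_error(elicit_normal_prior(5, 0.2), class = "csbayes_prior_error")
  expect_error(elicit_normal_prior(-1, 2), class = "csbayes_prior_error")
})

test_that("prior OR intervals invert the elicitation", {
  iv <- prior_or_interval(normal_prior(0, 0.674))
  expect_equal(round(iv, 1), c(0.2, 5.0))
  # the vague prior's interval spans ~27 orders of magnitude
  vague <- prior_or_interval(normal_prior(0, 1000))
  expect_equal(signif(vague[2], 2), 8.3e26)
  # inverse pair property over random ranges
  set.seed(9)
  for (i in 1:20) {
    lo <- runif(1, 0.05, 0.9)
    hi <- lo + runif(1, 0.5, 20)
    back <- prior_or_interval(elicit_normal_prior(lo, hi))
    expect_equal(back, c(lo, hi), tolerance = 1e-10)
  }
})

test_that("the log-posterior is linear in the counts", {
  prior <- cs_priors$vague
  lp1 <- ordinal_log_posterior(cs_table2(), prior)
  lp2 <- ordinal_log_posterior(cs_table2() * 2, prior)
  par <- c(-1.9, log(2.4), 0.1, 0.5)
  prior_part <- sum(dnorm(par[3:4], 0, sqrt(1000), log = TRUE)) +
    sum(dnorm(par[1:2], 0, sqrt(1000), log = TRUE))
  loglik1 <- lp1(par) - prior_part
  expect_equal(lp2(par) - prior_part, 2 * loglik1, tolerance = 1e-10)
})

test_that("with beta 0 and empirical cutpoints the likelihood hits the
           intercept-only multinomial maximum", {
  tab <- cs_table2()
  tot <- colSums(tab)[c("III", "I", "II")]  # severity order
  N <- sum(tot)
  cum <- cumsum(tot / N)
  par <- c(qlogis(cum[1]), log(qlogis(cum[2]) - qlogis(cum[1])), 0, 0)
  lp <- ordinal_log_posterior(tab, cs_priors$vague)
  prior_part <- sum(dnorm(par, 0, sqrt(1000), log = TRUE))
  expect_equal(lp(par) - prior_part, sum(tot * log(tot / N)),
               tolerance = 1e-8)
})

test_that("a two-level outcome reduces to logistic regression with the
           closed-form log-OR as MLE", {
  # 2x2 collapse: two groups, severities I and II only
  tab <- matrix(0L, 3, 3, dimnames = dimnames(cs_table2()))
  tab["2U", "II"] <- 9L; tab["2U", "I"] <- 11L
  tab["2D", "II"] <- 57L; tab["2D", "I"] <- 32L
  cohort <- filter_analyzable(expand_table(tab))$cohort
  lp <- ordinal_log_posterior(cohort, normal_prior(0, 1e8))
  expect_equal(attr(lp, "terms"), "2D")
  expect_equal(attr(lp, "n_cut"), 1L)
  fit <- optim(c(0, 0), function(p) -lp(p), method = "BFGS")
  # empirical cumulative log odds ratio: log((57/32) / (9/11))
  expect_equal(fit$par[2], log((57 * 11) / (32 * 9)), tolerance = 1e-4)
})

test_that("fitting from the table equals fitting from expanded records", {
  prior <- cs_priors$precise
  lp_tab <- ordinal_log_posterior(cs_table2(), prior)
  cohort <- filter_analyzable(expand_table(cs_table2()))$cohort
  lp_rec <- ordinal_log_posterior(cohort, prior)
  expect_equal(attr(lp_tab, "counts"), attr(lp_rec, "counts"),
               ignore_attr = TRUE)
  for (par in list(c(-2, 1, 0, 0), c(-1.9, 0.9, -0.1, 0.8), c(0, 0, 1, -1)))
    expect_identical(lp_tab(par), lp_rec(par))
})

test_that("a near-degenerate prior pins the posterior at exp(mu)", {
  pr <- normal_prior(log(2), 1e-6)
  fit <- fit_ordinal(cs_table2(), pr, fast_settings(seed = 23))
  expect_equal(fit$summary$or, c(2, 2), tolerance = 0.01)
})

test_that("relabeling the reference level inverts the odds ratio", {
  st <- fast_settings(seed = 29)
  f_2u <- fit_ordinal(cs_table2(), cs_priors$vague, st)
  f_2d <- fit_ordinal(cs_table2(), cs_priors$vague, st,
                      refs = c(group = "2D"))
  or_2d_vs_2u <- f_2u$summary$or[f_2u$summary$term == "2D"]
  or_2u_vs_2d <- f_2d$summary$or[f_2d$summary$term == "2U"]
  expect_equal(or_2d_vs_2u * or_2u_vs_2d, 1, tolerance = 0.05)
})

test_that("the posterior recovers known coefficients at large n", {
  beta <- c(log(0.9), log(2))
  spec <- cohort_sim_spec(n_patients = 20000, true_beta = beta,
                          ambiguous_label_prob = 0, seed = 101)
  cohort <- filter_analyzable(generate_cohort(spec))$cohort
  fit <- fit_ordinal(build_contingency(cohort), cs_priors$vague,
                     fast_settings(seed = 37))
  expect_lt(max(abs(log(fit$summary$or) - beta)), 0.1)
})

test_that("the sampler agrees with JAGS on the study posterior", {
  skip_if_not_installed("rjags")
  fit <- fit_ordinal(cs_table2(), cs_priors$vague,
                     mcmc_settings(n_chains = 2, burn_in = 2000,
                                   n_iterations = 45000, thin = 3, seed = 41))
  model_str <- "
  model {
    for (g in 1:3) {
      n[g,1:3] ~ dmulti(p[g,1:3], N[g])
      logit(q[g,1]) <- theta[1] - eta[g]
      logit(q[g,2]) <- theta[2] - eta[g]
      p[g,1] <- q[g,1]
      p[g,2] <- q[g,2] - q[g,1]
      p[g,3] <- 1 - q[g,2]
    }
    eta[1] <- 0
    eta[2] <- b1
    eta[3] <- b2
    b1 ~ dnorm(0, 0.001)
    b2 ~ dnorm(0, 0.001)
    t1 ~ dnorm(0, 0.001)
    dd ~ dnorm(0, 0.001)
    theta[1] <- t1
    theta[2] <- t1 + exp(dd)
  }"
  counts <- cs_table2()[, c("III", "I", "II")]
  set.seed(1)
  jm <- rjags::jags.model(textConnection(model_str),
                          data = list(n = counts, N = rowSums(counts)),
                          inits = list(t1 = -2, dd = 0.5, b1 = 0, b2 = 0),
                          n.chains = 2, n.adapt = 1000, quiet = TRUE)
  update(jm, 3000)
  m <- as.matrix(rjags::coda.samples(jm, c("b1", "b2"),
                                     n.iter = 45000, thin = 3))
  s <- fit$summary
  expect_lt(abs(s$or[s$term == "1U1D"] - median(exp(m[, "b1"]))), 0.1)
  expect_lt(abs(s$or[s$term == "2D"] - median(exp(m[, "b2"]))), 0.15)
  expect_lt(abs(s$pr_gt_1[s$term == "2D"] - mean(m[, "b2"] > 0)), 0.02)
})

test_that("the sensitivity suite aligns seeds and orders priors coherently", {
  st <- fast_settings(seed = 43)
  res <- sensitivity_suite(cs_table2(),
                           list(a = cs_priors$vague, b = cs_priors$vague,
                                opt = cs_priors$optimistic), st)
  # identical priors reproduce each other draw for draw
  a <- res[res$prior == "a", ]
  b <- res[res$prior == "b", ]
  expect_identical(a$or, b$or)
  expect_identical(a$pr_gt_1, b$pr_gt_1)
  # shifting prior mass upward cannot lower Pr(OR(2D) > 1)
  expect_gte(res$pr_gt_1[res$prior == "opt" & res$term == "2D"],
             res$pr_gt_1[res$prior == "a" & res$term == "2D"])
  expect_true(all(c("prior_or_low", "prior_or_high") %in% names(res)))
})

test_that("the variant-class model uses complete cases with PAV reference", {
  spec <- cohort_sim_spec(n_patients = 800, seed = 53)
  cohort <- filter_analyzable(generate_cohort(spec))$cohort
  cohort$vgroup[1:40] <- "UNKNOWN"
  lp <- ordinal_log_posterior(cohort, cs_priors$vague, covariates = "vgroup")
  expect_equal(attr(lp, "terms"), "PTV_GROUP")
  expect_equal(sum(attr(lp, "counts")), sum(cohort$vgroup != "UNKNOWN"))
  # multivariate: position + variant class, additive
  lp2 <- ordinal_log_posterior(cohort, cs_priors$vague,
                               covariates = c("group", "vgroup"))
  expect_equal(attr(lp2, "terms"), c("1U1D", "2D", "PTV_GROUP"))
})
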