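test_that("posterior draws live on the simplex and match Dirichlet means", {
  tab <- matrix(1, 2, 2, dimnames = list(g = c("a", "b"), s = c("x", "y")))
  d <- sample_dirichlet_posterior(tab, dirichlet_prior("jeffreys"),
                                  n_draws = 200000, seed = 1)
  expect_true(all(abs(rowSums(d$p) - 1) < 1e-12))
  # posterior concentration (n + alpha) = 1.5 per cell; mean 1.5/6 = 0.25
  expect_true(all(abs(colMeans(d$p) - 0.25) < 0.005))

  zero <- matrix(0, 2, 3, dimnames = list(g = c("a", "b"),
                                          s = c("x", "y", "z")))
  dz <- sample_dirichlet_posterior(zero, dirichlet_prior("uniform"),
                                   n_draws = 100000, seed = 2)
  expect_true(all(abs(colMeans(dz$p) - 1 / 6) < 0.01))
})

test_that("prior construction enforces positive concentrations", {
  expect_error(dirichlet_prior("custom", alpha = 0),
               class = "csbayes_prior_error")
  expect_equal(dirichlet_prior("uniform")$alpha, 1)
  expect_equal(dirichlet_prior()$alpha, 0.5)
})

test_that("contrast definitions reject degenerate comparisons", {
  expect_error(or_contrast("2D", "2D", "II", "I"),
               class = "csbayes_contrast_error")
  expect_error(or_contrast("2D", "2U", "II", "II"),
               class = "csbayes_contrast_error")
  expect_error(or_contrast(character(0), "2U", "II", "I"),
               class = "csbayes_contrast_error")
})

test_that("symmetric tables give OR centred on 1", {
  tab <- matrix(5, 2, 2, dimnames = list(g = c("a", "b"), s = c("x", "y")))
  d <- sample_dirichlet_posterior(tab, dirichlet_prior("jeffreys"),
                                  n_draws = 200000, seed = 3)
  s <- or_posterior(d, or_contrast("a", "b", "x", "y"))
  expect_lt(abs(s$pr_gt_1 - 0.5), 0.01)
  expect_lt(abs(s$point - 1), 0.05)
})

test_that("reversing a contrast inverts the odds ratio draw by draw", {
  d <- sample_dirichlet_posterior(cs_table2(), n_draws = 50000, seed = 4)
  fwd <- or_posterior(d, or_contrast("2D", "1U1D", "II", "I"),
                      keep_draws = TRUE)
  swapped <- or_posterior(d, or_contrast("2D", "1U1D", "I", "II"),
                          keep_draws = TRUE)
  rows <- or_posterior(d, or_contrast("1U1D", "2D", "II", "I"),
                       keep_draws = TRUE)
  expect_equal(attr(fwd, "or_draws") * attr(swapped, "or_draws"),
               rep(1, 50000), tolerance = 1e-12)
  expect_equal(attr(fwd, "or_draws") * attr(rows, "or_draws"),
               rep(1, 50000), tolerance = 1e-12)
  # summary-level reciprocity
  expect_lt(abs(fwd$point * rows$point - 1), 0.02)
  expect_lt(abs(fwd$pr_gt_1 + rows$pr_gt_1 - 1), 0.01)
})

test_that("log-OR draws match the exact digamma/trigamma moments on all nine contrasts", {
  tab <- cs_table2()
  alpha <- tab + 0.5
  d <- sample_dirichlet_posterior(tab, dirichlet_prior("jeffreys"),
                                  n_draws = 200000, seed = 5)
  row_pairs <- list(c("2D", "1U1D"), c("1U1D", "2U"), c("2D", "2U"))
  col_pairs <- list(c("II", "I"), c("I", "III"), c("II", "III"))
  for (rp in row_pairs) for (cp in col_pairs) {
    s <- or_posterior(d, or_contrast(rp[1], rp[2], cp[1], cp[2]),
                      keep_draws = TRUE)
    lo <- log(attr(s, "or_draws"))
    # exact identity: E[log OR] is a sum of digamma terms (the joint
    # normalizer cancels); the Monte Carlo SE follows from trigamma
    oracle <- digamma_log_or(alpha, rp[1], rp[2], cp[1], cp[2])
    mc_se <- sqrt((trigamma(alpha[rp[1], cp[1]]) +
                     trigamma(alpha[rp[2], cp[2]]) +
                     trigamma(alpha[rp[1], cp[2]]) +
                     trigamma(alpha[rp[2], cp[1]])) / length(lo))
    expect_lt(abs(mean(lo) - oracle), 5 * mc_se)
    # for the well-populated II-vs-I contrasts the posterior is close to
    # normal, so the median agrees with the digamma mean too
    if (identical(cp, c("II", "I")))
      expect_lt(abs(log(s$point) - oracle), 0.05)
  }
})

test_that("pooled-row contrasts match the aggregated 2x2 subtable", {
  tab <- cs_table2()
  d3 <- sample_dirichlet_posterior(tab, dirichlet_prior("jeffreys"),
                                   n_draws = 200000, seed = 6)
  pooled <- or_posterior(d3, or_contrast("2D", c("2U", "1U1D"), "II", "I"))
  # aggregation property: summing Dirichlet components gives a Dirichlet
  # with summed concentrations, so the same contrast from the collapsed
  # table must agree in distribution
  sub <- rbind(`2D` = tab["2D", c("II", "I")],
               rest = tab["2U", c("II", "I")] + tab["1U1D", c("II", "I")])
  colnames(sub) <- c("II", "I")
  # per-cell concentrations add under aggregation: 0.5 for the 2D row,
  # 0.5 + 0.5 for the pooled row
  agg_alpha <- rbind(c(0.5, 0.5), c(1, 1))
  d2 <- sample_dirichlet_posterior(sub,
                                   dirichlet_prior("custom",
                                                   alpha = agg_alpha),
                                   n_draws = 200000, seed = 7)
  s2 <- or_posterior(d2, or_contrast("2D", "rest", "II", "I"))
  expect_lt(abs(log(pooled$point) - log(s2$point)), 0.03)
  expect_lt(abs(pooled$pr_gt_1 - s2$pr_gt_1), 0.01)
})

test_that("credible intervals tighten as counts scale up", {
  widths <- vapply(c(1, 10, 100), function(cc) {
    d <- sample_dirichlet_posterior(cs_table2() * cc, n_draws = 50000,
                                    seed = 8)
    s <- or_posterior(d, or_contrast("2D", "2U", "II", "I"))
    log(s$ci_high) - log(s$ci_low)
  }, 0)
  expect_true(all(diff(widths) < 0))
})

test_that("draws are reproducible given the seed", {
  d1 <- sample_dirichlet_posterior(cs_table2(), n_draws = 1000, seed = 9)
  d2 <- sample_dirichlet_posterior(cs_table2(), n_draws = 1000, seed = 9)
  expect_identical(d1$p, d2$p)
})
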