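# Shared sampling infrastructure: component-wise adaptive random-walk
# Metropolis over a user-supplied log-posterior, multi-chain orchestration,
# split-chain convergence diagnostics and posterior summaries.
#
# Proposal scales adapt by Robbins-Monro toward a target acceptance rate
# during burn-in only and are frozen afterwards, so the retained chain is
# a genuine (non-adaptive) Markov chain.

#' MCMC run settings
#'
#' Defaults follow the study's schedule: 3 chains, 5000 burn-in
#' iterations, 150000 retained-phase iterations with a thinning of 3
#' (50000 stored draws per chain).
#'
#' @param n_chains Number of chains.
#' @param burn_in Burn-in iterations (adaptation happens only here).
#' @param n_iterations Post-burn-in iterations per chain.
#' @param thin Thinning interval; `n_iterations %/% thin` draws are stored.
#' @param seed Master seed; independent per-chain sub-seeds are derived
#'   from it deterministically.
#' @param target_acceptance Target acceptance rate of the component-wise
#'   proposals (0.44 is the standard one-dimensional optimum).
#' @return An object of class `cs_mcmc_settings`.
#' @export
mcmc_settings <- function(n_chains = 3, burn_in = 5000, n_iterations = 150000,
                          thin = 3, seed, target_acceptance = 0.44) {
  stopifnot(n_chains >= 1, burn_in >= 0, n_iterations >= 1, thin >= 1,
            target_acceptance > 0, target_acceptance < 1)
  structure(list(n_chains = as.integer(n_chains),
                 burn_in = as.integer(burn_in),
                 n_iterations = as.integer(n_iterations),
                 thin = as.integer(thin), seed = as.integer(seed),
                 target_acceptance = target_acceptance),
            class = "cs_mcmc_settings")
}

# One chain of component-wise adaptive random-walk Metropolis.
.run_one_chain <- function(log_posterior, init, settings) {
  p <- length(init)
  burn <- settings$burn_in
  iters <- settings$n_iterations
  thin <- settings$thin
  target <- settings$target_acceptance
  n_stored <- iters %/% thin

  cur <- as.numeric(init)
  lp_cur <- log_posterior(cur)
  if (!is.finite(lp_cur))
    .cs_error("log-posterior is not finite at the chain's initial point",
              "csbayes_init_error")
  ls <- rep(0, p)                     # log proposal scales
  draws <- matrix(NA_real_, n_stored, p)
  acc_count <- rep(0L, p)
  total <- burn + iters
  # pre-generate the innovations: standard-normal proposal steps and the
  # uniform acceptance variates (scales multiply in at use time)
  z <- matrix(rnorm(total * p), total, p)
  lu <- matrix(log(runif(total * p)), total, p)
  s <- 0L
  for (it in seq_len(total)) {
    adapting <- it <= burn
    for (j in seq_len(p)) {
      prop <- cur
      prop[j] <- cur[j] + exp(ls[j]) * z[it, j]
      lp_prop <- log_posterior(prop)
      d <- lp_prop - lp_cur
      accept <- is.finite(lp_prop) && lu[it, j] < d
      if (accept) { cur <- prop; lp_cur <- lp_prop }
      if (adapting) {
        alpha <- if (!is.finite(lp_prop)) 0 else min(1, exp(d))
        ls[j] <- ls[j] + it^-0.6 * (alpha - target)
      } else if (accept) acc_count[j] <- acc_count[j] + 1L
    }
    if (!adapting && (it - burn) %% thin == 0L) {
      s <- s + 1L
      draws[s, ] <- cur
    }
  }
  acc_rate <- acc_count / iters
  if (all(acc_rate == 0))
    warning("no proposals were accepted after burn-in; ",
            "the sampler looks pathological", call. = FALSE)
  list(draws = draws, acceptance = acc_rate, scales = exp(ls))
}

#' Run multiple Metropolis chains over a log-posterior
#'
#' @param log_posterior Function of a parameter vector returning the
#'   unnormalized log-posterior density (`-Inf` allowed outside support).
#' @param init Initial values: a numeric vector (shared by all chains), a
#'   `n_chains` x p matrix (one row per chain), or a function of the chain
#'   index returning a vector.
#' @param settings An [mcmc_settings()].
#' @param param_names Optional parameter names.
#' @return An object of class `cs_draws`: stored draws as a
#'   (iteration, parameter, chain) array plus acceptance rates, frozen
#'   proposal scales and full settings provenance. Identical inputs and
#'   seed reproduce the draws bit for bit.
#' @export
run_chains <- function(log_posterior, init, settings, param_names = NULL) {
  stopifnot(inherits(settings, "cs_mcmc_settings"))
  n_chains <- settings$n_chains
  chain_seeds <- .with_seed(settings$seed,
                            sample.int(.Machine$integer.max - 1L, n_chains))
  get_init <- function(ch) {
    if (is.function(init)) init(ch)
    else if (is.matrix(init)) init[ch, ]
    else init
  }
  p <- length(get_init(1L))
  if (is.null(param_names)) param_names <- paste0("par", seq_len(p))
  if (anyDuplicated(param_names))
    .cs_error("parameter names must be unique", "csbayes_spec_error")

  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains))
    chains[[ch]] <- .with_seed(chain_seeds[ch],
                               .run_one_chain(log_posterior, get_init(ch),
                                              settings))
  n_stored <- settings$n_iterations %/% settings$thin
  draws <- array(NA_real_, c(n_stored, p, n_chains),
                 dimnames = list(NULL, param_names, NULL))
  for (ch in seq_len(n_chains)) draws[, , ch] <- chains[[ch]]$draws
  structure(list(
    draws = draws, param_names = param_names, settings = settings,
    acceptance = do.call(rbind, lapply(chains, `[[`, "acceptance")),
    scales = do.call(rbind, lapply(chains, `[[`, "scales")),
    chain_seeds = chain_seeds),
    class = "cs_draws")
}

#' Pool stored draws of one parameter across chains
#'
#' @param draws A `cs_draws` object.
#' @param parameter Parameter name or index.
#' @return Numeric vector of pooled draws.
#' @export
pooled_draws <- function(draws, parameter) {
  stopifnot(inherits(draws, "cs_draws"))
  if (is.character(parameter)) {
    idx <- match(parameter, draws$param_names)
    if (is.na(idx))
      .cs_error(sprintf("unknown parameter '%s'", parameter),
                "csbayes_lookup_error")
    parameter <- idx
  }
  as.vector(draws$draws[, parameter, ])
}

#' Split-chain potential scale reduction factor (R-hat)
#'
#' Each chain is split in half and the classical between/within-variance
#' R-hat is computed over the resulting half-chains. Values near 1
#' indicate convergence; above ~1.01 warrant attention.
#'
#' @param draws A `cs_draws` object (>= 2 chains, >= 10 stored draws).
#' @return Named vector of R-hat values, one per parameter.
#' @export
gelman_rubin <- function(draws) {
  stopifnot(inherits(draws, "cs_draws"))
  dd <- draws$draws
  n_chains <- dim(dd)[3]
  n <- dim(dd)[1]
  if (n_chains < 2)
    .cs_error("R-hat requires at least two chains", "csbayes_diag_error")
  if (n < 10)
    .cs_error("R-hat requires at least 10 stored draws", "csbayes_diag_error")
  half <- n %/% 2
  out <- vapply(seq_along(draws$param_names), function(j) {
    halves <- list()
    for (ch in seq_len(n_chains)) {
      halves[[length(halves) + 1L]] <- dd[seq_len(half), j, ch]
      halves[[length(halves) + 1L]] <- dd[(n - half + 1L):n, j, ch]
    }
    m <- length(halves)
    means <- vapply(halves, mean, 0)
    vars <- vapply(halves, var, 0)
    B <- half * var(means)
    W <- mean(vars)
    if (W == 0) return(1)
    sqrt(((half - 1) / half * W + B / half) / W)
  }, 0)
  names(out) <- draws$param_names
  out
}

#' Effective sample size
#'
#' Autocorrelation-based effective number of independent draws, pooled
#' over chains, using Geyer's initial-positive-sequence truncation of the
#' chain-averaged autocorrelation function.
#'
#' @param draws A `cs_draws` object.
#' @return Named vector of effective sample sizes per parameter.
#' @export
effective_size <- function(draws) {
  stopifnot(inherits(draws, "cs_draws"))
  dd <- draws$draws
  n <- dim(dd)[1]; n_chains <- dim(dd)[3]
  max_lag <- min(n - 1L, 1000L)
  out <- vapply(seq_along(draws$param_names), function(j) {
    rho <- rowMeans(vapply(seq_len(n_chains), function(ch) {
      x <- dd[, j, ch]
      if (var(x) == 0) return(rep(0, max_lag + 1L))
      drop(acf(x, lag.max = max_lag, plot = FALSE,
               demean = TRUE)$acf)
    }, numeric(max_lag + 1L)))
    # Geyer: sum paired autocorrelations while the pair sums stay positive
    tau <- 1
    t <- 1L
    while (t + 1L <= max_lag) {
      pair <- rho[t + 1L] + rho[t + 2L]
      if (!is.finite(pair) || pair <= 0) break
      tau <- tau + 2 * pair
      t <- t + 2L
    }
    n * n_chains / tau
  }, 0)
  names(out) <- draws$param_names
  out
}

#' Summarize one parameter's posterior
#'
#' Applies an optional monotone transform per draw, then reports the
#' posterior median, the equal-tailed 95% credible interval (linear
#' interpolation between order statistics) and the exceedance probability
#' against a threshold stated on the untransformed scale (default 0, i.e.
#' Pr(OR > 1) when the transform is `exp`).
#'
#' @param draws A `cs_draws` object.
#' @param parameter Parameter name or index.
#' @param transform `"identity"` or `"exp"`.
#' @param threshold Exceedance threshold on the untransformed scale.
#' @return List with `median`, `ci_low`, `ci_high`, `pr_gt_threshold`,
#'   `n_draws`.
#' @export
summarize_draws <- function(draws, parameter,
                            transform = c("identity", "exp"),
                            threshold = 0) {
  transform <- match.arg(transform)
  x <- pooled_draws(draws, parameter)
  pr <- mean(x > threshold)
  if (transform == "exp") x <- exp(x)
  q <- unname(quantile(x, c(0.025, 0.5, 0.975)))
  list(median = q[2], ci_low = q[1], ci_high = q[3],
       pr_gt_threshold = pr, n_draws = length(x))
}

#' Trace plot of stored draws
#'
#' @param draws A `cs_draws` object.
#' @param parameter Parameter name or index.
#' @param ... Passed to [graphics::matplot()].
#' @export
traceplot <- function(draws, parameter, ...) {
  stopifnot(inherits(draws, "cs_draws"))
  if (is.character(parameter))
    parameter <- match(parameter, draws$param_names)
  m <- draws$draws[, parameter, ]
  graphics::matplot(m, type = "l", lty = 1,
                    xlab = "stored iteration",
                    ylab = draws$param_names[parameter], ...)
  invisible(draws)
}

#' Persist stored draws as a flat table
#'
#' Long-format TSV with columns `chain`, `iter` and one column per
#' parameter, alongside a JSON run manifest (settings, chain seeds,
#' acceptance rates, R-hat, effective sizes).
#'
#' @param draws A `cs_draws` object.
#' @param path Output TSV path; the manifest is written next to it with a
#'   `.manifest.json` suffix.
#' @export
write_draws <- function(draws, path) {
  stopifnot(inherits(draws, "cs_draws"))
  dd <- draws$draws
  n <- dim(dd)[1]; n_chains <- dim(dd)[3]
  flat <- do.call(rbind, lapply(seq_len(n_chains), function(ch)
    data.frame(chain = ch, iter = seq_len(n), dd[, , ch, drop = FALSE][, , 1])))
  names(flat) <- c("chain", "iter", draws$param_names)
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(settings = unclass(draws$settings),
                   chain_seeds = draws$chain_seeds,
                   acceptance = draws$acceptance,
                   rhat = tryCatch(as.list(gelman_rubin(draws)),
                                   error = function(e) NULL),
                   ess = as.list(effective_size(draws)))
  jsonlite::write_json(manifest, sub("\\.tsv$", ".manifest.json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
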