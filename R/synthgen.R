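# Synthetic cohort generation.  The study's raw per-patient table is not
# public, so tests, demos and recovery studies run on cohorts simulated
# with the same statistical structure the analysis assumes: mutation-group
# proportions from the published cohort composition, ordinal severity from
# a cumulative-logit model, and onset age from a moment-matched Gamma.

# Evaluate a function with the RNG seeded locally, restoring global state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specify a synthetic cohort
#'
#' Defaults reproduce the published cohort's structure: 147 patients split
#' 24/18/105 across the 2U/1U1D/2D groups, severity from a
#' proportional-odds model whose coefficients equal the study's
#' vague-prior posterior medians (odds ratio 0.9 for 1U1D, 2.0 for 2D,
#' both against 2U), onset age with mean 8 and SD 13.4 months capped at 72,
#' about 16% of onset ages missing, and about 7% of type I/II patients
#' carrying an ambiguous subtype label (10 of 147 overall).
#'
#' @param n_patients Number of patients.
#' @param group_probs Probabilities of the 2U, 1U1D and 2D groups (must sum
#'   to 1).
#' @param true_beta Log odds ratios of a more severe subtype for 1U1D and
#'   2D versus the 2U reference.
#' @param true_cutpoints Cutpoints (theta1, theta2) of the cumulative-logit
#'   model on the latent severity scale, strictly increasing; the default
#'   matches the 2U reference group's empirical cumulative frequencies.
#' @param onset_mean_months,onset_sd_months Moments of the onset-age
#'   distribution (months). `onset_mean_months` may be a single value or
#'   one value per group, enabling group-specific onset means.
#' @param onset_max_months Upper truncation for onset ages.
#' @param onset_missing_prob Probability that an onset age is missing.
#' @param ambiguous_label_prob Probability that a type I or II patient's
#'   label is replaced by an ambiguous one (`I_OR_II` or `I_SLASH_II`).
#' @param seed Master RNG seed; the generator is fully reproducible.
#' @return An object of class `cs_sim_spec`.
#' @export
cohort_sim_spec <- function(n_patients = 147,
                            group_probs = c(24, 18, 105) / 147,
                            true_beta = c(log(0.9), log(2.0)),
                            true_cutpoints = c(qlogis(3 / 23), qlogis(14 / 23)),
                            onset_mean_months = 8,
                            onset_sd_months = 13.4,
                            onset_max_months = 72,
                            onset_missing_prob = 24 / 147,
                            ambiguous_label_prob = 0.074,
                            seed = 1L) {
  if (length(group_probs) != 3 || any(group_probs < 0) ||
      abs(sum(group_probs) - 1) > 1e-8)
    .cs_error("group_probs must be a 3-element probability simplex",
              "csbayes_spec_error")
  if (length(true_cutpoints) != 2 || diff(true_cutpoints) <= 0)
    .cs_error("true_cutpoints must be strictly increasing",
              "csbayes_spec_error")
  if (!length(true_beta) %in% c(2, 3))
    .cs_error("true_beta must have one entry per non-reference group",
              "csbayes_spec_error")
  if (!length(onset_mean_months) %in% c(1, 3) || any(onset_mean_months <= 0) ||
      onset_sd_months <= 0 || onset_max_months <= 0)
    .cs_error("onset moments must be positive", "csbayes_spec_error")
  for (p in c(onset_missing_prob, ambiguous_label_prob))
    if (p < 0 || p > 1)
      .cs_error("probabilities must lie in [0, 1]", "csbayes_spec_error")
  structure(list(n_patients = as.integer(n_patients),
                 group_probs = group_probs, true_beta = true_beta,
                 true_cutpoints = true_cutpoints,
                 onset_mean_months = onset_mean_months,
                 onset_sd_months = onset_sd_months,
                 onset_max_months = onset_max_months,
                 onset_missing_prob = onset_missing_prob,
                 ambiguous_label_prob = ambiguous_label_prob,
                 seed = as.integer(seed)),
            class = "cs_sim_spec")
}

#' Moment-matched Gamma parameters for onset age
#'
#' Shape and rate of the Gamma distribution with the requested mean and
#' standard deviation. A Gamma is used because the onset-age distribution
#' is non-negative and strongly right-skewed (SD well above the mean).
#'
#' @param mean,sd Target mean and standard deviation.
#' @return List with `shape` and `rate`.
#' @export
onset_gamma_params <- function(mean, sd) {
  list(shape = mean^2 / sd^2, rate = mean / sd^2)
}

#' Closed-form severity cell probabilities of the cumulative-logit model
#'
#' P(severity = k | group) for each group under
#' logit P(Y <= k) = theta_k - beta_g, with severity ordered III < I < II.
#'
#' @param true_beta,true_cutpoints As in [cohort_sim_spec()].
#' @return A 3 x 3 matrix (groups by severity levels III, I, II).
#' @export
severity_cell_probs <- function(true_beta, true_cutpoints) {
  eta <- c(0, true_beta[1:2])
  c1 <- plogis(true_cutpoints[1] - eta)
  c2 <- plogis(true_cutpoints[2] - eta)
  m <- cbind(III = c1, I = c2 - c1, II = 1 - c2)
  rownames(m) <- group_levels
  m
}

#' Generate a synthetic cohort
#'
#' Samples mutation groups, ordinal severity, onset ages and label
#' ambiguity per the simulation spec, returning a cohort data frame in the
#' standard dialect (region labels stand in for coordinates; upstream
#' alleles are always protein-truncating, mirroring the real cohort where
#' no upstream PAV was observed).
#'
#' @param spec A [cohort_sim_spec()].
#' @return A cohort data frame ([validate_cohort()]-conformant).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cs_sim_spec"))
  n <- spec$n_patients
  .with_seed(spec$seed, {
    group <- sample(group_levels, n, replace = TRUE, prob = spec$group_probs)
    gi <- match(group, group_levels)

    # ordinal severity from the cumulative-logit model
    eta <- c(0, spec$true_beta[1:2])[gi]
    p_le1 <- plogis(spec$true_cutpoints[1] - eta)
    p_le2 <- plogis(spec$true_cutpoints[2] - eta)
    u <- runif(n)
    sev <- severity_levels[1L + (u > p_le1) + (u > p_le2)]

    # onset age: moment-matched Gamma, truncated at the cap by resampling
    mu <- if (length(spec$onset_mean_months) == 1)
      rep(spec$onset_mean_months, 3) else spec$onset_mean_months
    onset <- numeric(n)
    for (g in 1:3) {
      idx <- which(gi == g)
      if (!length(idx)) next
      gp <- onset_gamma_params(mu[g], spec$onset_sd_months)
      x <- rgamma(length(idx), shape = gp$shape, rate = gp$rate)
      while (any(bad <- x > spec$onset_max_months))
        x[bad] <- rgamma(sum(bad), shape = gp$shape, rate = gp$rate)
      onset[idx] <- x
    }
    onset[runif(n) < spec$onset_missing_prob] <- NA_real_

    # subtype labels; a fraction of type I/II labels is made ambiguous
    subtype <- sev
    eligible <- sev %in% c("I", "II")
    amb <- eligible & runif(n) < spec$ambiguous_label_prob
    subtype[amb] <- sample(c("I_OR_II", "I_SLASH_II"), sum(amb), replace = TRUE)

    r1 <- ifelse(group == "2D", "DOWNSTREAM", "UPSTREAM")
    r2 <- ifelse(group == "2U", "UPSTREAM", "DOWNSTREAM")
    # upstream alleles are always PTV; downstream alleles PTV ~60%/PAV ~40%
    cl1 <- ifelse(r1 == "UPSTREAM", "PTV",
                  ifelse(runif(n) < 0.6, "PTV", "PAV"))
    cl2 <- ifelse(r2 == "UPSTREAM", "PTV",
                  ifelse(runif(n) < 0.6, "PTV", "PAV"))

    data.frame(
      patient_id = sprintf("SYN%04d", seq_len(n)),
      sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.58, 0.42)),
      mut1_cdna = NA_integer_, mut1_offset = NA_integer_,
      mut1_region = r1, mut1_class = cl1,
      mut2_cdna = NA_integer_, mut2_offset = NA_integer_,
      mut2_region = r2, mut2_class = cl2,
      subtype = subtype,
      onset_age_months = onset,
      source = sample(c("database", "literature"), n, replace = TRUE,
                      prob = c(85, 62) / 147),
      stringsAsFactors = FALSE)
  })
}

#' Expand a contingency table into individual patient records
#'
#' One minimal record per count unit, with the mutation-position group
#' (encoded through region labels) and subtype set and every other field
#' missing. Lets record-level models consume a published table directly;
#' rebuilding the table from the expansion is the identity.
#'
#' @param table A 3 x 3 contingency table as from [build_contingency()]
#'   (rows 2U, 1U1D, 2D; columns II, I, III).
#' @return A cohort data frame with one row per patient.
#' @export
expand_table <- function(table) {
  stopifnot(is.matrix(table), all(table >= 0), all(is.finite(table)))
  rows <- rownames(table); cols <- colnames(table)
  grp <- rep(rep(rows, times = ncol(table)), times = as.vector(table))
  sev <- rep(rep(cols, each = nrow(table)), times = as.vector(table))
  n <- length(grp)
  df <- data.frame(
    patient_id = if (n) sprintf("TAB%04d", seq_len(n)) else character(0),
    sex = rep(NA_character_, n),
    mut1_cdna = rep(NA_integer_, n), mut1_offset = rep(NA_integer_, n),
    mut1_region = ifelse(grp == "2D", "DOWNSTREAM", "UPSTREAM"),
    mut1_class = rep("UNKNOWN", n),
    mut2_cdna = rep(NA_integer_, n), mut2_offset = rep(NA_integer_, n),
    mut2_region = ifelse(grp == "2U", "UPSTREAM", "DOWNSTREAM"),
    mut2_class = rep("UNKNOWN", n),
    subtype = sev,
    onset_age_months = rep(NA_real_, n),
    source = rep(NA_character_, n),
    stringsAsFactors = FALSE)
  if (!n) df$mut1_region <- df$mut2_region <- character(0)
  df
}

#' Serialize / read a simulation spec as YAML
#'
#' @param spec A [cohort_sim_spec()].
#' @param path File path.
#' @export
write_sim_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path, precision = 17)
  invisible(path)
}

#' @rdname write_sim_spec
#' @export
read_sim_spec <- function(path) {
  do.call(cohort_sim_spec, yaml::read_yaml(path))
}
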