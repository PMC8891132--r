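# Shared test utilities: reduced MCMC schedules for property tests and the
# digamma oracle for Dirichlet log-odds-ratios.

# Reduced schedule: enough draws for distributional checks at test speed.
fast_settings <- function(seed, chains = 2) {
  mcmc_settings(n_chains = chains, burn_in = 2000, n_iterations = 12000,
                thin = 3, seed = seed)
}

# Minimal schedule for repeated fits (coverage loops).
tiny_settings <- function(seed) {
  mcmc_settings(n_chains = 1, burn_in = 600, n_iterations = 5000, thin = 1,
                seed = seed)
}

# Independent oracle: under p ~ Dirichlet(alpha), E[log p_i] =
# digamma(alpha_i) - digamma(sum(alpha)); the normalizing term cancels in
# a log odds ratio, so E[log OR] is a sum of four digamma terms.
digamma_log_or <- function(alpha, num_row, den_row, num_col, den_col) {
  digamma(alpha[num_row, num_col]) + digamma(alpha[den_row, den_col]) -
    digamma(alpha[num_row, den_col]) - digamma(alpha[den_row, num_col])
}

# A small cohort of explicit coordinate-level records (one of each group).
coord_cohort <- function() {
  data.frame(
    patient_id = c("P1", "P2", "P3", "P4"),
    sex = c("M", "F", NA, "M"),
    mut1_cdna = c(100L, 1397L, 2000L, NA),
    mut1_offset = NA_integer_,
    mut1_region = c(NA, NA, NA, "DOWNSTREAM"),
    mut1_class = c("PTV", "PTV", "PAV", "UNKNOWN"),
    mut2_cdna = c(500L, 3000L, 4000L, NA),
    mut2_offset = NA_integer_,
    mut2_region = c(NA, NA, NA, "DOWNSTREAM"),
    mut2_class = c("PTV", "PAV", "PAV", "PTV"),
    subtype = c("III", "I", "II", "COFS"),
    onset_age_months = c(24, 12, 0, NA),
    source = c("database", "database", "literature", "literature"),
    stringsAsFactors = FALSE)
}
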