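# Packaged fixtures: the published severity-by-genotype contingency table
# (the complete analyzable dataset of the study) and a synthetic 147-record
# cohort with the published label composition.

#' The published severity-by-genotype contingency table
#'
#' Counts of the 136 analyzable Cockayne patients by mutation-position
#' group (rows 2U, 1U1D, 2D) and severity class (columns II, I, III;
#' type II pools classical type II and COFS). This table is the complete
#' dataset behind the contingency and ordinal analyses.
#'
#' @return A 3 x 3 integer matrix of counts.
#' @export
#' @examples
#' cs_table2()
#' sum(cs_table2())  # 136 analyzable patients
cs_table2 <- function() {
  matrix(c(9L, 5L, 57L,    # type II
           11L, 11L, 32L,  # type I
           3L, 1L, 7L),    # type III
         nrow = 3,
         dimnames = list(group = group_levels,
                         severity = c("II", "I", "III")))
}

#' Synthetic 147-record cohort with the published label composition
#'
#' A deterministic, fully synthetic cohort that reproduces the published
#' inclusion accounting: the 136 analyzable patients expanded from the
#' contingency table, plus 4 patients labelled `I_OR_II`, 6 labelled
#' `I_SLASH_II` and 1 `UNCLASSIFIED` (147 in total). Onset ages are drawn
#' once from the moment-matched Gamma model with group-specific means
#' (11.8, 11.4 and 6.5 months for 2U, 1U1D, 2D) and ~16% missingness, so
#' the age analysis can be exercised; they are synthetic stand-ins, not
#' the study's restricted per-patient ages.
#'
#' @param seed Seed for the synthetic onset ages (default fixed, so the
#'   fixture is reproducible across sessions).
#' @return A cohort data frame with 147 rows.
#' @export
cohort_fixture_147 <- function(seed = 20220217L) {
  base <- expand_table(cs_table2())
  amb <- data.frame(
    patient_id = sprintf("AMB%04d", 1:11),
    sex = NA_character_,
    mut1_cdna = NA_integer_, mut1_offset = NA_integer_,
    mut1_region = c(rep("DOWNSTREAM", 8), "UPSTREAM", "UPSTREAM", "DOWNSTREAM"),
    mut1_class = "UNKNOWN",
    mut2_cdna = NA_integer_, mut2_offset = NA_integer_,
    mut2_region = c(rep("DOWNSTREAM", 8), "UPSTREAM", "DOWNSTREAM", "DOWNSTREAM"),
    mut2_class = "UNKNOWN",
    subtype = c(rep("I_OR_II", 4), rep("I_SLASH_II", 6), "UNCLASSIFIED"),
    onset_age_months = NA_real_,
    source = NA_character_,
    stringsAsFactors = FALSE)
  cohort <- rbind(base, amb)
  cohort$patient_id <- sprintf("FIX%04d", seq_len(nrow(cohort)))

  cohort <- classify_cohort(cohort)
  group_mean <- c(`2U` = 11.8, `1U1D` = 11.4, `2D` = 6.5)
  .with_seed(seed, {
    # synthetic variant classes: upstream alleles are always truncating
    # (as observed in the cohort), downstream alleles ~60% PTV
    for (side in c("mut1", "mut2")) {
      reg <- cohort[[paste0(side, "_region")]]
      cohort[[paste0(side, "_class")]] <-
        ifelse(reg == "UPSTREAM", "PTV",
               ifelse(runif(nrow(cohort)) < 0.6, "PTV", "PAV"))
    }
    for (g in group_levels) {
      idx <- which(cohort$group == g)
      gp <- onset_gamma_params(group_mean[[g]], 13.4)
      x <- rgamma(length(idx), shape = gp$shape, rate = gp$rate)
      while (any(bad <- x > 72))
        x[bad] <- rgamma(sum(bad), shape = gp$shape, rate = gp$rate)
      cohort$onset_age_months[idx] <- round(x, 1)
    }
    cohort$onset_age_months[runif(nrow(cohort)) < 24 / 147] <- NA_real_
  })
  cohort[, .cohort_columns]
}
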