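# Patient data model and classification of CSB/ERCC6 mutations relative to
# the PiggyBac (PGBD3) insertion in intron 5 (NM_000124.3: c.1397+6912).

#' @keywords internal
.cs_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "csbayes_error", "error", "condition")))
}

#' Position of the PiggyBac insertion
#'
#' The PGBD3 transposon sits in intron 5 of *CSB/ERCC6*, at c.1397+6912:
#' coding exon 5 ends at c.1397, and the insertion point lies 6912
#' intronic bases downstream of it.
#'
#' @format A named list with `exon_boundary` (last coding base of exon 5,
#'   1397) and `intron_offset` (intronic offset of the insertion, 6912).
#' @export
piggybac_insertion <- list(exon_boundary = 1397L, intron_offset = 6912L)

#' Ordered severity levels and mutation-position groups
#'
#' Severity is ordered mild to severe: type III < type I < type II (type II
#' pools classical type II with COFS, the most severe presentations).
#' Mutation-position groups are `2U` (both alleles upstream of the
#' insertion), `1U1D` (one on each side) and `2D` (both downstream); `2U`
#' is the reference level in regression encodings.
#'
#' @name cs_levels
#' @export
severity_levels <- c("III", "I", "II")

#' @rdname cs_levels
#' @export
group_levels <- c("2U", "1U1D", "2D")

#' Construct a mutation descriptor
#'
#' A mutation is located either by a cDNA coordinate (1-based coding
#' position, HGVS c.-style, with an optional signed intronic offset) or by
#' a precomputed region label. If both are supplied they must agree once
#' the coordinate is classified.
#'
#' @param cdna Integer coding-sequence position (>= 1), or `NA`.
#' @param offset Signed integer intronic offset relative to `cdna`
#'   (non-zero when present), or `NA` for exonic positions.
#' @param region Optional precomputed label, `"UPSTREAM"` or `"DOWNSTREAM"`.
#' @param class Variant class: `"PTV"` (protein-truncating), `"PAV"`
#'   (protein-altering) or `"UNKNOWN"`.
#' @return An object of class `cs_mutation`.
#' @export
mutation <- function(cdna = NA, offset = NA, region = NA_character_,
                     class = "UNKNOWN") {
  cdna <- if (is.na(cdna)) NA_integer_ else as.integer(cdna)
  offset <- if (is.na(offset)) NA_integer_ else as.integer(offset)
  if (!is.na(region) && !region %in% c("UPSTREAM", "DOWNSTREAM"))
    .cs_error("region label must be UPSTREAM or DOWNSTREAM",
              "csbayes_malformed_record")
  if (!class %in% c("PTV", "PAV", "UNKNOWN"))
    .cs_error("variant class must be PTV, PAV or UNKNOWN",
              "csbayes_malformed_record")
  if (is.na(cdna) && is.na(region))
    .cs_error("mutation needs a cDNA coordinate or a region label",
              "csbayes_malformed_record")
  if (!is.na(cdna) && cdna < 1L)
    .cs_error("cdna position must be >= 1", "csbayes_malformed_record")
  if (!is.na(offset)) {
    if (is.na(cdna))
      .cs_error("intronic offset requires an exonic anchor position",
                "csbayes_malformed_record")
    if (offset == 0L)
      .cs_error("intronic offset must be non-zero", "csbayes_malformed_record")
  }
  structure(list(cdna = cdna, offset = offset, region = region, class = class),
            class = "cs_mutation")
}

# Vectorised classification backbone shared by classify_position() and the
# cohort-level wrappers.  Returns list(region, intron5_flag).
.classify_vec <- function(cdna, offset, region) {
  n <- max(length(cdna), length(offset), length(region))
  cdna <- rep_len(as.integer(cdna), n)
  offset <- rep_len(as.integer(offset), n)
  region <- rep_len(as.character(region), n)
  out <- rep(NA_character_, n)
  flag <- rep(FALSE, n)
  b <- piggybac_insertion$exon_boundary
  ins <- piggybac_insertion$intron_offset

  has_coord <- !is.na(cdna)
  # exonic coordinates: on or before the exon-5 boundary -> upstream
  exonic <- has_coord & is.na(offset)
  out[exonic] <- ifelse(cdna[exonic] <= b, "UPSTREAM", "DOWNSTREAM")
  # intronic coordinates: intron 5 is c.1397+N / c.1398-N; positions in it
  # are compared against the insertion offset and always flagged for review
  intronic <- has_coord & !is.na(offset)
  in5_fwd <- intronic & cdna == b & offset > 0L
  in5_rev <- intronic & cdna == (b + 1L) & offset < 0L
  out[in5_fwd] <- ifelse(offset[in5_fwd] <= ins, "UPSTREAM", "DOWNSTREAM")
  out[in5_rev] <- "DOWNSTREAM"
  flag[in5_fwd | in5_rev] <- TRUE
  other_intron <- intronic & !(in5_fwd | in5_rev)
  out[other_intron] <- ifelse(cdna[other_intron] <= b, "UPSTREAM", "DOWNSTREAM")

  has_label <- !is.na(region) & region != ""
  contradiction <- has_label & !is.na(out) & region != out
  if (any(contradiction))
    .cs_error(sprintf(
      "coordinate and region label disagree for %d record(s)",
      sum(contradiction)), "csbayes_consistency_error")
  out[is.na(out) & has_label] <- region[is.na(out) & has_label]
  if (anyNA(out))
    .cs_error("record lacks both a classifiable coordinate and a region label",
              "csbayes_malformed_record")
  list(region = out, intron5_flag = flag)
}

#' Classify a mutation upstream or downstream of the PiggyBac insertion
#'
#' Coding positions at or before c.1397 (exons 2-5) are upstream of the
#' insertion; positions from c.1398 on (exons 6-21) are downstream.
#' Intron-5 positions (c.1397+N) are compared against the insertion offset
#' itself: N <= 6912 classifies upstream, N > 6912 downstream, and either
#' way the result carries an `intron5_flag` attribute marking it for
#' review, because intron-5 variants sit between the exon-based groups.
#'
#' @param m A [mutation()] descriptor.
#' @return `"UPSTREAM"` or `"DOWNSTREAM"`, with attribute `intron5_flag`.
#' @export
#' @examples
#' classify_position(mutation(cdna = 1397))           # UPSTREAM
#' classify_position(mutation(cdna = 1398))           # DOWNSTREAM
#' classify_position(mutation(cdna = 1397, offset = 6913))  # DOWNSTREAM, flagged
classify_position <- function(m) {
  stopifnot(inherits(m, "cs_mutation"))
  r <- .classify_vec(m$cdna, m$offset, m$region)
  structure(r$region, intron5_flag = r$intron5_flag)
}

#' Classify a biallelic pair into a mutation-position group
#'
#' @param a,b [mutation()] descriptors for the two alleles.
#' @return A mutation-position group: `"2U"`, `"1U1D"` or `"2D"`.
#'   Symmetric in its arguments.
#' @export
classify_pair <- function(a, b) {
  pa <- classify_position(a)
  pb <- classify_position(b)
  n_up <- sum(c(pa, pb) == "UPSTREAM")
  c("2D", "1U1D", "2U")[n_up + 1L]
}

#' Group a pair of variant classes for the PTV/PAV analysis
#'
#' A patient with one protein-truncating and one protein-altering variant
#' is analysed in the PAV group, since the altering variant has the more
#' permissive consequence. Pairs involving an unknown class are returned
#' as `"UNKNOWN"` and excluded from complete-case variant analyses.
#'
#' @param a_class,b_class Variant classes (`"PTV"`, `"PAV"`, `"UNKNOWN"`);
#'   vectorised.
#' @return `"PTV_GROUP"`, `"PAV_GROUP"` or `"UNKNOWN"`.
#' @export
variant_group <- function(a_class, b_class) {
  ok <- c("PTV", "PAV", "UNKNOWN")
  if (!all(a_class %in% ok) || !all(b_class %in% ok))
    .cs_error("variant classes must be PTV, PAV or UNKNOWN",
              "csbayes_malformed_record")
  out <- rep("UNKNOWN", length(a_class))
  out[a_class == "PAV" | b_class == "PAV"] <- "PAV_GROUP"
  out[a_class == "PTV" & b_class == "PTV"] <- "PTV_GROUP"
  out
}

#' Map consequence keywords to PTV/PAV classes
#'
#' Opt-in helper for ingest: nonsense, frameshift and canonical-splice
#' consequences map to PTV; missense and in-frame changes to PAV.
#' Anything else is left UNKNOWN. The analysis itself always trusts the
#' input's variant-class column; consequence inference is never implicit.
#'
#' @param consequence Character vector of consequence keywords.
#' @return Character vector of classes.
#' @export
consequence_to_class <- function(consequence) {
  x <- tolower(as.character(consequence))
  out <- rep("UNKNOWN", length(x))
  out[grepl("nonsense|stop[_ ]?gain|frameshift|splice", x)] <- "PTV"
  out[grepl("missense|in[-_ ]?frame", x)] <- "PAV"
  out
}

.cohort_columns <- c("patient_id", "sex", "mut1_cdna", "mut1_offset",
                     "mut1_region", "mut1_class", "mut2_cdna", "mut2_offset",
                     "mut2_region", "mut2_class", "subtype",
                     "onset_age_months", "source")

.subtype_labels <- c("II", "COFS", "I", "III", "I_OR_II", "I_SLASH_II",
                     "UNCLASSIFIED")

#' Validate a cohort data frame
#'
#' Checks the cohort CSV/TSV dialect: one row per patient with columns
#' `patient_id`, `sex`, `mut1_cdna`, `mut1_offset`, `mut1_region`,
#' `mut1_class`, `mut2_cdna`, `mut2_offset`, `mut2_region`, `mut2_class`,
#' `subtype`, `onset_age_months`, `source`. Both mutation slots must be
#' populated (the cohort is biallelic by inclusion criteria) and onset
#' ages, when present, non-negative.
#'
#' @param cohort A data frame.
#' @return The cohort, invisibly, with columns coerced to canonical types.
#' @export
validate_cohort <- function(cohort) {
  missing_cols <- setdiff(.cohort_columns, names(cohort))
  if (length(missing_cols))
    .cs_error(paste("cohort is missing columns:",
                    paste(missing_cols, collapse = ", ")),
              "csbayes_schema_error")
  for (col in c("mut1_cdna", "mut1_offset", "mut2_cdna", "mut2_offset"))
    cohort[[col]] <- suppressWarnings(as.integer(cohort[[col]]))
  cohort$onset_age_months <- suppressWarnings(as.numeric(cohort$onset_age_months))
  bad_subtype <- !cohort$subtype %in% .subtype_labels
  if (any(bad_subtype))
    .cs_error(sprintf("invalid subtype label(s) in rows: %s",
                      paste(which(bad_subtype), collapse = ", ")),
              "csbayes_schema_error")
  for (side in c("mut1", "mut2")) {
    has_coord <- !is.na(cohort[[paste0(side, "_cdna")]])
    has_label <- !is.na(cohort[[paste0(side, "_region")]]) &
      cohort[[paste0(side, "_region")]] != ""
    if (any(!has_coord & !has_label))
      .cs_error(sprintf(
        "%s lacks both coordinate and region label in rows: %s", side,
        paste(which(!has_coord & !has_label), collapse = ", ")),
        "csbayes_malformed_record")
  }
  neg <- !is.na(cohort$onset_age_months) & cohort$onset_age_months < 0
  if (any(neg))
    .cs_error("negative onset ages are not allowed", "csbayes_schema_error")
  invisible(cohort)
}

#' Classify every patient's mutation-position and variant groups
#'
#' Adds `group` (factor, levels 2U < 1U1D < 2D), `intron5_flag` (TRUE when
#' either allele lies inside intron 5, see [classify_position()]) and
#' `vgroup` (PTV/PAV grouping) columns.
#'
#' @param cohort A validated cohort data frame.
#' @return The cohort with classification columns added.
#' @export
classify_cohort <- function(cohort) {
  cohort <- validate_cohort(cohort)
  c1 <- .classify_vec(cohort$mut1_cdna, cohort$mut1_offset, cohort$mut1_region)
  c2 <- .classify_vec(cohort$mut2_cdna, cohort$mut2_offset, cohort$mut2_region)
  n_up <- (c1$region == "UPSTREAM") + (c2$region == "UPSTREAM")
  cohort$group <- factor(c("2D", "1U1D", "2U")[n_up + 1L], levels = group_levels)
  cohort$intron5_flag <- c1$intron5_flag | c2$intron5_flag
  cohort$vgroup <- variant_group(cohort$mut1_class, cohort$mut2_class)
  cohort
}

#' Restrict a cohort to patients analyzable in the ordinal model
#'
#' Drops patients whose subtype label is ambiguous (`I_OR_II`,
#' `I_SLASH_II`) or `UNCLASSIFIED`, and maps `COFS` into the type II
#' class (the most severe presentations are pooled). The retained cohort
#' gains a `severity` column, an ordered factor III < I < II.
#'
#' @param cohort A cohort data frame (classified or not; classification
#'   columns are added if absent).
#' @return A list with `cohort` (the analyzable records) and `exclusions`
#'   (data frame of `patient_id`, `reason`). Applying the filter twice is
#'   a no-op.
#' @export
filter_analyzable <- function(cohort) {
  if (!"group" %in% names(cohort)) cohort <- classify_cohort(cohort)
  drop_reason <- c(I_OR_II = "ambiguous subtype (I or II)",
                   I_SLASH_II = "boundary subtype (I/II)",
                   UNCLASSIFIED = "unclassifiable subtype")
  excluded <- cohort$subtype %in% names(drop_reason)
  exclusions <- data.frame(
    patient_id = cohort$patient_id[excluded],
    reason = unname(drop_reason[cohort$subtype[excluded]]),
    stringsAsFactors = FALSE)
  kept <- cohort[!excluded, , drop = FALSE]
  subtype <- ifelse(kept$subtype == "COFS", "II", kept$subtype)
  kept$severity <- factor(subtype, levels = severity_levels, ordered = TRUE)
  rownames(kept) <- NULL
  list(cohort = kept, exclusions = exclusions)
}

#' Build the severity-by-genotype contingency table
#'
#' Counts analyzable patients by mutation-position group and severity
#' class. Rows are ordered 2U, 1U1D, 2D and columns II, I, III for report
#' parity with the study's presentation.
#'
#' @param cohort The `cohort` element returned by [filter_analyzable()].
#' @return A 3 x 3 integer matrix of counts.
#' @export
build_contingency <- function(cohort) {
  if (!"severity" %in% names(cohort))
    .cs_error("cohort must first pass filter_analyzable()",
              "csbayes_schema_error")
  tab <- table(group = factor(cohort$group, levels = group_levels),
               severity = factor(as.character(cohort$severity),
                                 levels = c("II", "I", "III")))
  m <- matrix(as.integer(tab), nrow = 3,
              dimnames = list(group = group_levels,
                              severity = c("II", "I", "III")))
  m
}

#' Read / write a cohort file
#'
#' Comma- or tab-separated per the file extension (`.tsv`/`.tab` means
#' tabs). Missing values are empty fields or `"NA"`.
#'
#' @param path File path.
#' @return `read_cohort()`: a validated cohort data frame.
#' @export
read_cohort <- function(path) {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("", "NA"),
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  validate_cohort(df)
}

#' @rdname read_cohort
#' @param cohort A cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(cohort[, intersect(c(.cohort_columns,
                                          "group", "severity"), names(cohort))],
                     path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
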