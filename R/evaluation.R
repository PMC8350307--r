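# Concordance and treatment-distribution statistics.

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.05 -> 0.1), matching how clinical
#' tables are conventionally printed; base `round()` rounds half to even.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  pow <- 10^digits
  sign(x) * floor(abs(x) * pow + 0.5) / pow
}

#' Concordance between engine and reference labels
#'
#' Fraction of positions where the engine's recommendation equals the
#' reference (specialist) decision. Counts are exact; the proportion is the
#' plain ratio, rounded only for display.
#'
#' @param engine_labels,reference_labels Equal-length non-empty character
#'   vectors.
#' @return List with `n_total`, `n_agree`, `proportion`.
#' @export
concordance <- function(engine_labels, reference_labels) {
  if (length(engine_labels) == 0L)
    stop("label vectors must be non-empty", call. = FALSE)
  if (length(engine_labels) != length(reference_labels))
    stop("label vectors must have equal length", call. = FALSE)
  n_agree <- sum(engine_labels == reference_labels)
  list(n_total = length(engine_labels), n_agree = n_agree,
       proportion = n_agree / length(engine_labels))
}

pct_block <- function(labels, levels, denom, digits = 1) {
  counts <- vapply(levels, function(l) sum(labels == l), integer(1))
  data.frame(therapy = levels, count = counts,
             pct = round_half_up(100 * counts / denom, digits),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Treatment-distribution table for a cohort
#'
#' Per-therapy counts and percentages within the acute subcohort (course
#' under 12 weeks), the chronic subcohort, and the overall
#' antibiotic-indicated fraction. Chronic therapies are pooled into INCS
#' versus antibiotic-indicated (antibiotic or macrolide trial), as the
#' published tables pool them. Percentages are rounded half-up to 1 decimal
#' within blocks and 2 decimals for the overall antibiotic fraction.
#'
#' @param cohort Cohort data.frame (needs `patient_id` and `duration_days`).
#' @param plans data.frame from [classify_patients()] aligned by
#'   `patient_id`.
#' @return List with `ars` and `crs` block data.frames and
#'   `overall_antibiotic` (count, pct).
#' @export
distribution_table <- function(cohort, plans) {
  if (!setequal(cohort$patient_id, plans$patient_id) ||
      nrow(cohort) != nrow(plans))
    stop("cohort and plans must align by patient_id", call. = FALSE)
  plans <- plans[match(cohort$patient_id, plans$patient_id), ]
  acute <- vapply(cohort$duration_days, classify_course, character(1)) == "ACUTE"

  ars <- pct_block(plans$therapy[acute],
                   c("DECONGESTANT", "DECONGESTANT_PLUS_INCS", "ANTIBIOTIC"),
                   denom = sum(acute))
  crs_lab <- ifelse(plans$antibiotic_indicated[!acute],
                    "ANTIBIOTIC_INDICATED", "INCS")
  crs <- pct_block(crs_lab, c("INCS", "ANTIBIOTIC_INDICATED"),
                   denom = sum(!acute))
  n_ab <- sum(plans$antibiotic_indicated)
  list(ars = ars, crs = crs,
       overall_antibiotic = list(
         count = n_ab,
         pct = round_half_up(100 * n_ab / nrow(plans), 2)))
}

#' Evaluate a labelled cohort against the rule engine
#'
#' Re-classifies every record from its raw symptom vector, recommends a
#' therapy, and compares with the cohort's reference labels: concordance,
#' the treatment-distribution blocks, and the reference-by-engine confusion
#' matrix.
#'
#' @param cohort Cohort data.frame with a `reference_label` column (from
#'   [generate_cohort()] or [read_cohort()]).
#' @param rs Rule set; defaults to the shipped EPOS 2012 rules.
#' @return Object of class `evaluation_report`.
#' @export
evaluate_cohort <- function(cohort, rs = epos_ruleset()) {
  if (is.null(cohort$reference_label))
    stop("cohort lacks a reference_label column", call. = FALSE)
  profiles <- df_to_profiles(cohort[, intersect(names(cohort),
                                                profile_fields)])
  plans <- classify_patients(profiles, rs)
  conc <- concordance(plans$therapy, cohort$reference_label)
  dist <- distribution_table(cohort, plans)
  confusion <- table(reference = cohort$reference_label,
                     engine = plans$therapy)
  structure(c(conc, dist,
              list(concordance_pct = round_half_up(100 * conc$proportion, 1),
                   confusion = confusion, plans = plans)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation report (n = ", x$n_total, ")\n", sep = "")
  cat(sprintf("  concordance: %d/%d = %.1f%%\n",
              x$n_agree, x$n_total, x$concordance_pct))
  cat("  acute subcohort (n = ", sum(x$ars$count), "):\n", sep = "")
  for (i in seq_len(nrow(x$ars)))
    cat(sprintf("    %-24s %5d  %5.1f%%\n",
                x$ars$therapy[i], x$ars$count[i], x$ars$pct[i]))
  cat("  chronic subcohort (n = ", sum(x$crs$count), "):\n", sep = "")
  for (i in seq_len(nrow(x$crs)))
    cat(sprintf("    %-24s %5d  %5.1f%%\n",
                x$crs$therapy[i], x$crs$count[i], x$crs$pct[i]))
  cat(sprintf("  overall antibiotic-indicated: %d  %.2f%%\n",
              x$overall_antibiotic$count, x$overall_antibiotic$pct))
  invisible(x)
}

#' Serialize an evaluation report
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- list(
    n_total = report$n_total, n_agree = report$n_agree,
    concordance = report$proportion,
    concordance_pct = report$concordance_pct,
    ars_block = report$ars, crs_block = report$crs,
    overall_antibiotic = report$overall_antibiotic,
    confusion = as.data.frame(report$confusion, stringsAsFactors = FALSE)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_report_json
#' @export
write_report_tsv <- function(report, path) {
  rows <- rbind(
    data.frame(block = "ARS", report$ars, stringsAsFactors = FALSE),
    data.frame(block = "CRS", report$crs, stringsAsFactors = FALSE),
    data.frame(block = "OVERALL", therapy = "ANTIBIOTIC_INDICATED",
               count = report$overall_antibiotic$count,
               pct = report$overall_antibiotic$pct,
               stringsAsFactors = FALSE),
    data.frame(block = "CONCORDANCE", therapy = "",
               count = report$n_agree, pct = report$concordance_pct,
               stringsAsFactors = FALSE)
  )
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
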