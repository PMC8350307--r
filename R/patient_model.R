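#' @keywords internal
"_PACKAGE"

# ---- vocabularies ----------------------------------------------------------

#' Diagnostic categories
#'
#' The six mutually exclusive diagnostic categories the engine can assign.
#' Acute presentations (course shorter than 12 weeks) fall into common cold,
#' post-viral acute rhinosinusitis (ARS) or acute bacterial rhinosinusitis
#' (ABRS); chronic presentations (12 weeks or longer) into chronic
#' rhinosinusitis (CRS), macrolide-eligible CRS (refractory, polyp-free, low
#' total IgE) or CRS with a postoperative purulent complication.
#'
#' @return Character vector of the six category names.
#' @export
diagnosis_categories <- function() {
  c("COMMON_COLD", "POST_VIRAL_ARS", "ABRS",
    "CRS", "CRS_MACROLIDE_ELIGIBLE", "CRS_COMPLICATION")
}

#' Therapy classes
#'
#' @return Character vector of the five therapy classes the recommender emits.
#' @export
therapy_classes <- function() {
  c("DECONGESTANT", "DECONGESTANT_PLUS_INCS", "ANTIBIOTIC",
    "INCS", "MACROLIDE_TRIAL")
}

tristate_levels <- c("yes", "no", "unknown")

# Column order of the patient record CSV schema.
profile_fields <- c(
  "patient_id", "duration_days", "worsening_after_day5",
  "discoloured_discharge", "discharge_unilateral",
  "severe_local_pain", "pain_unilateral",
  "fever_celsius", "inflammatory_markers_elevated", "two_stage_course",
  "nasal_polyps", "serum_ige_low", "refractory_to_incs",
  "postop_purulent_complication", "specialist_override_antibiotic"
)

profile_bool_fields <- c(
  "worsening_after_day5", "discoloured_discharge", "discharge_unilateral",
  "severe_local_pain", "pain_unilateral", "two_stage_course",
  "refractory_to_incs", "postop_purulent_complication",
  "specialist_override_antibiotic"
)

profile_tristate_fields <- c(
  "inflammatory_markers_elevated", "nasal_polyps", "serum_ige_low"
)

# ---- constructor & validation ----------------------------------------------

#' Construct a validated patient symptom profile
#'
#' One patient presentation: symptom duration, the five cardinal signs of
#' bacterial superinfection (discoloured/purulent discharge, severe local
#' pain, fever above 38 degrees C, raised ESR/CRP, two-stage course), and the
#' chronic-disease modifiers (nasal polyps, low total serum IgE,
#' refractoriness to intranasal corticosteroid, postoperative purulent
#' complication).
#'
#' Tri-state fields take `"yes"`, `"no"` or `"unknown"`; an unknown value
#' never satisfies a sign predicate, so missing laboratory data cannot push a
#' patient over the antibiotic threshold. The unilateral-predominance flags
#' qualify their parent sign and require it to be present; they do not count
#' as signs of their own.
#'
#' @param patient_id Opaque string identifier.
#' @param duration_days Non-negative integer, days since symptom onset.
#' @param worsening_after_day5 Logical; symptoms worsened after day 5
#'   (requires `duration_days >= 6`).
#' @param discoloured_discharge,discharge_unilateral Logical; coloured or
#'   purulent nasal secretion, and its one-sided predominance.
#' @param severe_local_pain,pain_unilateral Logical; severe facial/local
#'   pain, and its one-sided predominance.
#' @param fever_celsius Body temperature in degrees C in `[34, 43]`, or `NA`
#'   if not measured.
#' @param inflammatory_markers_elevated `"yes"`, `"no"` or `"unknown"`;
#'   raised erythrocyte sedimentation rate or CRP.
#' @param two_stage_course Logical; deterioration after a previous milder
#'   course ("double sickening").
#' @param nasal_polyps,serum_ige_low Tri-state chronic-disease modifiers.
#' @param refractory_to_incs Logical; chronic disease refractory to
#'   intranasal corticosteroid.
#' @param postop_purulent_complication Logical.
#' @param specialist_override_antibiotic Logical, evaluation-only: the
#'   reference label forces antibiotics for reasons outside the engine's
#'   inputs (e.g. immunosuppression).
#'
#' @return An object of class `symptom_profile` (a named list).
#' @examples
#' symptom_profile("p1", duration_days = 14,
#'                 discoloured_discharge = TRUE, fever_celsius = 38.6,
#'                 inflammatory_markers_elevated = "yes")
#' @export
symptom_profile <- function(patient_id,
                            duration_days,
                            worsening_after_day5 = FALSE,
                            discoloured_discharge = FALSE,
                            discharge_unilateral = FALSE,
                            severe_local_pain = FALSE,
                            pain_unilateral = FALSE,
                            fever_celsius = NA_real_,
                            inflammatory_markers_elevated = "unknown",
                            two_stage_course = FALSE,
                            nasal_polyps = "unknown",
                            serum_ige_low = "unknown",
                            refractory_to_incs = FALSE,
                            postop_purulent_complication = FALSE,
                            specialist_override_antibiotic = FALSE) {
  rec <- list(
    patient_id = patient_id,
    duration_days = duration_days,
    worsening_after_day5 = worsening_after_day5,
    discoloured_discharge = discoloured_discharge,
    discharge_unilateral = discharge_unilateral,
    severe_local_pain = severe_local_pain,
    pain_unilateral = pain_unilateral,
    fever_celsius = fever_celsius,
    inflammatory_markers_elevated = inflammatory_markers_elevated,
    two_stage_course = two_stage_course,
    nasal_polyps = nasal_polyps,
    serum_ige_low = serum_ige_low,
    refractory_to_incs = refractory_to_incs,
    postop_purulent_complication = postop_purulent_complication,
    specialist_override_antibiotic = specialist_override_antibiotic
  )
  validate_profile(rec)
}

#' Validate a raw patient record into a symptom profile
#'
#' Coerces a named list (or one-row data.frame) of raw field values into a
#' `symptom_profile`. `patient_id` and `duration_days` are required; absent
#' optional fields default to `FALSE` (booleans), `"unknown"` (tri-states) or
#' `NA` (fever). Booleans accept logicals or the strings `"true"`/`"false"`;
#' an empty fever cell is treated as not measured.
#'
#' Rejected with an error: negative or non-integer duration, fever outside
#' `[34, 43]` degrees C, worsening-after-day-5 with a duration under 6 days,
#' a unilateral flag without its parent sign, or a tri-state value outside
#' `{yes, no, unknown}`.
#'
#' @param record Named list or single-row data.frame of raw field values.
#' @return A validated `symptom_profile`. Validating an already-valid
#'   profile returns an equal profile (idempotence).
#' @export
validate_profile <- function(record) {
  if (is.data.frame(record)) {
    if (nrow(record) != 1L)
      stop("validate_profile() expects a single record", call. = FALSE)
    record <- as.list(record)
  }
  if (!is.list(record))
    stop("record must be a named list or one-row data.frame", call. = FALSE)

  extra <- setdiff(names(record), profile_fields)
  if (length(extra))
    stop("unknown field(s): ", paste(extra, collapse = ", "), call. = FALSE)
  for (f in c("patient_id", "duration_days"))
    if (is.null(record[[f]]) || length(record[[f]]) != 1L || is.na(record[[f]]))
      stop("missing required field: ", f, call. = FALSE)

  p <- list()
  p$patient_id <- as.character(record$patient_id)

  dur <- record$duration_days
  if (is.character(dur)) dur <- suppressWarnings(as.numeric(dur))
  if (!is.numeric(dur) || is.na(dur) || dur < 0 || dur != floor(dur))
    stop("invariant violated: duration_days must be a non-negative integer",
         call. = FALSE)
  p$duration_days <- as.integer(dur)

  for (f in profile_bool_fields)
    p[[f]] <- coerce_bool(record[[f]], f)

  fever <- record$fever_celsius
  if (is.null(fever) || length(fever) == 0L ||
      (is.character(fever) && !nzchar(trimws(fever)))) fever <- NA_real_
  fever <- suppressWarnings(as.numeric(fever))
  if (!is.na(fever) && (fever < 34 || fever > 43))
    stop("invariant violated: fever_celsius must lie in [34, 43] degrees C",
         call. = FALSE)
  p$fever_celsius <- fever

  for (f in profile_tristate_fields)
    p[[f]] <- coerce_tristate(record[[f]], f)

  if (p$worsening_after_day5 && p$duration_days < 6L)
    stop("invariant violated: worsening_after_day5 requires duration_days >= 6",
         call. = FALSE)
  if (p$discharge_unilateral && !p$discoloured_discharge)
    stop("invariant violated: discharge_unilateral requires discoloured_discharge",
         call. = FALSE)
  if (p$pain_unilateral && !p$severe_local_pain)
    stop("invariant violated: pain_unilateral requires severe_local_pain",
         call. = FALSE)

  structure(p[profile_fields], class = "symptom_profile")
}

coerce_bool <- function(x, field) {
  if (is.null(x) || length(x) == 0L || all(is.na(x))) return(FALSE)
  if (is.logical(x)) return(x[[1L]])
  if (is.character(x)) {
    v <- tolower(trimws(x[[1L]]))
    if (v %in% c("true", "t", "1")) return(TRUE)
    if (v %in% c("false", "f", "0", "")) return(FALSE)
  }
  if (is.numeric(x) && x[[1L]] %in% c(0, 1)) return(x[[1L]] == 1)
  stop("field ", field, ": cannot interpret ", deparse(x), " as boolean",
       call. = FALSE)
}

coerce_tristate <- function(x, field) {
  if (is.null(x) || length(x) == 0L || all(is.na(x))) return("unknown")
  v <- tolower(trimws(as.character(x[[1L]])))
  if (!nzchar(v)) return("unknown")
  if (!v %in% tristate_levels)
    stop("field ", field, ": value must be one of yes/no/unknown, got ",
         deparse(x), call. = FALSE)
  v
}

#' @export
print.symptom_profile <- function(x, ...) {
  cat("<symptom_profile> ", x$patient_id,
      " (", x$duration_days, " d)\n", sep = "")
  signs <- count_abrs_signs(x)
  cat("  course: ", classify_course(x$duration_days),
      ", cardinal signs: ", signs, "/5\n", sep = "")
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

#' Convert symptom profiles to a data.frame in the CSV schema
#'
#' @param profiles A `symptom_profile` or a list of them.
#' @return data.frame with the 15 schema columns, one row per profile.
#' @export
profiles_to_df <- function(profiles) {
  if (inherits(profiles, "symptom_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    as.data.frame(unclass(p), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

#' Convert a data.frame of patient records into symptom profiles
#'
#' @param df data.frame with (a subset of) the patient schema columns.
#' @return List of validated `symptom_profile` objects.
#' @export
df_to_profiles <- function(df) {
  lapply(seq_len(nrow(df)), function(i) validate_profile(df[i, , drop = FALSE]))
}

#' Read patient records from CSV or JSON
#'
#' CSV must carry the schema header (`patient_id,duration_days,...`) with
#' booleans as `true`/`false`, tri-states as `yes`/`no`/`unknown` and absent
#' fever as an empty cell. JSON is an array of objects with the same keys.
#'
#' @param path File path; format inferred from the extension unless given.
#' @param format `"csv"`, `"json"`, or `NULL` to infer.
#' @return List of validated `symptom_profile` objects.
#' @export
read_patients <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  df <- switch(match.arg(format, c("csv", "json")),
    csv = utils::read.csv(path, colClasses = "character", comment.char = "#",
                          check.names = FALSE, strip.white = TRUE),
    json = {
      x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
      if (!is.data.frame(x)) x <- as.data.frame(x, stringsAsFactors = FALSE)
      x
    })
  if (nrow(df) == 0L) stop("no patient records in ", path, call. = FALSE)
  df_to_profiles(df)
}

#' Write patient records as CSV
#'
#' @param profiles List of `symptom_profile` objects (or a cohort data.frame).
#' @param path Output path.
#' @export
write_patients <- function(profiles, path) {
  df <- if (is.data.frame(profiles)) profiles else profiles_to_df(profiles)
  utils::write.csv(format_record_df(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# lower-case true/false, empty string for missing fever: the on-disk dialect
format_record_df <- function(df) {
  for (f in intersect(names(df), profile_bool_fields))
    df[[f]] <- ifelse(df[[f]], "true", "false")
  if ("fever_celsius" %in% names(df))
    df$fever_celsius <- ifelse(is.na(df$fever_celsius), "",
                               format(df$fever_celsius, trim = TRUE))
  df
}
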