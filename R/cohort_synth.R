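# Synthetic cohort generator: raw symptom vectors drawn inside each
# diagnostic category's defining region, so the classifier (not the
# generator) determines every downstream label.

override_reasons <- c(
  "chronic immunosuppressive therapy",
  "anticancer treatment",
  "focus-of-infection search before transplantation/valve implantation",
  "recidivist with pathological ostiomeatal unit",
  "metachronous purulent infection"
)

#' Specify a synthetic cohort
#'
#' @param counts Named integer vector or list giving the number of patients
#'   per diagnostic category (names from [diagnosis_categories()]; omitted
#'   categories default to 0).
#' @param override_count Number of patients, drawn uniformly without
#'   replacement across the whole cohort, whose reference label is forced to
#'   `ANTIBIOTIC` by a specialist override (modelling decisions made on
#'   grounds outside the engine's inputs). Must not exceed the total count.
#' @param seed Integer seed; generation is fully reproducible given the spec.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(counts, override_count = 0L, seed = 1L) {
  counts <- unlist(counts)
  bad <- setdiff(names(counts), diagnosis_categories())
  if (length(bad))
    stop("unknown categor(ies): ", paste(bad, collapse = ", "), call. = FALSE)
  full <- stats::setNames(integer(6), diagnosis_categories())
  full[names(counts)] <- as.integer(counts)
  if (any(full < 0)) stop("counts must be non-negative", call. = FALSE)
  override_count <- as.integer(override_count)
  if (override_count < 0 || override_count > sum(full))
    stop("override_count must lie in [0, total count]", call. = FALSE)
  structure(list(counts = full, override_count = override_count,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' The study-replica cohort preset
#'
#' The published retrospective cohort structure: 622 acute presentations
#' (335 common cold, 186 post-viral, 101 bacterial) and 843 chronic ones
#' (830 plain CRS and 13 antibiotic-indicated CRS cases, split here 7
#' macrolide-eligible / 6 postoperative complication — the split within the
#' 13 is not published, only their total), 1465 patients in all.
#'
#' @param override_count,seed Passed to [cohort_spec()].
#' @return A `cohort_spec` totalling 1465 patients.
#' @export
study_replica_spec <- function(override_count = 0L, seed = 1L) {
  cohort_spec(c(COMMON_COLD = 335L, POST_VIRAL_ARS = 186L, ABRS = 101L,
                CRS = 830L, CRS_MACROLIDE_ELIGIBLE = 7L,
                CRS_COMPLICATION = 6L),
              override_count = override_count, seed = seed)
}

#' Read a cohort spec from JSON
#'
#' JSON object with `counts` (category to integer mapping), optional
#' `override_count` and `seed`.
#'
#' @param path Path to the JSON spec.
#' @return A `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  x <- jsonlite::fromJSON(path)
  cohort_spec(x$counts,
              override_count = if (is.null(x$override_count)) 0L
                               else x$override_count,
              seed = if (is.null(x$seed)) 1L else x$seed)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> n =", sum(x$counts),
      "| overrides =", x$override_count, "| seed =", x$seed, "\n")
  print(x$counts)
  invisible(x)
}

# ---- per-category sampling -------------------------------------------------

# draw k of the five cardinal signs and fill in the dependent fields
sample_signs <- function(k) {
  signs <- sample(c("discharge", "pain", "fever", "markers", "two_stage"), k)
  fever_sign <- "fever" %in% signs
  fever <- if (fever_sign) {
    x <- stats::runif(1, 38, 40.5)           # fever sign: strictly above 38
    if (x <= 38) 38.1 else x
  } else if (stats::runif(1) < 0.3) {
    NA_real_                                  # temperature not taken
  } else {
    stats::runif(1, 36.5, 38.0)
  }
  discharge <- "discharge" %in% signs
  pain <- "pain" %in% signs
  list(
    discoloured_discharge = discharge,
    discharge_unilateral = discharge && stats::runif(1) < 0.5,
    severe_local_pain = pain,
    pain_unilateral = pain && stats::runif(1) < 0.5,
    fever_celsius = fever,
    inflammatory_markers_elevated =
      if ("markers" %in% signs) "yes" else sample(c("no", "unknown"), 1),
    two_stage_course = "two_stage" %in% signs
  )
}

#' Sample one symptom profile from a diagnostic category
#'
#' Draws a raw symptom vector uniformly within the region that defines the
#' requested category and no higher-precedence one, so re-classifying the
#' profile recovers the generating category exactly. Uses the current RNG
#' state; seed management belongs to [generate_cohort()].
#'
#' Regions: common cold 1-10 days without worsening, 0-2 signs; post-viral
#' ARS meets the temporal criterion (11-83 days, or 6-10 days with
#' worsening) with 0-2 signs; ABRS likewise but with 3-5 signs; chronic
#' categories draw 84-365 days, with the macrolide triple (refractory,
#' polyp-free, low IgE) enforced, excluded, or dominated by a postoperative
#' complication as the category requires.
#'
#' @param category One of [diagnosis_categories()].
#' @param patient_id Identifier for the generated profile.
#' @return A validated `symptom_profile`.
#' @export
sample_profile <- function(category, patient_id = "synth") {
  category <- match.arg(category, diagnosis_categories())
  acute <- category %in% c("COMMON_COLD", "POST_VIRAL_ARS", "ABRS")

  if (acute) {
    if (category == "COMMON_COLD") {
      duration <- sample(1:10, 1)
      worsening <- FALSE
      k <- sample(0:2, 1)
    } else {
      # meet the temporal criterion by one of its two disjuncts
      if (stats::runif(1) < 0.5) {
        duration <- sample(11:83, 1)
        worsening <- stats::runif(1) < 0.2
      } else {
        duration <- sample(6:10, 1)
        worsening <- TRUE
      }
      k <- if (category == "ABRS") sample(3:5, 1) else sample(0:2, 1)
    }
    s <- sample_signs(k)
    return(symptom_profile(
      patient_id, duration_days = duration, worsening_after_day5 = worsening,
      discoloured_discharge = s$discoloured_discharge,
      discharge_unilateral = s$discharge_unilateral,
      severe_local_pain = s$severe_local_pain,
      pain_unilateral = s$pain_unilateral,
      fever_celsius = s$fever_celsius,
      inflammatory_markers_elevated = s$inflammatory_markers_elevated,
      two_stage_course = s$two_stage_course
    ))
  }

  duration <- sample(84:365, 1)
  s <- sample_signs(sample(0:2, 1))          # background signs, not decisive
  if (category == "CRS_COMPLICATION") {
    postop <- TRUE
    polyps <- sample(tristate_levels, 1)
    ige <- sample(tristate_levels, 1)
    refractory <- stats::runif(1) < 0.3
  } else if (category == "CRS_MACROLIDE_ELIGIBLE") {
    postop <- FALSE
    polyps <- "no"
    ige <- "yes"
    refractory <- TRUE
  } else {                                    # plain CRS
    postop <- FALSE
    polyps <- sample(tristate_levels, 1)
    ige <- sample(tristate_levels, 1)
    refractory <- stats::runif(1) < 0.3
    if (refractory && polyps == "no" && ige == "yes") refractory <- FALSE
  }
  symptom_profile(
    patient_id, duration_days = duration,
    worsening_after_day5 = stats::runif(1) < 0.2,
    discoloured_discharge = s$discoloured_discharge,
    discharge_unilateral = s$discharge_unilateral,
    severe_local_pain = s$severe_local_pain,
    pain_unilateral = s$pain_unilateral,
    fever_celsius = s$fever_celsius,
    inflammatory_markers_elevated = s$inflammatory_markers_elevated,
    two_stage_course = s$two_stage_course,
    nasal_polyps = polyps, serum_ige_low = ige,
    refractory_to_incs = refractory,
    postop_purulent_complication = postop
  )
}

# ---- cohort generation -----------------------------------------------------

#' Generate a synthetic cohort
#'
#' Draws exactly the requested number of raw symptom profiles per category,
#' attaches the generating category (`true_category`) and the guideline
#' reference label (`reference_label` = the therapy the category maps to),
#' then injects the requested number of specialist overrides: patients
#' chosen uniformly without replacement from those whose guideline label is
#' not already `ANTIBIOTIC` (an override models a specialist departing from
#' the guideline, so it must change the label), with the reference label
#' forced to `ANTIBIOTIC` and a free-text reason recorded. Overrides change
#' only the reference label, never the symptom vector the engine sees.
#' Byte-identical output for identical specs (RNG state is saved and
#' restored).
#'
#' @param spec A [cohort_spec()].
#' @return data.frame in the patient CSV schema plus `true_category`,
#'   `reference_label`, `override_reason`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(spec$seed)

  n_total <- sum(spec$counts)
  if (n_total == 0L) return(empty_cohort())

  profiles <- vector("list", n_total)
  true_cat <- character(n_total)
  i <- 0L
  for (cat in diagnosis_categories()) {
    for (j in seq_len(spec$counts[[cat]])) {
      i <- i + 1L
      profiles[[i]] <- sample_profile(cat, sprintf("synth-%05d", i))
      true_cat[i] <- cat
    }
  }
  df <- profiles_to_df(profiles)
  df$true_category <- true_cat
  df$reference_label <- vapply(true_cat,
                               function(cc) recommend(cc)$therapy, character(1))
  df$override_reason <- ""

  if (spec$override_count > 0L) {
    eligible <- which(df$reference_label != "ANTIBIOTIC")
    if (spec$override_count > length(eligible))
      stop("override_count exceeds the ", length(eligible),
           " patients not already labelled ANTIBIOTIC", call. = FALSE)
    idx <- eligible[sample(length(eligible), spec$override_count)]
    df$specialist_override_antibiotic[idx] <- TRUE
    df$reference_label[idx] <- "ANTIBIOTIC"
    df$override_reason[idx] <- sample(override_reasons, spec$override_count,
                                      replace = TRUE)
  }
  df
}

empty_cohort <- function() {
  df <- profiles_to_df(list(symptom_profile("x", 1L)))[0, , drop = FALSE]
  df$true_category <- character(0)
  df$reference_label <- character(0)
  df$override_reason <- character(0)
  df
}

#' Write / read a cohort CSV
#'
#' The patient schema plus `true_category,reference_label,override_reason`,
#' with booleans as `true`/`false` and absent fever as an empty cell.
#' Comment lines starting with `#` before the header record provenance
#' (notably the generation seed) and are skipped on reading.
#'
#' @param cohort Cohort data.frame from [generate_cohort()].
#' @param path File path.
#' @param seed Optional integer; recorded as a `# seed: <n>` header comment.
#' @return `write_cohort` returns the path invisibly; `read_cohort` the
#'   cohort data.frame with typed columns.
#' @export
write_cohort <- function(cohort, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  utils::write.table(format_record_df(cohort), con, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", comment.char = "#",
                        check.names = FALSE, strip.white = TRUE)
  df$duration_days <- as.integer(df$duration_days)
  for (f in intersect(names(df), profile_bool_fields))
    df[[f]] <- tolower(df[[f]]) == "true"
  if ("fever_celsius" %in% names(df))
    df$fever_celsius <- suppressWarnings(as.numeric(df$fever_celsius))
  df
}
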