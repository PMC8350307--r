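# Map each diagnostic category to its guideline therapy class.

therapy_map <- c(
  COMMON_COLD            = "DECONGESTANT",
  POST_VIRAL_ARS         = "DECONGESTANT_PLUS_INCS",
  ABRS                   = "ANTIBIOTIC",
  CRS                    = "INCS",
  CRS_MACROLIDE_ELIGIBLE = "MACROLIDE_TRIAL",
  CRS_COMPLICATION       = "ANTIBIOTIC"
)

antibiotic_therapies <- c("ANTIBIOTIC", "MACROLIDE_TRIAL")

#' Recommend a therapy class for a diagnosis
#'
#' Guideline mapping: common cold gets symptomatic decongestive therapy;
#' post-viral ARS adds an intranasal corticosteroid (INCS); ABRS and CRS
#' with a postoperative purulent complication get antibiotics; plain CRS
#' gets INCS as the drug of choice; refractory polyp-free CRS with low
#' total IgE gets a therapeutic macrolide trial. Therapy classes only —
#' no drug names, doses or durations.
#'
#' @param diagnosis A `diagnosis` object from [infer()], or a category name.
#' @return Object of class `treatment_plan` with `therapy` and
#'   `antibiotic_indicated` (true iff the therapy is an antibiotic or a
#'   macrolide trial).
#' @examples
#' recommend("CRS")            # INCS, no antibiotic
#' recommend("ABRS")$therapy   # "ANTIBIOTIC"
#' @export
recommend <- function(diagnosis) {
  category <- if (inherits(diagnosis, "diagnosis")) diagnosis$category
              else as.character(diagnosis)
  if (length(category) != 1L || !category %in% names(therapy_map))
    stop("unknown diagnostic category: ", paste(category, collapse = ", "),
         call. = FALSE)
  therapy <- unname(therapy_map[category])
  structure(list(therapy = therapy,
                 antibiotic_indicated = therapy %in% antibiotic_therapies),
            class = "treatment_plan")
}

#' @export
print.treatment_plan <- function(x, ...) {
  cat("<treatment_plan> ", x$therapy,
      if (x$antibiotic_indicated) "  (antibiotic indicated)", "\n", sep = "")
  invisible(x)
}

#' Classify patient records and recommend therapy
#'
#' End-to-end convenience over [infer()] and [recommend()]: one output row
#' per profile with the diagnosis, therapy class, antibiotic flag and the
#' ordered fired-rule log.
#'
#' @param profiles List of `symptom_profile` objects.
#' @param rs Rule set; defaults to the shipped EPOS 2012 rules.
#' @return data.frame with columns `patient_id`, `diagnosis`, `therapy`,
#'   `antibiotic_indicated`, `fired_rules` (rule ids joined by `;`).
#' @export
classify_patients <- function(profiles, rs = epos_ruleset()) {
  if (inherits(profiles, "symptom_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    d <- infer(p, rs)
    plan <- recommend(d)
    data.frame(patient_id = p$patient_id,
               diagnosis = d$category,
               therapy = plan$therapy,
               antibiotic_indicated = plan$antibiotic_indicated,
               fired_rules = paste(d$fired_rules, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
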