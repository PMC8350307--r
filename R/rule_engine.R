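# Forward-chaining inference over declarative if-then rules, plus the
# EPOS 2012 knowledge base and the diagnostic classification operations.

# ---- rule & ruleset --------------------------------------------------------

#' Construct an if-then rule
#'
#' A rule is a conjunction of antecedent fact tokens and a single consequent
#' fact asserted when all antecedents hold. Rules never retract facts, so
#' forward chaining is monotone and terminates at a unique fixpoint.
#'
#' @param id Unique rule identifier.
#' @param antecedent Character vector of fact tokens (conjunction).
#' @param consequent Single fact token asserted when the antecedent holds.
#' @param priority Integer; fired-rule logs are ordered by
#'   (priority ascending, id lexicographic).
#' @return Object of class `cds_rule`.
#' @export
rule <- function(id, antecedent, consequent, priority = 100L) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(antecedent), length(antecedent) >= 1L,
            is.character(consequent), length(consequent) == 1L)
  structure(list(id = id, antecedent = antecedent,
                 consequent = consequent, priority = as.integer(priority)),
            class = "cds_rule")
}

#' Construct a validated rule set
#'
#' @param rules List of [rule()] objects.
#' @param facts Character vector declaring the complete fact vocabulary
#'   (seed facts plus every derivable fact). Rules referencing undeclared
#'   facts are a configuration error.
#' @return Object of class `cds_ruleset`.
#' @export
ruleset <- function(rules, facts) {
  stopifnot(is.list(rules), is.character(facts))
  ids <- vapply(rules, function(r) r$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate rule id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  for (r in rules) {
    bad <- setdiff(c(r$antecedent, r$consequent), facts)
    if (length(bad))
      stop("rule '", r$id, "' references undeclared fact(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  ord <- order(vapply(rules, function(r) r$priority, integer(1)), ids)
  structure(list(rules = rules[ord], facts = facts), class = "cds_ruleset")
}

#' @export
print.cds_ruleset <- function(x, ...) {
  cat("<cds_ruleset> ", length(x$rules), " rules over ",
      length(x$facts), " facts\n", sep = "")
  for (r in x$rules)
    cat(sprintf("  [%3d] %-22s %s => %s\n", r$priority, r$id,
                paste(r$antecedent, collapse = " & "), r$consequent))
  invisible(x)
}

#' Read a rule set from a declarative JSON file
#'
#' The file carries `facts` (declared tokens) and `rules`, a list of
#' `{id, priority, if, then}` objects — the machine form of the knowledge
#' base, revisable without code changes.
#'
#' @param path Path to the JSON rule file.
#' @return A validated `cds_ruleset`.
#' @export
read_ruleset <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (is.null(x$facts) || is.null(x$rules))
    stop("rule file must have top-level 'facts' and 'rules'", call. = FALSE)
  rules <- lapply(x$rules, function(r)
    rule(r$id, unlist(r[["if"]]), r[["then"]],
         if (is.null(r$priority)) 100L else r$priority))
  ruleset(rules, unlist(x$facts))
}

#' The shipped EPOS 2012 rule set
#'
#' Loads the default knowledge base: acute presentations are split into
#' common cold, post-viral ARS and ABRS by the temporal criterion (more than
#' 10 days, or worsening after day 5) and the at-least-3-of-5 cardinal-sign
#' threshold; chronic presentations into CRS, macrolide-eligible CRS
#' (refractory, polyp-free, low total IgE) and CRS with postoperative
#' purulent complication.
#'
#' @return A `cds_ruleset`.
#' @export
epos_ruleset <- function() {
  read_ruleset(system.file("extdata", "epos2012_rules.json",
                           package = "eposcds", mustWork = TRUE))
}

# ---- seed predicates -------------------------------------------------------

#' Evaluate the primitive predicates of a profile into seed facts
#'
#' The rule language is purely conjunctive, so every predicate is seeded
#' together with its complement (e.g. `signs_ge_3` / `signs_lt_3`); rules
#' needing negation reference the complementary token. Unknown tri-states
#' seed the negative token: missing data never satisfies a sign.
#'
#' @param profile A `symptom_profile`.
#' @return Character vector of seed fact tokens.
#' @export
profile_facts <- function(profile) {
  stopifnot(inherits(profile, "symptom_profile"))
  course <- classify_course(profile$duration_days)
  c(
    if (course == "ACUTE") "course_acute" else "course_chronic",
    if (meets_abrs_temporal_criterion(profile))
      "temporal_criterion_met" else "temporal_criterion_not_met",
    if (count_abrs_signs(profile) >= 3L) "signs_ge_3" else "signs_lt_3",
    if (profile$postop_purulent_complication)
      "postop_complication" else "no_postop_complication",
    if (profile$refractory_to_incs) "refractory_to_incs" else "not_refractory",
    if (profile$nasal_polyps == "no") "polyps_absent" else "polyps_present_or_unknown",
    if (profile$serum_ige_low == "yes") "ige_low" else "ige_not_low_or_unknown"
  )
}

# ---- forward chaining ------------------------------------------------------

#' Run forward chaining to the monotone fixpoint
#'
#' Repeatedly fires every rule whose antecedent is contained in the current
#' fact set and whose consequent is not yet asserted, until no rule can fire.
#' Facts only accumulate, so the fixpoint exists, is unique, and is
#' independent of rule order; the fired-rule log is ordered by
#' (priority, rule id).
#'
#' @param x A `symptom_profile` (seed facts computed via [profile_facts()])
#'   or a character vector of seed fact tokens.
#' @param rs A `cds_ruleset`.
#' @return List with `facts` (sorted fact set at the fixpoint) and `fired`
#'   (ordered fired-rule identifiers).
#' @export
fire_rules <- function(x, rs) {
  stopifnot(inherits(rs, "cds_ruleset"))
  seeds <- if (inherits(x, "symptom_profile")) profile_facts(x)
           else as.character(x)
  bad <- setdiff(seeds, rs$facts)
  if (length(bad))
    stop("undeclared seed fact(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  facts <- seeds
  fired <- character(0)
  repeat {
    changed <- FALSE
    for (r in rs$rules) {           # rules pre-sorted by (priority, id)
      if (!(r$consequent %in% facts) && all(r$antecedent %in% facts)) {
        facts <- c(facts, r$consequent)
        fired <- c(fired, r$id)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(facts = sort(unique(facts)), fired = fired)
}

# ---- classification operations ---------------------------------------------

#' Classify the disease course from symptom duration
#'
#' Acute rhinosinusitis lasts less than 12 weeks; at 12 weeks (84 days) and
#' beyond the presentation is chronic. "Less than 12 weeks" is read as a
#' strict upper bound, so day 84 itself is chronic.
#'
#' @param duration_days Non-negative integer days.
#' @return `"ACUTE"` or `"CHRONIC"`.
#' @export
classify_course <- function(duration_days) {
  if (!is.numeric(duration_days) || is.na(duration_days) || duration_days < 0)
    stop("duration_days must be a non-negative number", call. = FALSE)
  if (duration_days < 84) "ACUTE" else "CHRONIC"
}

#' Count the cardinal signs of bacterial superinfection
#'
#' The five EPOS indicators: discoloured/purulent discharge, severe local
#' pain, fever strictly above 38 degrees C, raised ESR/CRP, and a two-stage
#' course. Unknown markers and unmeasured fever count as absent; the
#' unilateral-predominance flags qualify their sign but are not counted
#' separately.
#'
#' @param profile A `symptom_profile`.
#' @return Integer in `[0, 5]`.
#' @export
count_abrs_signs <- function(profile) {
  stopifnot(inherits(profile, "symptom_profile"))
  sum(
    profile$discoloured_discharge,
    profile$severe_local_pain,
    isTRUE(!is.na(profile$fever_celsius) && profile$fever_celsius > 38),
    profile$inflammatory_markers_elevated == "yes",
    profile$two_stage_course
  )
}

#' Temporal criterion for considering bacterial ARS
#'
#' True when acute symptoms have lasted more than 10 days, or have worsened
#' after day 5 of the illness. Both bounds are strict readings of the
#' guideline text; a 10-day uncomplicated course does not qualify.
#'
#' @param profile A `symptom_profile`.
#' @return Logical.
#' @export
meets_abrs_temporal_criterion <- function(profile) {
  stopifnot(inherits(profile, "symptom_profile"))
  profile$duration_days > 10L || profile$worsening_after_day5
}

category_facts <- c(
  common_cold = "COMMON_COLD", post_viral_ars = "POST_VIRAL_ARS",
  abrs = "ABRS", crs = "CRS",
  crs_macrolide_eligible = "CRS_MACROLIDE_ELIGIBLE",
  crs_complication = "CRS_COMPLICATION"
)

#' Infer the diagnostic category of a patient presentation
#'
#' Runs the forward chainer over the profile's seed facts and reads off the
#' single diagnostic category fact at the fixpoint. The shipped rule set
#' guarantees exactly one category per valid profile: chronic complications
#' outrank macrolide eligibility, and ABRS outranks post-viral ARS.
#'
#' @param profile A `symptom_profile`.
#' @param rs A `cds_ruleset`; defaults to the shipped EPOS 2012 rules.
#' @return Object of class `diagnosis` with `category` and `fired_rules`.
#' @examples
#' \dontrun{
#' p <- symptom_profile("p1", 14, discoloured_discharge = TRUE,
#'                      fever_celsius = 38.6, severe_local_pain = TRUE)
#' infer(p)  # ABRS
#' }
#' @export
infer <- function(profile, rs = epos_ruleset()) {
  res <- fire_rules(profile, rs)
  hit <- category_facts[names(category_facts) %in% res$facts]
  if (length(hit) != 1L)
    stop("rule set derived ", length(hit),
         " diagnostic categories (expected exactly 1) for patient ",
         profile$patient_id, call. = FALSE)
  structure(list(category = unname(hit), fired_rules = res$fired,
                 patient_id = profile$patient_id),
            class = "diagnosis")
}

#' @export
print.diagnosis <- function(x, ...) {
  cat("<diagnosis> ", x$patient_id, ": ", x$category,
      "  [", paste(x$fired_rules, collapse = ", "), "]\n", sep = "")
  invisible(x)
}
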