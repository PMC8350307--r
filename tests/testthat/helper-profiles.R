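# Build an acute profile with a given number of cardinal signs, added in a
# fixed order: discharge, pain, fever 38.6, markers, two-stage course.
acute_with_signs <- function(duration, nsigns, worsening = FALSE,
                             id = "t") {
  symptom_profile(
    id, duration_days = duration, worsening_after_day5 = worsening,
    discoloured_discharge = nsigns >= 1,
    severe_local_pain = nsigns >= 2,
    fever_celsius = if (nsigns >= 3) 38.6 else 37.0,
    inflammatory_markers_elevated = if (nsigns >= 4) "yes" else "no",
    two_stage_course = nsigns >= 5
  )
}

chronic_profile <- function(duration = 120, polyps = "unknown",
                            ige = "unknown", refractory = FALSE,
                            postop = FALSE, id = "t") {
  symptom_profile(id, duration_days = duration,
                  nasal_polyps = polyps, serum_ige_low = ige,
                  refractory_to_incs = refractory,
                  postop_purulent_complication = postop)
}
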