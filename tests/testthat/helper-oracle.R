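# Independent oracle: the diagnostic criteria written as one flat
# conditional over raw field values. Shares no code with the rule engine;
# any divergence between the two is a defect in one of them.
oracle_classify <- function(duration_days,
                            worsening_after_day5 = FALSE,
                            discoloured_discharge = FALSE,
                            severe_local_pain = FALSE,
                            fever_celsius = NA_real_,
                            inflammatory_markers_elevated = "unknown",
                            two_stage_course = FALSE,
                            nasal_polyps = "unknown",
                            serum_ige_low = "unknown",
                            refractory_to_incs = FALSE,
                            postop_purulent_complication = FALSE) {
  if (duration_days >= 84) {
    if (postop_purulent_complication) return("CRS_COMPLICATION")
    if (refractory_to_incs && nasal_polyps == "no" && serum_ige_low == "yes")
      return("CRS_MACROLIDE_ELIGIBLE")
    return("CRS")
  }
  signs <- sum(discoloured_discharge,
               severe_local_pain,
               !is.na(fever_celsius) && fever_celsius > 38,
               inflammatory_markers_elevated == "yes",
               two_stage_course)
  temporal <- duration_days > 10 || worsening_after_day5
  if (temporal && signs >= 3) return("ABRS")
  if (temporal) return("POST_VIRAL_ARS")
  "COMMON_COLD"
}
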