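{
  "name": "epos2012",
  "description": "EPOS 2012 diagnostic rules for rhinosinusitis. Seed facts are the evaluated profile predicates (each with its complement, since antecedents are pure conjunctions); derived facts are the six diagnostic categories. Chronic plain CRS needs three rules because 'not all macrolide conditions met' is a disjunction of the three complements.",
  "facts": [
    "course_acute", "course_chronic",
    "temporal_criterion_met", "temporal_criterion_not_met",
    "signs_ge_3", "signs_lt_3",
    "postop_complication", "no_postop_complication",
    "refractory_to_incs", "not_refractory",
    "polyps_absent", "polyps_present_or_unknown",
    "ige_low", "ige_not_low_or_unknown",
    "common_cold", "post_viral_ars", "abrs",
    "crs", "crs_macrolide_eligible", "crs_complication"
  ],
  "rules": [
    {
      "id": "R1_abrs",
      "priority": 10,
      "if": ["course_acute", "temporal_criterion_met", "signs_ge_3"],
      "then": "abrs"
    },
    {
      "id": "R2_post_viral",
      "priority": 20,
      "if": ["course_acute", "temporal_criterion_met", "signs_lt_3"],
      "then": "post_viral_ars"
    },
    {
      "id": "R3_common_cold",
      "priority": 30,
      "if": ["course_acute", "temporal_criterion_not_met"],
      "then": "common_cold"
    },
    {
      "id": "R4_crs_complication",
      "priority": 40,
      "if": ["course_chronic", "postop_complication"],
      "then": "crs_complication"
    },
    {
      "id": "R5_crs_macrolide",
      "priority": 50,
      "if": ["course_chronic", "no_postop_complication",
             "refractory_to_incs", "polyps_absent", "ige_low"],
      "then": "crs_macrolide_eligible"
    },
    {
      "id": "R6a_crs_not_refractory",
      "priority": 60,
      "if": ["course_chronic", "no_postop_complication", "not_refractory"],
      "then": "crs"
    },
    {
      "id": "R6b_crs_polyps",
      "priority": 61,
      "if": ["course_chronic", "no_postop_complication",
             "polyps_present_or_unknown"],
      "then": "crs"
    },
    {
      "id": "R6c_crs_ige",
      "priority": 62,
      "if": ["course_chronic", "no_postop_complication",
             "ige_not_low_or_unknown"],
      "then": "crs"
    }
  ]
}
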