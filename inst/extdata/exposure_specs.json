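{
  "version": 1,
  "note": "Per-exposure adjustment sets for the trajectory-association models. The footnote-to-exposure mapping is a documented assumption; edit freely. 'exposure_reference' null means: use the largest cohort level.",
  "specs": [
    {"exposure": "age_cat", "adjustment_set": [], "exposure_reference": "40-49"},
    {"exposure": "stage", "adjustment_set": ["age_cat"], "exposure_reference": "II"},
    {"exposure": "positive_nodes", "adjustment_set": ["age_cat"], "exposure_reference": null},
    {"exposure": "grade", "adjustment_set": ["age_cat"], "exposure_reference": "II"},
    {"exposure": "tumor_size", "adjustment_set": ["age_cat"], "exposure_reference": "<2cm"},
    {"exposure": "her2", "adjustment_set": ["age_cat"], "exposure_reference": "negative"},
    {"exposure": "chemotherapy", "adjustment_set": ["age_cat", "cci", "stage"], "exposure_reference": "yes"},
    {"exposure": "surgery_rt", "adjustment_set": ["age_cat", "cci", "stage", "cohabitation"], "exposure_reference": "lumpectomy"},
    {"exposure": "cci", "adjustment_set": ["age_cat", "education"], "exposure_reference": "0"},
    {"exposure": "prior_med_any", "adjustment_set": ["age_cat", "cci", "income", "cohabitation", "education"], "exposure_reference": "no"},
    {"exposure": "prior_med_psychoanaleptic", "adjustment_set": ["age_cat", "cci", "income", "cohabitation", "education"], "exposure_reference": "no"},
    {"exposure": "prior_med_psycholeptic", "adjustment_set": ["age_cat", "cci", "income", "cohabitation", "education"], "exposure_reference": "no"},
    {"exposure": "prior_med_thyroid", "adjustment_set": ["age_cat", "cci", "income", "cohabitation", "education"], "exposure_reference": "no"},
    {"exposure": "prior_med_hormonal_contraceptive", "adjustment_set": ["age_cat", "cci", "income", "cohabitation", "education"], "exposure_reference": "no"},
    {"exposure": "prior_med_analgesic", "adjustment_set": ["age_cat", "cci", "income", "cohabitation", "education"], "exposure_reference": "no"},
    {"exposure": "prior_med_diuretic_antihypertensive", "adjustment_set": ["age_cat", "cci", "income", "cohabitation", "education"], "exposure_reference": "no"},
    {"exposure": "prior_med_airway_antihistamine", "adjustment_set": ["age_cat", "cci", "income", "cohabitation", "education"], "exposure_reference": "no"}
  ]
}
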