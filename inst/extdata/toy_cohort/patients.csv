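patient_id,diagnosis_date,age_at_diagnosis,er_status
T01,0,45,positive
T02,0,44,positive
T03,0,46,positive
T04,0,43,positive
T05,0,57,positive
T06,0,45,positive
T07,0,45,positive
T08,0,45,positive
T09,0,45,positive
T10,0,45,negative
T11,0,45,positive
T12,0,45,positive
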