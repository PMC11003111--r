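patient_id,event_date,reason
T04,655,recurrence
T08,400,death
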