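patient_id,visit_date,aet_reported,therapy
T01,190,TRUE,TAM
T01,372,TRUE,TAM
T01,554,TRUE,TAM
T01,736,TRUE,TAM
T01,918,TRUE,TAM
T01,1100,TRUE,TAM
T01,1282,TRUE,TAM
T01,1464,TRUE,TAM
T01,1646,TRUE,TAM
T02,200,TRUE,TAM
T03,200,TRUE,TAM
T03,201,TRUE,TAM
T03,202,TRUE,TAM
T04,200,TRUE,TAM
T04,382,TRUE,TAM
T04,564,TRUE,TAM
T05,190,TRUE,TAM
T05,372,TRUE,TAM
T05,554,TRUE,TAM
T06,190,TRUE,AI
T06,372,TRUE,AI
T06,554,TRUE,AI
T07,-10,TRUE,TAM
T07,190,TRUE,TAM
T08,190,TRUE,TAM
T09,190,FALSE,TAM
T10,190,TRUE,TAM
T10,372,TRUE,TAM
T11,190,TRUE,TAM
T11,554,TRUE,TAM
T12,190,TRUE,TAM
T12,372,TRUE,AI
T12,554,TRUE,AI
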