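person_id,system,code,onset,abatement
F01,ICD10,U07.1,2020-06-01,
F02,ICD10,U07.1,2020-06-05,
F03,ICD10,U07.1,2020-06-03,
F05,ICD10,U07.1,2020-06-01,
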