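person_id,system,code,start,end
F01,SNOMED,57485005,2020-06-01T08:00:00,2020-06-10T20:00:00
F02,SNOMED,57485005,2020-06-05T08:00:00,2020-06-14T20:00:00
F03,SNOMED,57485005,2020-06-03T08:00:00,2020-06-12T20:00:00
F04,SNOMED,57485005,2020-06-01T08:00:00,2020-06-10T20:00:00
F05,SNOMED,57485005,2020-06-01T08:00:00,2020-06-10T20:00:00
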