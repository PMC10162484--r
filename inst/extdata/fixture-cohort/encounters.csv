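person_id,ward_type,start,end
F01,ICU,2020-06-01T08:00:00,2020-06-20T20:00:00
F02,ICU,2020-06-05T08:00:00,2020-06-18T20:00:00
F03,ICU,2020-06-03T08:00:00,2020-06-12T20:00:00
F04,ICU,2020-06-01T08:00:00,2020-07-05T20:00:00
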