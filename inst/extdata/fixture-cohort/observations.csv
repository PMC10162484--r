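person_id,system,code,value_num,value_unit,value_code,observed_at
F01,LOINC,2708-6,91.0,%,,2020-06-01T09:30:00
F02,LOINC,2708-6,88.5,%,,2020-06-05T10:00:00
F03,LOINC,2708-6,96.0,%,,2020-06-03T09:00:00
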