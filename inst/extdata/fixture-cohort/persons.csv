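person_id,birth_year,sex
F01,1955,female
F02,1948,male
F03,1960,female
F04,1972,male
F05,1939,female
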