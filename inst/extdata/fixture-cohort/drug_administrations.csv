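person_id,system,code,dose_value,dose_unit,administered_at
F01,ATC,H02AB02,1,mg,2020-06-01T09:00:00
F01,ATC,H02AB02,1,mg,2020-06-02T09:00:00
F01,ATC,H02AB02,1,mg,2020-06-03T09:00:00
F01,ATC,H02AB02,1,mg,2020-06-04T09:00:00
F01,ATC,H02AB02,1,mg,2020-06-05T09:00:00
F01,ATC,H02AB02,1,mg,2020-06-06T09:00:00
F01,ATC,H02AB02,1,mg,2020-06-07T09:00:00
F01,ATC,H02AB02,1,mg,2020-06-08T09:00:00
F01,ATC,H02AB02,1,mg,2020-06-09T09:00:00
F01,ATC,H02AB02,1,mg,2020-06-10T09:00:00
F02,ATC,H02AB02,3,mg,2020-06-05T09:00:00
F02,ATC,H02AB02,3,mg,2020-06-06T09:00:00
F02,ATC,H02AB02,3,mg,2020-06-07T09:00:00
F02,ATC,H02AB02,3,mg,2020-06-08T09:00:00
F02,ATC,H02AB02,3,mg,2020-06-09T09:00:00
F02,ATC,H02AB02,3,mg,2020-06-10T09:00:00
F02,ATC,H02AB02,3,mg,2020-06-11T09:00:00
F02,ATC,H02AB02,3,mg,2020-06-12T09:00:00
F02,ATC,H02AB02,3,mg,2020-06-13T09:00:00
F02,ATC,H02AB02,3,mg,2020-06-14T09:00:00
F03,ATC,H02AB02,1,mg,2020-06-03T09:00:00
F03,ATC,H02AB02,1,mg,2020-06-05T09:00:00
F03,ATC,H02AB02,1,mg,2020-06-06T09:00:00
F03,ATC,H02AB02,1,mg,2020-06-07T09:00:00
F03,ATC,H02AB02,1,mg,2020-06-08T09:00:00
F03,ATC,H02AB02,1,mg,2020-06-09T09:00:00
F03,ATC,H02AB02,1,mg,2020-06-10T09:00:00
F03,ATC,H02AB02,1,mg,2020-06-11T09:00:00
F03,ATC,H02AB02,1,mg,2020-06-12T09:00:00
F05,ATC,H02AB02,1,mg,2020-06-01T09:00:00
F05,ATC,H02AB02,1,mg,2020-06-02T09:00:00
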