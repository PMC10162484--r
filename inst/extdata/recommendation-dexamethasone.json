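{
  "id": "covid19-dexamethasone",
  "title": "Dexamethasone in critically ill COVID-19 patients requiring oxygen supply",
  "version": "1.0.0",
  "valid_from": "2020-06-16",
  "population": {
    "type": "combination",
    "operator": "ALL_OF",
    "negated": false,
    "members": [
      {
        "type": "criterion",
        "kind": "condition",
        "concept": {
          "system": "ICD10",
          "code": "U07.1",
          "display": "COVID-19"
        },
        "negated": false
      },
      {
        "type": "criterion",
        "kind": "procedure_active",
        "concept": {
          "system": "SNOMED",
          "code": "57485005",
          "display": "Oxygen therapy"
        },
        "negated": false
      }
    ]
  },
  "intervention": {
    "type": "combination",
    "operator": "ALL_OF",
    "negated": false,
    "members": [
      {
        "type": "criterion",
        "kind": "drug_administration",
        "concept": {
          "system": "ATC",
          "code": "H02AB02",
          "display": "Dexamethasone"
        },
        "negated": false,
        "dosage": {
          "dose": {
            "value": 1,
            "unit": {
              "system": "UCUM",
              "code": "mg"
            }
          },
          "frequency_per_day": 1,
          "duration_days": 10
        }
      }
    ]
  }
}
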