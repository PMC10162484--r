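{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "https://example.org/adhera/recommendation.schema.json",
  "title": "Guideline recommendation document",
  "description": "Declarative, terminology-coded representation of a single guideline recommendation: content metadata plus the population (P) and intervention (I) criterion trees of its PICO decomposition. Comparison and outcome elements are accepted but not used by the evaluation engine.",
  "type": "object",
  "required": ["id", "title", "version", "valid_from", "population", "intervention"],
  "properties": {
    "id": { "type": "string", "minLength": 1 },
    "title": { "type": "string", "minLength": 1 },
    "version": { "type": "string", "minLength": 1 },
    "valid_from": { "type": "string", "format": "date", "pattern": "^\\d{4}-\\d{2}-\\d{2}$" },
    "population": { "$ref": "#/definitions/combination" },
    "intervention": { "$ref": "#/definitions/combination" },
    "comparison": {},
    "outcome": {}
  },
  "definitions": {
    "concept": {
      "type": "object",
      "required": ["system", "code"],
      "properties": {
        "system": { "enum": ["ICD10", "SNOMED", "ATC", "LOINC", "UCUM"] },
        "code": { "type": "string", "minLength": 1 },
        "display": { "type": "string" }
      }
    },
    "quantity": {
      "type": "object",
      "required": ["value", "unit"],
      "properties": {
        "value": { "type": "number" },
        "unit": { "$ref": "#/definitions/concept" }
      }
    },
    "dosage": {
      "type": "object",
      "required": ["dose"],
      "properties": {
        "dose": { "$ref": "#/definitions/quantity" },
        "frequency_per_day": { "type": "integer", "minimum": 1 },
        "duration_days": {
          "oneOf": [
            { "type": "integer", "minimum": 1 },
            { "const": "unbounded" }
          ]
        }
      }
    },
    "criterion": {
      "type": "object",
      "required": ["kind", "concept"],
      "properties": {
        "type": { "const": "criterion" },
        "kind": {
          "enum": ["condition", "drug_administration", "observation",
                   "procedure_active", "episode_attribute"]
        },
        "concept": { "$ref": "#/definitions/concept" },
        "dosage": { "$ref": "#/definitions/dosage" },
        "comparator": {
          "type": "object",
          "required": ["op", "threshold"],
          "properties": {
            "op": { "enum": ["<", "<=", "=", ">=", ">"] },
            "threshold": { "$ref": "#/definitions/quantity" }
          }
        },
        "negated": { "type": "boolean" }
      }
    },
    "combination": {
      "type": "object",
      "required": ["operator", "members"],
      "properties": {
        "type": { "const": "combination" },
        "operator": { "enum": ["ALL_OF", "ANY_OF"] },
        "negated": { "type": "boolean" },
        "members": {
          "type": "array",
          "minItems": 1,
          "items": {
            "oneOf": [
              { "$ref": "#/definitions/criterion" },
              { "$ref": "#/definitions/combination" }
            ]
          }
        }
      }
    }
  }
}
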