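{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "YLL decomposition report",
  "description": "Report written by ylldecomp::write_report(format = 'json'). All burden quantities are in years of life lost per 1000 population; negative values mean reduced burden.",
  "type": "object",
  "required": [
    "labels", "yll0", "yll1", "delta_yll",
    "partial", "total", "residue_free", "percent", "warnings"
  ],
  "properties": {
    "labels": {
      "type": "array",
      "items": { "type": "string" },
      "minItems": 2,
      "maxItems": 2
    },
    "yll0": { "type": "number" },
    "yll1": { "type": "number" },
    "delta_yll": { "type": "number" },
    "partial": { "$ref": "#/definitions/approach" },
    "total": { "$ref": "#/definitions/approach" },
    "residue_free": { "$ref": "#/definitions/triple" },
    "percent": { "$ref": "#/definitions/nullable_triple" },
    "percent_rounded": { "$ref": "#/definitions/nullable_triple" },
    "warnings": {
      "type": "array",
      "items": { "type": "string" }
    }
  },
  "definitions": {
    "approach": {
      "type": "object",
      "required": ["age_structure", "death", "age_at_death", "death_rate", "residual"],
      "properties": {
        "age_structure": { "type": "number" },
        "death": { "type": "number" },
        "age_at_death": { "type": "number" },
        "death_rate": { "type": "number" },
        "residual": { "type": "number" }
      }
    },
    "triple": {
      "type": "object",
      "required": ["age_structure", "death_rate", "age_at_death"],
      "properties": {
        "age_structure": { "type": "number" },
        "death_rate": { "type": "number" },
        "age_at_death": { "type": "number" }
      }
    },
    "nullable_triple": {
      "type": "object",
      "required": ["age_structure", "death_rate", "age_at_death"],
      "properties": {
        "age_structure": { "type": ["number", "null"] },
        "death_rate": { "type": ["number", "null"] },
        "age_at_death": { "type": ["number", "null"] }
      }
    }
  }
}
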