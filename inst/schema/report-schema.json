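{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "methagree pipeline report",
  "type": "object",
  "required": ["header", "provenance", "dataset"],
  "properties": {
    "header": {
      "type": "object",
      "required": ["created"],
      "properties": {
        "created": { "type": "string" }
      }
    },
    "provenance": {
      "type": "object",
      "required": ["package_version", "r_version", "seed", "config", "config_hash"],
      "properties": {
        "package_version": { "type": "string" },
        "r_version": { "type": "string" },
        "seed": { "type": "integer" },
        "config": { "type": "object", "required": [] },
        "config_hash": { "type": "string" }
      }
    },
    "dataset": {
      "type": "object",
      "required": ["n_sites", "n_samples", "n_subjects", "methods"],
      "properties": {
        "n_sites": { "type": "integer" },
        "n_samples": { "type": "integer" },
        "n_subjects": { "type": "integer" },
        "methods": { "type": "array", "items": { "type": "string" } }
      }
    },
    "filter": {
      "type": "object",
      "required": ["counts"],
      "properties": {
        "counts": { "type": "object", "required": ["retained"] }
      }
    },
    "pca": {
      "type": "object",
      "required": ["variance_explained", "n_components"],
      "properties": {
        "variance_explained": { "type": "array", "items": { "type": "number" } },
        "n_components": { "type": "integer" }
      }
    }
  }
}
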