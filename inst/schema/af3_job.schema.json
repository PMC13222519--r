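{
  "$comment": "Schema for residuekit job specifications (AlphaFold3-style input with a namespaced customComponents extension). Version 1.",
  "type": "object",
  "required": ["name", "sequences"],
  "properties": {
    "name": { "type": "string" },
    "modelSeeds": {
      "type": "array",
      "minItems": 1,
      "items": { "type": "integer" }
    },
    "sequences": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["protein"],
        "properties": {
          "protein": {
            "type": "object",
            "required": ["id", "sequence"],
            "properties": {
              "id": { "type": "string", "pattern": "^[A-Za-z]+$" },
              "sequence": { "type": "string", "pattern": "^[A-ZX]+$" },
              "modifications": {
                "type": "array",
                "items": {
                  "type": "object",
                  "required": ["position", "componentId"],
                  "properties": {
                    "position": { "type": "integer" },
                    "componentId": {
                      "type": "string",
                      "pattern": "^[A-Z0-9]{1,3}$"
                    }
                  }
                }
              }
            }
          }
        }
      }
    },
    "customComponents": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["componentId", "csv"],
        "properties": {
          "componentId": { "type": "string", "pattern": "^[A-Z0-9]{3}$" },
          "csv": { "type": "string" }
        }
      }
    }
  }
}
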