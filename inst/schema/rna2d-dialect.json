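{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "rnasketch RNA 2D document dialect",
  "type": "object",
  "required": ["rnaComplexes", "classes"],
  "properties": {
    "rnaComplexes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name", "rnaMolecules"],
        "properties": {
          "name": {"type": "string"},
          "rnaMolecules": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["name", "sequence", "basePairs", "labels"],
              "properties": {
                "name": {"type": "string"},
                "sequence": {
                  "type": "array",
                  "items": {
                    "type": "object",
                    "required": ["residueName", "residueIndex", "x", "y"],
                    "properties": {
                      "residueName": {"type": "string"},
                      "residueIndex": {"type": "integer", "minimum": 1},
                      "x": {"type": "number"},
                      "y": {"type": "number"},
                      "styleClass": {"type": "string"}
                    }
                  }
                },
                "basePairs": {
                  "type": "array",
                  "items": {
                    "type": "object",
                    "required": ["residueIndex1", "residueIndex2", "lw", "predicted"],
                    "properties": {
                      "residueIndex1": {"type": "integer", "minimum": 1},
                      "residueIndex2": {"type": "integer", "minimum": 1},
                      "lw": {
                        "type": "string",
                        "pattern": "^(canonical|[ct][WHS][WHS])$"
                      },
                      "predicted": {"type": "boolean"}
                    }
                  }
                },
                "labels": {
                  "type": "array",
                  "items": {
                    "type": "object",
                    "required": ["residueIndex", "label"],
                    "properties": {
                      "residueIndex": {"type": "integer", "minimum": 1},
                      "label": {"type": "string"}
                    }
                  }
                }
              }
            }
          }
        }
      }
    },
    "classes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name", "colour", "fontSize", "visibility"],
        "properties": {
          "name": {"type": "string"},
          "colour": {"type": "string"},
          "fontSize": {"type": "number"},
          "visibility": {"type": "string", "enum": ["visible", "hidden"]}
        }
      }
    }
  }
}
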