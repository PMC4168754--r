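{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "gpmlgraph node-link graph",
  "type": "object",
  "required": ["nodes", "edges"],
  "properties": {
    "nodes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "kind"],
        "properties": {
          "id": {"type": "string"},
          "kind": {"enum": ["molecule", "group", "connector", "annotation"]},
          "style": {"type": "object"}
        }
      }
    },
    "edges": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "source", "target", "interaction_type", "directed"],
        "properties": {
          "id": {"type": "string"},
          "source": {"type": "string"},
          "target": {"type": "string"},
          "interaction_type": {"type": "string"},
          "directed": {"type": "boolean"},
          "style": {"type": "object"}
        }
      }
    }
  }
}
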