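{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "OntoRelCat mapping catalog",
  "type": "object",
  "required": ["schema", "entries"],
  "properties": {
    "schema": { "type": "string" },
    "entries": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["construct_iri", "construct_kind", "relational_kind", "relational_id"],
        "properties": {
          "construct_iri": { "type": "string" },
          "construct_kind": {
            "enum": ["class", "object_property", "data_property", "class_axiom",
                     "data_axiom", "property_axiom", "datatype", "generated_class"]
          },
          "relational_kind": {
            "enum": ["relation", "referential_key", "domain", "constraint"]
          },
          "relational_id": { "type": "string" },
          "extra": { "type": "string" }
        }
      }
    }
  }
}
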