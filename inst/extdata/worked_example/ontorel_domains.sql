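-- SQL domains for schema ontorel
CREATE SCHEMA IF NOT EXISTS "ontorel";
SET search_path = "ontorel";
CREATE DOMAIN "iid_type" AS uuid;
CREATE DOMAIN "xsd:String" AS TEXT;
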