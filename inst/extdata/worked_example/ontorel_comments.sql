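-- Construct documentation for schema ontorel
SET search_path = "ontorel";
COMMENT ON TABLE "prescription" IS 'A document that directs the administration or dispensing of drugs to a patient. [rxo:Prescription]';
COMMENT ON TABLE "rxo_GEN_0001" IS 'Generated class representing the expression (http://example.org/rxonto#DrugAdministrationSpecification ⊔ http://example.org/rxonto#DrugDispensingSpecification) [rxo:GEN_0001]';
COMMENT ON TABLE "has_part" IS 'Relates a whole document to one of its parts. [rxo:hasPart]';
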