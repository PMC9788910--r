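-- Referential keys for schema ontorel
SET search_path = "ontorel";
ALTER TABLE "drug_administration_specification" ADD CONSTRAINT "drug_administration_specification_isa_document_part" FOREIGN KEY ("rxo_DrugAdministrationSpecification_iid") REFERENCES "document_part" ("rxo_DocumentPart_iid");
ALTER TABLE "drug_dispensing_specification" ADD CONSTRAINT "drug_dispensing_specification_isa_document_part" FOREIGN KEY ("rxo_DrugDispensingSpecification_iid") REFERENCES "document_part" ("rxo_DocumentPart_iid");
ALTER TABLE "drug_administration_specification" ADD CONSTRAINT "drug_administration_specification_isa_rxo_GEN_0001" FOREIGN KEY ("rxo_DrugAdministrationSpecification_iid") REFERENCES "rxo_GEN_0001" ("rxo_GEN_0001_iid");
ALTER TABLE "drug_dispensing_specification" ADD CONSTRAINT "drug_dispensing_specification_isa_rxo_GEN_0001" FOREIGN KEY ("rxo_DrugDispensingSpecification_iid") REFERENCES "rxo_GEN_0001" ("rxo_GEN_0001_iid");
ALTER TABLE "prescription" ADD CONSTRAINT "prescription_isa_Thing" FOREIGN KEY ("rxo_Prescription_iid") REFERENCES "Thing" ("Thing_iid");
ALTER TABLE "document_part" ADD CONSTRAINT "document_part_isa_Thing" FOREIGN KEY ("rxo_DocumentPart_iid") REFERENCES "Thing" ("Thing_iid");
ALTER TABLE "rxo_GEN_0001" ADD CONSTRAINT "rxo_GEN_0001_isa_Thing" FOREIGN KEY ("rxo_GEN_0001_iid") REFERENCES "Thing" ("Thing_iid");
ALTER TABLE "prescription_has_part_rxo_GEN_0001" ADD CONSTRAINT "prescription_has_part_rxo_GEN_0001_domain" FOREIGN KEY ("rxo_Prescription_iid") REFERENCES "prescription" ("rxo_Prescription_iid");
ALTER TABLE "prescription_has_part_rxo_GEN_0001" ADD CONSTRAINT "prescription_has_part_rxo_GEN_0001_range" FOREIGN KEY ("rxo_GEN_0001_iid") REFERENCES "rxo_GEN_0001" ("rxo_GEN_0001_iid");
ALTER TABLE "prescription_has_part_rxo_GEN_0001" ADD CONSTRAINT "prescription_has_part_rxo_GEN_0001_op" FOREIGN KEY ("rxo_Prescription_iid", "rxo_GEN_0001_iid") REFERENCES "has_part" ("subject_iid", "object_iid");
ALTER TABLE "prescription_date_signed" ADD CONSTRAINT "prescription_date_signed_dp" FOREIGN KEY ("rxo_Prescription_iid") REFERENCES "prescription" ("rxo_Prescription_iid");
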