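-- en label views for schema ontorel
SET search_path = "ontorel";
CREATE VIEW "v_en_Thing" AS SELECT "Thing_iid" AS "Thing_iid" FROM "Thing";
CREATE VIEW "v_en_prescription" AS SELECT "rxo_Prescription_iid" AS "prescription_iid" FROM "prescription";
CREATE VIEW "v_en_document_part" AS SELECT "rxo_DocumentPart_iid" AS "document_part_iid" FROM "document_part";
CREATE VIEW "v_en_drug_administration_specification" AS SELECT "rxo_DrugAdministrationSpecification_iid" AS "drug_administration_specification_iid" FROM "drug_administration_specification";
CREATE VIEW "v_en_drug_dispensing_specification" AS SELECT "rxo_DrugDispensingSpecification_iid" AS "drug_dispensing_specification_iid" FROM "drug_dispensing_specification";
CREATE VIEW "v_en_rxo_GEN_0001" AS SELECT "rxo_GEN_0001_iid" AS "rxo_GEN_0001_iid" FROM "rxo_GEN_0001";
CREATE VIEW "v_en_has_part" AS SELECT "subject_iid" AS "subject_iid", "object_iid" AS "object_iid" FROM "has_part";
CREATE VIEW "v_en_prescription_has_part_rxo_GEN_0001" AS SELECT "rxo_Prescription_iid" AS "prescription_iid", "rxo_GEN_0001_iid" AS "rxo_GEN_0001_iid" FROM "prescription_has_part_rxo_GEN_0001";
CREATE VIEW "v_en_prescription_date_signed" AS SELECT "rxo_Prescription_iid" AS "prescription_iid", "date_signed" AS "date_signed" FROM "prescription_date_signed";
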