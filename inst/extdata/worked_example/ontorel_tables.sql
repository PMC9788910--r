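-- Tables for schema ontorel (dependency order)
SET search_path = "ontorel";
CREATE TABLE "Thing" (
  "Thing_iid" "iid_type" NOT NULL,
  PRIMARY KEY ("Thing_iid")
);
CREATE TABLE "has_part" (
  "subject_iid" "iid_type" NOT NULL,
  "object_iid" "iid_type" NOT NULL,
  PRIMARY KEY ("subject_iid", "object_iid")
);
CREATE TABLE "prescription" (
  "rxo_Prescription_iid" "iid_type" NOT NULL,
  PRIMARY KEY ("rxo_Prescription_iid")
);
CREATE TABLE "document_part" (
  "rxo_DocumentPart_iid" "iid_type" NOT NULL,
  PRIMARY KEY ("rxo_DocumentPart_iid")
);
CREATE TABLE "rxo_GEN_0001" (
  "rxo_GEN_0001_iid" "iid_type" NOT NULL,
  PRIMARY KEY ("rxo_GEN_0001_iid")
);
CREATE TABLE "drug_administration_specification" (
  "rxo_DrugAdministrationSpecification_iid" "iid_type" NOT NULL,
  PRIMARY KEY ("rxo_DrugAdministrationSpecification_iid")
);
CREATE TABLE "drug_dispensing_specification" (
  "rxo_DrugDispensingSpecification_iid" "iid_type" NOT NULL,
  PRIMARY KEY ("rxo_DrugDispensingSpecification_iid")
);
CREATE TABLE "prescription_has_part_rxo_GEN_0001" (
  "rxo_Prescription_iid" "iid_type" NOT NULL,
  "rxo_GEN_0001_iid" "iid_type" NOT NULL,
  PRIMARY KEY ("rxo_Prescription_iid", "rxo_GEN_0001_iid")
);
CREATE TABLE "prescription_date_signed" (
  "rxo_Prescription_iid" "iid_type" NOT NULL,
  "date_signed" "xsd:String" NOT NULL,
  PRIMARY KEY ("rxo_Prescription_iid", "date_signed")
);
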