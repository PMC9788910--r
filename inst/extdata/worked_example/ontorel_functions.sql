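-- Constraint verification routines for schema ontorel
SET search_path = "ontorel";
CREATE FUNCTION "qc_prescription_has_part_rxo_GEN_0001"() RETURNS TABLE (iid "iid_type", observed bigint) AS $$
SELECT c."rxo_Prescription_iid" AS iid, count(r."rxo_Prescription_iid") AS observed
FROM "prescription" c LEFT JOIN "prescription_has_part_rxo_GEN_0001" r ON r."rxo_Prescription_iid" = c."rxo_Prescription_iid"
GROUP BY c."rxo_Prescription_iid"
HAVING count(r."rxo_Prescription_iid") < 1
$$ LANGUAGE sql STABLE;
CREATE FUNCTION "qc_prescription_date_signed"() RETURNS TABLE (iid "iid_type", observed bigint) AS $$
SELECT c."rxo_Prescription_iid" AS iid, count(r."rxo_Prescription_iid") AS observed
FROM "prescription" c LEFT JOIN "prescription_date_signed" r ON r."rxo_Prescription_iid" = c."rxo_Prescription_iid"
GROUP BY c."rxo_Prescription_iid"
HAVING count(r."rxo_Prescription_iid") < 1 OR count(r."rxo_Prescription_iid") > 1
$$ LANGUAGE sql STABLE;
CREATE FUNCTION "mc_union_rxo_GEN_0001"() RETURNS TABLE (iid "iid_type", observed bigint) AS $$
SELECT t."rxo_GEN_0001_iid" AS iid, 0 AS observed FROM "rxo_GEN_0001" t WHERE NOT (EXISTS (SELECT 1 FROM "drug_administration_specification" o WHERE o."rxo_DrugAdministrationSpecification_iid" = t."rxo_GEN_0001_iid") OR EXISTS (SELECT 1 FROM "drug_dispensing_specification" o WHERE o."rxo_DrugDispensingSpecification_iid" = t."rxo_GEN_0001_iid"))
UNION
SELECT t."rxo_DrugAdministrationSpecification_iid" AS iid, 0 AS observed FROM "drug_administration_specification" t WHERE NOT EXISTS (SELECT 1 FROM "rxo_GEN_0001" o WHERE o."rxo_GEN_0001_iid" = t."rxo_DrugAdministrationSpecification_iid")
UNION
SELECT t."rxo_DrugDispensingSpecification_iid" AS iid, 0 AS observed FROM "drug_dispensing_specification" t WHERE NOT EXISTS (SELECT 1 FROM "rxo_GEN_0001" o WHERE o."rxo_GEN_0001_iid" = t."rxo_DrugDispensingSpecification_iid")
$$ LANGUAGE sql STABLE;
CREATE FUNCTION "verification_report"() RETURNS TABLE (constraint_name text, iid "iid_type", observed bigint, min_required bigint, max_allowed bigint) AS $$
SELECT 'qc_prescription_has_part_rxo_GEN_0001' AS constraint_name, f.iid, f.observed, 1::bigint AS min_required, NULL::bigint AS max_allowed FROM "qc_prescription_has_part_rxo_GEN_0001"() f
UNION ALL
SELECT 'qc_prescription_date_signed' AS constraint_name, f.iid, f.observed, 1::bigint AS min_required, 1::bigint AS max_allowed FROM "qc_prescription_date_signed"() f
UNION ALL
SELECT 'mc_union_rxo_GEN_0001' AS constraint_name, f.iid, f.observed, NULL::bigint AS min_required, NULL::bigint AS max_allowed FROM "mc_union_rxo_GEN_0001"() f
$$ LANGUAGE sql STABLE;
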