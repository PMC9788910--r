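# ontorelforge

Compile an OWL 2 ontology into a highly normalized relational schema that
preserves the ontology's semantics — and a bidirectional mapping catalog
that ties every table, key, domain and constraint back to the class,
property or axiom it implements.

Biomedical and clinical data are described by formal ontologies (OBO-style
classes, object/data properties, quantified axioms, annotations) but stored
in relational databases whose structure rarely documents that semantics.
`ontorelforge` derives the database *from* the ontology, uniformly, one
relational construct per ontological construct:

| ontological construct | relational construct |
|---|---|
| class `C` | relation `C(C_iid)` with `C_iid` as primary key |
| universal class | root relation `Thing` holding every identifier |
| object property `p` | relation `p(subject_iid, object_iid)`, PK on the pair |
| inheritance `C0 ⊑ C1`, `p0 ⊑ p1` | *isa* foreign key from sub- to super-relation |
| association `C0 p[min..max] C1` | association relation + 3 foreign keys (domain class, range class, property) + a cardinality verification function when `min > 0` or `max` is finite |
| data association `C0 dp[qt] D` | data relation `(C0_iid, value)` + 1 foreign key |
| datatype `D` | SQL domain, e.g. `CREATE DOMAIN "xsd:String" AS TEXT` |
| annotation | SQL comment + per-language label views |
| individual | (optional) tuples sharing one GUID across its class relations |

Complex axioms — unions `⊔`, intersections `⊓`, nested quantified
restrictions — are first rewritten to the simple form
`identifier operator identifier` by a recursive reduction: each
sub-expression is replaced by a uniquely named generated class `Z`
accompanied by simple subclass axioms (`A ⊑ Z`, `B ⊑ Z` for a union;
`Z ⊑ A`, `Z ⊑ B` for an intersection) and a membership constraint pinning
`ext(Z)` to the exact union/intersection, emitted as an on-demand
verification function. Identical sub-expressions deduplicate to one class;
reduction is idempotent and byte-stable. The reduction rules are validated
in the test suite by exhaustive enumeration of all interpretations on small
models, not assumed.

## Worked example

The built-in worked example is a drug-prescription mini ontology: a
prescription document, two document parts (drug administration / dispensing
specifications), a `has_part` property, one data property, and **one complex
axiom** — every prescription has some part that is an administration or a
dispensing specification:

```r
library(ontorelforge)

we <- worked_example()
input <- tempfile(fileext = ".ofn")
writeLines(we$text, input)

report <- run_pipeline(input, "out/")
print(report)
#> Pipeline run report
#>   relations: 9  referential keys: 11  domains: 2
#>   quantification constraints: 2  membership constraints: 1  comments: 3
#>   warnings: 0  outputs: 9 files  elapsed: 0.05s
```

The 9 relations are `Thing`, the four class relations, the generated class
`rxo_GEN_0001` standing for the union *administration ⊔ dispensing*, the
`has_part` property relation, one association relation and one data
relation. The 11 referential keys are the four subclass keys (two into
`document_part`, two into the generated class), three root-class keys into
`Thing`, the three association keys and the data key. The two
quantification constraints check `has_part [1..*]` and `date_signed [1..1]`;
the single membership constraint verifies that the generated class equals
the union of its two operands.

The emitted scripts (`out/ontorel_domains.sql`, `_tables.sql`, `_keys.sql`,
`_functions.sql`, `_comments.sql`, `_views_en.sql`) begin with:

```sql
CREATE DOMAIN "iid_type" AS uuid;
CREATE DOMAIN "xsd:String" AS TEXT;

CREATE TABLE "prescription" (
  "rxo_Prescription_iid" "iid_type" NOT NULL,
  PRIMARY KEY ("rxo_Prescription_iid")
);
```

alongside `out/ontorel_ontorelcat.json` (the mapping catalog; one entry per
converted construct, round-tripping IRI → relational identifier → IRI) and
`out/ontorel_reduced.ofn` (the post-reduction normalized ontology).

A command-line front end wraps the same pipeline:

```sh
Rscript inst/cli/ontorel-forge.R generate --input onto.owl --out-dir out/ \
    --schema myschema --dialect postgresql --languages en,fr
Rscript inst/cli/ontorel-forge.R fixtures --out-dir fx/ --classes 5 \
    --associations 3 --seed 7
```

Input formats: RDF/XML and OWL functional-style syntax (local imports are
resolved transitively). Turtle is not supported. Configuration is plain
YAML (`read_ontology_config()`, `read_rdb_config()`); see the methods
vignette (`vignettes/ontology-to-relational.Rmd`) for every parameter, the
reduction rules in detail, and the design decisions.

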