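Package: ontorelforge
Title: Compile OWL Ontologies into Normalized Relational Schemas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts an OWL 2 ontology into a highly normalized relational
    schema that preserves ontological semantics. Classes, object properties,
    inheritance axioms, quantified association axioms, datatypes and
    annotations become relations, referential keys, SQL domains, verification
    functions and comments. Complex class expressions (unions, intersections,
    quantified restrictions) are first rewritten into a simple canonical
    axiom form by recursive reduction with uniquely named generated classes,
    and a bidirectional ontology-to-schema mapping catalog is emitted
    alongside executable DDL scripts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    yaml
Suggests:
    DBI,
    RSQLite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
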