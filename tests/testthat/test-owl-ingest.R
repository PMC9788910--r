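# Parsing OWL documents into the normalized ontology model.

test_that("a minimal document yields the declared class and no axioms", {
  f <- write_ofn("Declaration(Class(ex:A))")
  onto <- parse_ontology(f)
  expect_identical(onto$classes, ex("A"))
  expect_length(onto$axioms, 0)
  expect_identical(nrow(onto$warnings), 0L)
})

test_that("SubClassOf with named classes maps to one class-inheritance axiom", {
  f <- write_ofn(c("Declaration(Class(ex:A))", "Declaration(Class(ex:B))",
                   "SubClassOf(ex:A ex:B)"))
  onto <- parse_ontology(f)
  expect_length(onto$axioms, 1)
  ax <- onto$axioms[[1]]
  expect_identical(ax$kind, "class_inheritance")
  expect_identical(ax$domain$iri, ex("A"))
  expect_identical(ax$range$iri, ex("B"))
})

test_that("a top-level restriction becomes the axiom operator with its quantifier", {
  f <- write_ofn(c("Declaration(Class(ex:A))", "Declaration(Class(ex:B))",
                   "Declaration(Class(ex:C))", "Declaration(ObjectProperty(ex:p))",
                   "SubClassOf(ex:A ObjectSomeValuesFrom(ex:p ObjectUnionOf(ex:B ex:C)))"))
  onto <- parse_ontology(f)
  expect_length(onto$axioms, 1)
  ax <- onto$axioms[[1]]
  expect_identical(ax$kind, "class_association")
  expect_identical(ax$domain$iri, ex("A"))
  expect_identical(ax$property, ex("p"))
  expect_identical(ax$qt$min, 1L)
  expect_identical(ax$qt$max, Inf)
  expect_identical(ax$range$node, "union")
  expect_setequal(c(ax$range$left$iri, ax$range$right$iri), c(ex("B"), ex("C")))
})

test_that("cardinality restrictions map to the expected quantifier intervals", {
  f <- write_ofn(c("Declaration(Class(ex:A))", "Declaration(Class(ex:B))",
                   "Declaration(ObjectProperty(ex:p))",
                   "SubClassOf(ex:A ObjectMinCardinality(2 ex:p ex:B))",
                   "SubClassOf(ex:A ObjectMaxCardinality(3 ex:p ex:B))",
                   "SubClassOf(ex:A ObjectExactCardinality(1 ex:p ex:B))",
                   "SubClassOf(ex:A ObjectAllValuesFrom(ex:p ex:B))"))
  onto <- parse_ontology(f)
  qts <- lapply(onto$axioms, function(ax) c(ax$qt$min, ax$qt$max))
  expect_identical(qts, list(c(2, Inf), c(0, 3), c(1, 1), c(0, Inf)))
})

test_that("data restrictions become data-association axioms and register the datatype", {
  f <- write_ofn(c("Declaration(Class(ex:A))", "Declaration(DataProperty(ex:name))",
                   "SubClassOf(ex:A DataExactCardinality(1 ex:name xsd:string))"))
  onto <- parse_ontology(f)
  ax <- onto$axioms[[1]]
  expect_identical(ax$kind, "data_association")
  expect_identical(ax$range, "http://www.w3.org/2001/XMLSchema#string")
  expect_true(ax$range %in% onto$datatypes)
  expect_identical(c(ax$qt$min, ax$qt$max), c(1, 1))
})

test_that("labels resolve by language priority with local-name fallback", {
  f <- write_ofn(c("Declaration(Class(ex:A))", "Declaration(Class(ex:B))",
                   'AnnotationAssertion(rdfs:label ex:A "person"@en)',
                   'AnnotationAssertion(rdfs:label ex:A "personne"@fr)'))
  onto <- parse_ontology(f)
  expect_identical(resolve_label(onto, ex("A"),
                                 ontology_config(language_priority = c("fr", "en"))),
                   "personne")
  expect_identical(resolve_label(onto, ex("A"),
                                 ontology_config(language_priority = "en")), "person")
  # fallback chain: no matching language -> first available label
  expect_identical(resolve_label(onto, ex("A"),
                                 ontology_config(language_priority = "de")), "person")
  # no label at all -> IRI local name
  expect_identical(resolve_label(onto, ex("B"), ontology_config()), "B")
})

test_that("unsupported constructs are retained and warned, one warning each", {
  f <- write_ofn(c("Declaration(Class(ex:A))", "Declaration(Class(ex:B))",
                   "EquivalentClasses(ex:A ex:B)",
                   "DisjointClasses(ex:A ex:B)"))
  onto <- parse_ontology(f)
  others <- Filter(function(ax) ax$kind == "other", onto$axioms)
  expect_length(others, 2)
  expect_identical(sum(onto$warnings$code == "UNSUPPORTED_CONSTRUCT"), 2L)
})

test_that("entity closure holds: axiom IRIs are declared (undeclared ones repaired with a warning)", {
  f <- write_ofn(c("Declaration(Class(ex:A))", "SubClassOf(ex:A ex:Ghost)"))
  onto <- parse_ontology(f)
  expect_true(ex("Ghost") %in% onto$classes)
  expect_true("UNDECLARED_ENTITY" %in% onto$warnings$code)
  expect_length(ontorelforge:::onto_undeclared(onto), 0)
})

test_that("parsing is deterministic", {
  f <- write_ofn(c("Declaration(Class(ex:A))", "Declaration(Class(ex:B))",
                   "Declaration(ObjectProperty(ex:p))",
                   "SubClassOf(ex:A ObjectSomeValuesFrom(ex:p ex:B))",
                   'AnnotationAssertion(rdfs:label ex:A "alpha"@en)'))
  expect_identical(parse_ontology(f), parse_ontology(f))
})

test_that("input errors are specific: missing file, Turtle, bad prefix in filter", {
  expect_error(parse_ontology(tempfile()), class = "orf_input_error")
  ttl <- tempfile(fileext = ".ttl")
  writeLines("@prefix ex: <http://example.org/> .", ttl)
  expect_error(parse_ontology(ttl), class = "orf_input_error")
  f <- write_ofn("Declaration(Class(ex:A))")
  expect_error(parse_ontology(f, ontology_config(class_filter = "nope:A")),
               class = "orf_config_error")
})

test_that("class_filter keeps roots and descendants and drops the rest", {
  f <- write_ofn(c("Declaration(Class(ex:A))", "Declaration(Class(ex:B))",
                   "Declaration(Class(ex:C))", "Declaration(Class(ex:Other))",
                   "SubClassOf(ex:B ex:A)", "SubClassOf(ex:C ex:B)"))
  cfgf <- ontology_config(prefix_map = c(ex = EX_NS), class_filter = "ex:A")
  onto <- parse_ontology(f, cfgf)
  expect_setequal(onto$classes, c(ex("A"), ex("B"), ex("C")))
  expect_length(onto$axioms, 2)
})

test_that("RDF/XML and functional syntax yield the same model for the same ontology", {
  x <- tempfile(fileext = ".owl")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    '  xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"',
    '  xmlns:owl="http://www.w3.org/2002/07/owl#" xmlns:ex="http://example.org/onto#">',
    '<owl:Ontology rdf:about="http://example.org/onto"/>',
    '<owl:Class rdf:about="http://example.org/onto#A">',
    ' <rdfs:label xml:lang="en">alpha</rdfs:label>',
    ' <rdfs:subClassOf rdf:resource="http://example.org/onto#B"/>',
    ' <rdfs:subClassOf><owl:Restriction>',
    '  <owl:onProperty rdf:resource="http://example.org/onto#p"/>',
    '  <owl:someValuesFrom><owl:Class><owl:unionOf rdf:parseType="Collection">',
    '   <owl:Class rdf:about="http://example.org/onto#B"/>',
    '   <owl:Class rdf:about="http://example.org/onto#C"/>',
    '  </owl:unionOf></owl:Class></owl:someValuesFrom>',
    ' </owl:Restriction></rdfs:subClassOf></owl:Class>',
    '<owl:Class rdf:about="http://example.org/onto#B"/>',
    '<owl:Class rdf:about="http://example.org/onto#C"/>',
    '<owl:ObjectProperty rdf:about="http://example.org/onto#p"/>',
    '</rdf:RDF>'), x)
  fo <- write_ofn(c("Declaration(Class(ex:A))", "Declaration(Class(ex:B))",
                    "Declaration(Class(ex:C))", "Declaration(ObjectProperty(ex:p))",
                    "SubClassOf(ex:A ex:B)",
                    "SubClassOf(ex:A ObjectSomeValuesFrom(ex:p ObjectUnionOf(ex:B ex:C)))",
                    'AnnotationAssertion(rdfs:label ex:A "alpha"@en)'))
  a <- parse_ontology(x)
  b <- parse_ontology(fo)
  expect_setequal(a$classes, b$classes)
  expect_identical(lapply(a$axioms, ontorelforge:::axiom_key),
                   lapply(b$axioms, ontorelforge:::axiom_key))
  expect_identical(resolve_label(a, ex("A")), resolve_label(b, ex("A")))
})

test_that("local imports are merged transitively; unresolvable imports warn", {
  d <- tempfile(); dir.create(d)
  writeLines(c("Prefix(ex:=<http://example.org/onto#>)",
               "Ontology(<http://example.org/imported>",
               "Declaration(Class(ex:FromImport))", ")"),
             file.path(d, "imported.ofn"))
  writeLines(c("Prefix(ex:=<http://example.org/onto#>)",
               "Ontology(<http://example.org/main>",
               "Import(<http://example.org/imported.ofn>)",
               "Import(<http://example.org/absent.ofn>)",
               "Declaration(Class(ex:Local))", ")"),
             file.path(d, "main.ofn"))
  onto <- parse_ontology(file.path(d, "main.ofn"))
  expect_setequal(onto$classes, c(ex("Local"), ex("FromImport")))
  expect_identical(sum(onto$warnings$code == "IMPORT_UNRESOLVED"), 1L)
})
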