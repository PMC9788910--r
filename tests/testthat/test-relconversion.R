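# Conversion rules: classes, object properties, inheritance, associations,
# datatypes, individuals, and whole-model assembly.

simple_onto <- function(extra = character(0)) {
  f <- write_ofn(c("Declaration(Class(ex:Person))", "Declaration(Class(ex:Agent))",
                   'AnnotationAssertion(rdfs:label ex:Person "person"@en)',
                   extra))
  parse_ontology(f)
}

test_that("a class becomes a relation with a single iid attribute as primary key", {
  onto <- simple_onto()
  rel <- convert_class(ex("Person"), onto, name = "person")
  expect_identical(rel$kind, "class")
  expect_length(rel$attributes, 1)
  expect_identical(rel$attributes[[1]]$name, "ex_Person_iid")
  expect_identical(rel$attributes[[1]]$role, "iid")
  expect_identical(rel$primary_key, "ex_Person_iid")
})

test_that("the universal relation has exactly one iid attribute", {
  onto <- simple_onto()
  thing <- convert_class("Thing", onto)
  expect_length(thing$attributes, 1)
  expect_identical(thing$primary_key, "Thing_iid")
})

test_that("an object property becomes a subject/object pair relation", {
  f <- write_ofn(c("Declaration(ObjectProperty(ex:has_part))",
                   "Declaration(ObjectProperty(ex:located_in))"))
  onto <- parse_ontology(f)
  rel <- convert_object_property(ex("has_part"), onto)
  expect_identical(vapply(rel$attributes, function(a) a$name, character(1)),
                   c("subject_iid", "object_iid"))
  expect_identical(rel$primary_key, c("subject_iid", "object_iid"))
  # two distinct properties -> two distinct relations, never merged
  rel2 <- convert_object_property(ex("located_in"), onto)
  expect_false(identical(rel$id, rel2$id))
})

test_that("inheritance axioms become isa keys; diamonds and property pairs work", {
  f <- write_ofn(c("Declaration(Class(ex:A))", "Declaration(Class(ex:B))",
                   "Declaration(Class(ex:C))",
                   "Declaration(ObjectProperty(ex:p))", "Declaration(ObjectProperty(ex:q))",
                   "SubClassOf(ex:A ex:B)", "SubClassOf(ex:A ex:C)",
                   "SubObjectPropertyOf(ex:q ex:p)"))
  orel <- convert_file(f)
  isa <- Filter(function(k) k$kind == "isa", orel$keys)
  from_a <- Filter(function(k) k$source == ex("A"), isa)
  expect_length(from_a, 2)
  expect_setequal(vapply(from_a, function(k) k$target, character(1)),
                  c(ex("B"), ex("C")))
  prop_key <- Filter(function(k) k$source == ex("q"), isa)[[1]]
  expect_identical(prop_key$source_attrs, c("subject_iid", "object_iid"))
  expect_identical(prop_key$target, ex("p"))
  expect_identical(prop_key$target_attrs, c("subject_iid", "object_iid"))
  # dangling endpoint is an internal consistency error
  expect_error(
    convert_inheritance(ontorelforge:::axiom_class_inheritance(
      ex_class(ex("A")), ex_class(ex("Nowhere"))), orel$relations),
    class = "orf_consistency_error")
})

test_that("a class association yields one relation, three keys, and a constraint iff bounded", {
  f <- write_ofn(c("Declaration(Class(ex:C0))", "Declaration(Class(ex:C1))",
                   "Declaration(ObjectProperty(ex:p))", "Declaration(ObjectProperty(ex:q))",
                   "SubClassOf(ex:C0 ObjectAllValuesFrom(ex:p ex:C1))",
                   "SubClassOf(ex:C0 ObjectExactCardinality(1 ex:q ex:C1))"))
  orel <- convert_file(f)
  assoc <- Filter(function(r) r$kind == "association", orel$relations)
  expect_length(assoc, 2)
  for (a in assoc) {
    expect_length(a$attributes, 2)
    expect_identical(a$primary_key,
                     vapply(a$attributes, function(x) x$name, character(1)))
    ks <- Filter(function(k) k$source == a$id, orel$keys)
    expect_length(ks, 3)
    expect_setequal(vapply(ks, function(k) k$kind, character(1)),
                    c("assoc", "assoc", "op"))
  }
  # [0..*] gives no constraint; [1..1] gives one
  expect_length(orel$qconstraints, 1)
  expect_identical(orel$qconstraints[[1]]$min, 1L)
  expect_identical(orel$qconstraints[[1]]$max, 1)
  # same classes, two properties -> two distinct association relations
  ids <- vapply(assoc, function(r) r$id, character(1))
  expect_length(unique(ids), 2)
})

test_that("a data association yields a two-attribute relation keyed to its class", {
  f <- write_ofn(c("Declaration(Class(ex:Person))",
                   'AnnotationAssertion(rdfs:label ex:Person "person"@en)',
                   "Declaration(DataProperty(ex:hasName))",
                   "Declaration(DataProperty(ex:hasAge))",
                   "SubClassOf(ex:Person DataAllValuesFrom(ex:hasName xsd:string))",
                   "SubClassOf(ex:Person DataExactCardinality(1 ex:hasAge xsd:integer))"))
  orel <- convert_file(f)
  datar <- Filter(function(r) r$kind == "data", orel$relations)
  # two data properties -> two separate data relations, no wide table
  expect_length(datar, 2)
  name_rel <- datar[[which(vapply(datar, function(r) grepl("hasName", r$id), logical(1)))]]
  expect_identical(vapply(name_rel$attributes, function(a) a$name, character(1)),
                   c("ex_Person_iid", "hasName"))
  expect_identical(name_rel$primary_key, c("ex_Person_iid", "hasName"))
  dp_keys <- Filter(function(k) k$kind == "dp", orel$keys)
  expect_length(dp_keys, 2)
  expect_true(all(vapply(dp_keys, function(k) k$target == ex("Person"), logical(1))))
  # [1..1] on hasAge adds a quantification constraint, [0..*] on hasName does not
  expect_length(orel$qconstraints, 1)
})

test_that("datatypes map to SQL domains with fallback for unknown types", {
  cfg <- rdb_config()
  d <- convert_datatype("http://www.w3.org/2001/XMLSchema#string", cfg)
  expect_identical(d$name, "xsd:String")
  expect_identical(d$base, "TEXT")
  expect_false(d$fallback)
  d2 <- convert_datatype("http://www.w3.org/2001/XMLSchema#integer", cfg)
  expect_identical(d2$base, "INTEGER")
  d3 <- convert_datatype("http://example.org/custom#weirdType", cfg)
  expect_identical(d3$base, cfg$default_type)
  expect_true(d3$fallback)
})

test_that("individuals get one shared iid propagated through the taxonomy", {
  f <- write_ofn(c("Declaration(Class(ex:A))", "Declaration(Class(ex:B))",
                   "Declaration(NamedIndividual(ex:i1))",
                   "Declaration(NamedIndividual(ex:i2))",
                   "SubClassOf(ex:A ex:B)",
                   "ClassAssertion(ex:A ex:i1)"))
  orel <- convert_file(f, cfg = rdb_config(include_individuals = TRUE))
  ins1 <- Filter(function(x) TRUE, orel$inserts)
  by_iid <- split(vapply(ins1, function(x) x$relation, character(1)),
                  vapply(ins1, function(x) x$iid, character(1)))
  # i1 in A, propagated to B and Thing, one iid; i2 only in Thing, distinct iid
  expect_length(by_iid, 2)
  sizes <- sort(vapply(by_iid, length, integer(1)))
  expect_identical(unname(sizes), c(1L, 3L))
  expect_true(any(vapply(by_iid, function(r) setequal(r, c("Thing", ex("A"), ex("B"))),
                         logical(1))))
})

test_that("assembly realizes the counting example and rejects isa cycles", {
  # c=3 classes, s=2 subclass axioms, a=1 association: 6 relations
  f <- write_ofn(c("Declaration(Class(ex:A))", "Declaration(Class(ex:B))",
                   "Declaration(Class(ex:C))", "Declaration(ObjectProperty(ex:p))",
                   "SubClassOf(ex:A ex:B)", "SubClassOf(ex:B ex:C)",
                   "SubClassOf(ex:A ObjectAllValuesFrom(ex:p ex:C))"))
  orel <- convert_file(f)
  expect_identical(length(orel$relations), 6L)
  # keys: 2 isa + 1 root->Thing (C) + 3 association
  expect_identical(length(orel$keys), 6L)

  fcyc <- write_ofn(c("Declaration(Class(ex:A))", "Declaration(Class(ex:B))",
                      "SubClassOf(ex:A ex:B)", "SubClassOf(ex:B ex:A)"))
  red <- reduce_ontology(parse_ontology(fcyc))
  err <- tryCatch(assemble(red$ontology, red$constraints),
                  orf_cycle_error = function(e) e)
  expect_s3_class(err, "orf_cycle_error")
  expect_match(conditionMessage(err), "ex:A")
})

test_that("an empty ontology assembles to the universal relation only", {
  f <- write_ofn(character(0))
  orel <- convert_file(f)
  expect_identical(names(orel$relations), "Thing")
  orel2 <- convert_file(f, config = ontology_config(reuse_thing = FALSE))
  expect_length(orel2$relations, 0)
})

test_that("every iid attribute shares the single configured iid domain", {
  fx <- gen_fixture(fixture_params(4, 2, 2, 1, 3, 2, 0, seed = 5))
  p <- tempfile(fileext = ".ofn"); writeLines(fx$text, p)
  orel <- convert_file(p)
  for (rel in orel$relations) {
    for (a in rel$attributes) {
      if (a$role == "iid") expect_identical(a$domain, "iid_type")
    }
  }
  # uniform association template: two iid attrs, composite PK
  for (rel in Filter(function(r) r$kind == "association", orel$relations)) {
    expect_identical(vapply(rel$attributes, function(a) a$role, character(1)),
                     c("iid", "iid"))
    expect_length(rel$primary_key, 2)
  }
})

test_that("every relational construct has an ontological origin and vice versa", {
  fx <- gen_fixture(fixture_params(3, 1, 1, 0, 2, 1, 1, 3, seed = 9))
  p <- tempfile(fileext = ".ofn"); writeLines(fx$text, p)
  orel <- convert_file(p)
  onto <- orel$onto
  origins <- vapply(orel$relations, function(r) r$origin, character(1))
  expect_true(all(nzchar(origins)))
  # one relation per class, per property, per association/data axiom
  expect_true(all(onto$classes %in% names(orel$relations)))
  expect_true(all(onto$object_properties %in% names(orel$relations)))
  n_assoc_ax <- sum(vapply(onto$axioms, function(ax)
    ax$kind %in% c("class_association", "data_association"), logical(1)))
  expect_identical(sum(vapply(orel$relations, function(r)
    r$kind %in% c("association", "data"), logical(1))), n_assoc_ax)
})
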