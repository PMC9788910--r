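# Axiom complexity reduction: canonical forms, the recursive reduction
# function, whole-ontology reduction and its properties.

test_that("canonical forms are deterministic and commutative-operator stable", {
  a <- ex_class(ex("A")); b <- ex_class(ex("B")); c_ <- ex_class(ex("C"))
  expect_identical(canonical_form(a), ex("A"))
  expect_identical(canonical_form(ex_union(b, a)), canonical_form(ex_union(a, b)))
  r1 <- ex_restriction(ex("p"), qt(1, 1), ex_intersection(c_, b))
  r2 <- ex_restriction(ex("p"), qt(1, 1), ex_intersection(b, c_))
  expect_identical(canonical_form(r1), canonical_form(r2))
  # union and intersection of the same operands stay distinct
  expect_false(canonical_form(ex_union(a, b)) == canonical_form(ex_intersection(a, b)))
})

test_that("quantifier intervals validate their bounds", {
  expect_identical(qt(0, 3)$max, 3)
  expect_identical(qt(2)$max, Inf)
  expect_error(qt(2, 1), class = "orf_type_error")
  expect_error(qt(-1), class = "orf_type_error")
})

test_that("the reduction recursion covers its four cases", {
  reg <- gen_registry(EX_NS, "ex")
  # case 1: a named class is its own representative
  r <- phi(ex_class(ex("A")), reg)
  expect_identical(r$representative, ex("A"))
  expect_length(r$constraints, 0)
  expect_length(r$new_axioms, 0)

  # case 2: union -> fresh Z, A isa Z and B isa Z, union constraint
  r <- phi(ex_union(ex_class(ex("A")), ex_class(ex("B"))), reg)
  z <- r$representative
  expect_match(z, "GEN_[0-9]{4}$")
  expect_length(r$new_axioms, 2)
  for (ax in r$new_axioms) {
    expect_identical(ax$kind, "class_inheritance")
    expect_identical(ax$range$iri, z)
  }
  expect_setequal(vapply(r$new_axioms, function(ax) ax$domain$iri, character(1)),
                  c(ex("A"), ex("B")))
  expect_length(r$constraints, 1)
  expect_identical(r$constraints[[1]]$kind, "union")
  expect_identical(r$constraints[[1]]$target, z)

  # case 3: intersection -> fresh Z, Z isa A and Z isa B, intersection constraint
  r <- phi(ex_intersection(ex_class(ex("A")), ex_class(ex("B"))), reg)
  z2 <- r$representative
  expect_false(z2 == z)
  for (ax in r$new_axioms) expect_identical(ax$domain$iri, z2)
  expect_identical(r$constraints[[1]]$kind, "intersection")

  # registry deduplication: the same canonical form returns the same class
  r2 <- phi(ex_union(ex_class(ex("B")), ex_class(ex("A"))), reg)
  expect_identical(r2$representative, z)
})

test_that("a complex association axiom reduces to the hand-traced simple set", {
  # C p[1..*] (A or B)  =>  {C p[1..*] Z, A isa Z, B isa Z} + union(Z; A, B)
  f <- write_ofn(c("Declaration(Class(ex:A))", "Declaration(Class(ex:B))",
                   "Declaration(Class(ex:C))", "Declaration(ObjectProperty(ex:p))",
                   "SubClassOf(ex:C ObjectSomeValuesFrom(ex:p ObjectUnionOf(ex:A ex:B)))"))
  red <- reduce_ontology(parse_ontology(f))
  onto <- red$ontology
  expect_length(onto$generated, 1)
  z <- unname(onto$generated[[1]])
  expect_length(onto$axioms, 3)
  expect_true(all(vapply(onto$axioms, is_simple_axiom, logical(1))))
  kinds <- vapply(onto$axioms, function(ax) ax$kind, character(1))
  expect_identical(sort(kinds), c("class_association", "class_inheritance", "class_inheritance"))
  assoc <- onto$axioms[[which(kinds == "class_association")]]
  expect_identical(assoc$domain$iri, ex("C"))
  expect_identical(assoc$range$iri, z)
  expect_length(red$constraints, 1)
  expect_setequal(red$constraints[[1]]$operands, c(ex("A"), ex("B")))
})

test_that("a shared sub-expression across axioms yields exactly one generated class", {
  f <- write_ofn(c("Declaration(Class(ex:A))", "Declaration(Class(ex:B))",
                   "Declaration(Class(ex:C))", "Declaration(Class(ex:D))",
                   "Declaration(ObjectProperty(ex:p))",
                   "SubClassOf(ex:C ObjectSomeValuesFrom(ex:p ObjectUnionOf(ex:A ex:B)))",
                   "SubClassOf(ex:D ObjectSomeValuesFrom(ex:p ObjectUnionOf(ex:B ex:A)))"))
  red <- reduce_ontology(parse_ontology(f))
  expect_length(red$ontology$generated, 1)
  expect_length(red$constraints, 1)
  # the two isa axioms into Z are shared, not duplicated
  isa <- Filter(function(ax) ax$kind == "class_inheritance", red$ontology$axioms)
  expect_length(isa, 2)
})

test_that("an already simple ontology is a fixed point with zero constraints", {
  f <- write_ofn(c("Declaration(Class(ex:A))", "Declaration(Class(ex:B))",
                   "Declaration(ObjectProperty(ex:p))",
                   "SubClassOf(ex:A ex:B)",
                   "SubClassOf(ex:A ObjectSomeValuesFrom(ex:p ex:B))"))
  onto <- parse_ontology(f)
  red <- reduce_ontology(onto)
  expect_length(red$constraints, 0)
  expect_identical(lapply(red$ontology$axioms, ontorelforge:::axiom_key),
                   lapply(onto$axioms, ontorelforge:::axiom_key))
})

test_that("reduction is idempotent and its generated names are run-stable", {
  params <- fixture_params(5, 2, 3, 0, 2, 1, 3, 4, seed = 11)
  fx <- gen_fixture(params)
  r1 <- reduce_ontology(fx$ontology)
  r2 <- reduce_ontology(r1$ontology)
  expect_same_onto(r1$ontology, r2$ontology)
  # byte-identical generated IRIs across two independent runs
  fxb <- gen_fixture(params)
  r1b <- reduce_ontology(fxb$ontology)
  expect_identical(r1$ontology$generated, r1b$ontology$generated)
})

test_that("randomized expression trees always reduce to the simple form", {
  for (seed in 1:25) {
    fx <- gen_fixture(fixture_params(4, 2, 2, 0, 1, 0, 3, 6, seed = seed))
    red <- reduce_ontology(fx$ontology)
    expect_true(all(vapply(red$ontology$axioms, is_simple_axiom, logical(1))),
                info = paste("seed", seed))
  }
})

test_that("the small-model oracle confirms semantics preservation", {
  # union in an association filler: C p[1..*] (A or B), 3 classes + 1 property
  f1 <- write_ofn(c("Declaration(Class(ex:A))", "Declaration(Class(ex:B))",
                    "Declaration(Class(ex:C))", "Declaration(ObjectProperty(ex:p))",
                    "SubClassOf(ex:C ObjectSomeValuesFrom(ex:p ObjectUnionOf(ex:A ex:B)))"))
  res <- check_reduction_semantics(parse_ontology(f1), n_individuals = 2)
  expect_true(res$equivalent)
  expect_gt(res$n_satisfying, 0)

  # pure union / intersection inheritance over 4 classes, 3 individuals
  f2 <- write_ofn(c("Declaration(Class(ex:A))", "Declaration(Class(ex:B))",
                    "Declaration(Class(ex:C))", "Declaration(Class(ex:D))",
                    "SubClassOf(ObjectUnionOf(ex:A ex:B) ex:C)",
                    "SubClassOf(ex:D ObjectIntersectionOf(ex:A ex:B))"))
  res2 <- check_reduction_semantics(parse_ontology(f2), n_individuals = 3)
  expect_true(res2$equivalent)
  expect_identical(res2$n_interpretations, 4096L)
})
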