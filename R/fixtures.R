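# Synthetic ontology generation: parameterized random ontologies with exactly
# realized construct counts, an arithmetic counting oracle predicting the
# relational construct counts from the conversion rules, and the didactic
# prescription-flavored worked example carrying one complex axiom.

FIXTURE_NS <- "http://example.org/fixture#"

#' Fixture generation parameters
#'
#' All counts are realized exactly; the generated taxonomy is acyclic by
#' construction (a subclass axiom always points from a higher-indexed class to
#' a lower-indexed one).
#'
#' @param n_classes,n_object_properties Number of named classes / object
#'   properties.
#' @param n_subclass_axioms,n_subproperty_axioms Number of inheritance axioms.
#' @param n_class_associations,n_data_associations Number of association
#'   axioms (each data association introduces its own data property).
#' @param n_complex_axioms Number of complex axioms (random expression trees).
#' @param max_expr_depth Maximum expression depth of complex axioms (>= 2 when
#'   complex axioms are requested).
#' @param seed RNG seed; fixed seed gives a byte-identical document.
#' @return A `fixture_params` object.
#' @export
fixture_params <- function(n_classes = 0L, n_object_properties = 0L,
                           n_subclass_axioms = 0L, n_subproperty_axioms = 0L,
                           n_class_associations = 0L, n_data_associations = 0L,
                           n_complex_axioms = 0L, max_expr_depth = 3L,
                           seed = 1L) {
  p <- list(n_classes = as.integer(n_classes),
            n_object_properties = as.integer(n_object_properties),
            n_subclass_axioms = as.integer(n_subclass_axioms),
            n_subproperty_axioms = as.integer(n_subproperty_axioms),
            n_class_associations = as.integer(n_class_associations),
            n_data_associations = as.integer(n_data_associations),
            n_complex_axioms = as.integer(n_complex_axioms),
            max_expr_depth = as.integer(max_expr_depth),
            seed = as.integer(seed))
  if (any(vapply(p, function(x) is.na(x) || x < 0L, logical(1)))) {
    orf_input_error("fixture parameters must be non-negative integers")
  }
  c_ <- p$n_classes
  if (p$n_subclass_axioms > c_ * (c_ - 1L) / 2L) {
    orf_input_error("n_subclass_axioms exceeds the number of acyclic class pairs")
  }
  op <- p$n_object_properties
  if (p$n_subproperty_axioms > op * (op - 1L) / 2L) {
    orf_input_error("n_subproperty_axioms exceeds the number of acyclic property pairs")
  }
  if (p$n_class_associations > 0L && (c_ < 1L || op < 1L)) {
    orf_input_error("class associations require at least one class and one object property")
  }
  if (p$n_class_associations > c_ * c_ * op) {
    orf_input_error("n_class_associations exceeds the number of distinct (class, property, class) triples")
  }
  if (p$n_data_associations > 0L && c_ < 1L) {
    orf_input_error("data associations require at least one class")
  }
  if (p$n_complex_axioms > 0L && (c_ < 2L || op < 1L || p$max_expr_depth < 2L)) {
    orf_input_error("complex axioms require >= 2 classes, >= 1 object property and depth >= 2")
  }
  structure(p, class = "fixture_params")
}

FIXTURE_QTS <- list(qt(0L, Inf), qt(1L, Inf), qt(1L, 1L), qt(0L, 3L))
FIXTURE_DATA_QTS <- list(qt(0L, Inf), qt(1L, 1L), qt(0L, 1L))
FIXTURE_DATATYPES <- c("http://www.w3.org/2001/XMLSchema#string",
                       "http://www.w3.org/2001/XMLSchema#integer",
                       "http://www.w3.org/2001/XMLSchema#dateTime")

#' Arithmetic counting oracle for the conversion rules
#'
#' Predicts, by pure arithmetic over the conversion rules, the relational
#' construct counts produced end-to-end for a fixture with no complex axioms:
#' `1 + c + p + a + d` relations, `s` subclass isa keys plus one key per
#' root class into the universal relation, one isa key per sub-property
#' axiom, three keys per class association and one per data association.
#'
#' @param params A [fixture_params()] with `n_complex_axioms = 0`.
#' @param n_root_classes Number of classes without a named superclass.
#' @param n_datatypes Number of distinct datatypes used.
#' @param n_bounded_quantifiers Number of association axioms with `min > 0` or
#'   a finite `max`.
#' @return Named list of predicted counts.
#' @export
counting_oracle <- function(params, n_root_classes, n_datatypes,
                            n_bounded_quantifiers) {
  if (params$n_complex_axioms > 0L) {
    orf_input_error("the counting oracle is defined for fixtures without complex axioms")
  }
  list(
    relations = 1L + params$n_classes + params$n_object_properties +
      params$n_class_associations + params$n_data_associations,
    referential_keys = params$n_subclass_axioms + params$n_subproperty_axioms +
      3L * params$n_class_associations + params$n_data_associations +
      n_root_classes,
    domains = 1L + n_datatypes,
    quantification_constraints = n_bounded_quantifiers
  )
}

# random expression tree over the fixture classes/properties
gen_expr <- function(depth, class_iris, prop_iris, top = FALSE) {
  if (depth <= 1L) {
    return(ex_class(sample(class_iris, 1L)))
  }
  node <- if (top) {
    sample(c("union", "intersection", "restriction"), 1L)
  } else {
    sample(c("class", "union", "intersection", "restriction"), 1L,
           prob = c(0.4, 0.25, 0.2, 0.15))
  }
  switch(node,
    class = ex_class(sample(class_iris, 1L)),
    union = ex_union(gen_expr(depth - 1L, class_iris, prop_iris),
                     gen_expr(depth - 1L, class_iris, prop_iris)),
    intersection = ex_intersection(gen_expr(depth - 1L, class_iris, prop_iris),
                                   gen_expr(depth - 1L, class_iris, prop_iris)),
    restriction = ex_restriction(sample(prop_iris, 1L),
                                 FIXTURE_QTS[[sample.int(4L, 1L)]],
                                 gen_expr(depth - 1L, class_iris, prop_iris))
  )
}

#' Generate a synthetic ontology fixture
#'
#' Builds a valid ontology document realizing the requested construct counts
#' exactly, together with the expected post-conversion counts computed by the
#' arithmetic [counting_oracle()] (available when no complex axioms were
#' requested).
#'
#' @param params A [fixture_params()].
#' @param path Optional file path; the functional-syntax document is written
#'   there when given.
#' @return List with `ontology` (the built `muonto`), `text` (the serialized
#'   document), `path` (or `NULL`) and `expected` (counting-oracle record, or
#'   `NULL` when complex axioms are present).
#' @export
gen_fixture <- function(params, path = NULL) {
  stopifnot(inherits(params, "fixture_params"))
  set.seed(params$seed)
  cls <- sprintf("%sC%03d", FIXTURE_NS, seq_len(params$n_classes))
  ops <- sprintf("%sp%03d", FIXTURE_NS, seq_len(params$n_object_properties))
  dps <- sprintf("%sd%03d", FIXTURE_NS, seq_len(params$n_data_associations))

  onto <- muonto(prefixes = c(BUILTIN_PREFIXES, fx = FIXTURE_NS),
                 default_prefix = "fx", iri = "http://example.org/fixture")
  onto$classes <- cls
  onto$object_properties <- ops
  onto$data_properties <- dps
  for (i in seq_along(cls)) {
    onto <- onto_add_annotation(onto, cls[i], RDFS_LABEL, sprintf("class_%03d", i), "en")
  }
  for (i in seq_along(ops)) {
    onto <- onto_add_annotation(onto, ops[i], RDFS_LABEL, sprintf("relates_%03d", i), "en")
  }

  # subclass axioms over pairs (child > parent): acyclic by construction
  if (params$n_subclass_axioms > 0L) {
    pairs <- which(upper.tri(matrix(0, params$n_classes, params$n_classes)), arr.ind = TRUE)
    pick <- pairs[sample.int(nrow(pairs), params$n_subclass_axioms), , drop = FALSE]
    for (r in seq_len(nrow(pick))) {
      child <- cls[pick[r, "col"]]; parent <- cls[pick[r, "row"]]
      onto$axioms[[length(onto$axioms) + 1L]] <-
        axiom_class_inheritance(ex_class(child), ex_class(parent))
    }
  }
  if (params$n_subproperty_axioms > 0L) {
    pairs <- which(upper.tri(matrix(0, params$n_object_properties,
                                    params$n_object_properties)), arr.ind = TRUE)
    pick <- pairs[sample.int(nrow(pairs), params$n_subproperty_axioms), , drop = FALSE]
    for (r in seq_len(nrow(pick))) {
      onto$axioms[[length(onto$axioms) + 1L]] <-
        axiom_property_inheritance(ops[pick[r, "col"]], ops[pick[r, "row"]])
    }
  }
  n_bounded <- 0L
  if (params$n_class_associations > 0L) {
    triples <- expand.grid(d = seq_along(cls), p = seq_along(ops), r = seq_along(cls))
    pick <- triples[sample.int(nrow(triples), params$n_class_associations), , drop = FALSE]
    for (r in seq_len(nrow(pick))) {
      q <- FIXTURE_QTS[[sample.int(length(FIXTURE_QTS), 1L)]]
      if (q$min > 0L || is.finite(q$max)) n_bounded <- n_bounded + 1L
      onto$axioms[[length(onto$axioms) + 1L]] <-
        axiom_class_association(ex_class(cls[pick[r, "d"]]), ops[pick[r, "p"]],
                                q, ex_class(cls[pick[r, "r"]]))
    }
  }
  datatypes <- character(0)
  for (i in seq_len(params$n_data_associations)) {
    q <- FIXTURE_DATA_QTS[[sample.int(length(FIXTURE_DATA_QTS), 1L)]]
    if (q$min > 0L || is.finite(q$max)) n_bounded <- n_bounded + 1L
    dt <- sample(FIXTURE_DATATYPES, 1L)
    datatypes <- union(datatypes, dt)
    onto$axioms[[length(onto$axioms) + 1L]] <-
      axiom_data_association(ex_class(sample(cls, 1L)), dps[i], q, dt)
  }
  onto$datatypes <- datatypes
  # Complex axioms: the domain class sits strictly above every class in the
  # expression (same orientation as the generated taxonomy, where a subclass
  # axiom always points from a higher-indexed class to a lower-indexed one),
  # so the isa edges introduced by the reduction can never close a cycle.
  for (i in seq_len(params$n_complex_axioms)) {
    d <- sample(2:length(cls), 1L)
    pool <- cls[seq_len(d - 1L)]
    expr <- gen_expr(params$max_expr_depth, pool, ops, top = TRUE)
    onto$axioms[[length(onto$axioms) + 1L]] <- if (expr$node == "restriction") {
      # a top-level restriction is an association axiom (its property and
      # quantifier are the operator), matching how ingestion reads it back
      axiom_class_association(ex_class(cls[d]), expr$property, expr$qt, expr$operand)
    } else {
      axiom_class_inheritance(ex_class(cls[d]), expr)
    }
  }

  expected <- NULL
  if (params$n_complex_axioms == 0L) {
    with_super <- unique(vapply(
      Filter(function(ax) ax$kind == "class_inheritance", onto$axioms),
      function(ax) ax$domain$iri, character(1)))
    expected <- counting_oracle(params,
                                n_root_classes = params$n_classes - length(with_super),
                                n_datatypes = length(datatypes),
                                n_bounded_quantifiers = n_bounded)
  }
  text <- write_functional(onto, path)
  list(ontology = onto, text = text, path = path, expected = expected,
       params = params)
}

#' The didactic worked example: a drug-prescription mini ontology
#'
#' A small prescription-flavored ontology: a prescription document, two
#' document parts (a drug administration specification and a drug dispensing
#' specification), a part-of object property and exactly one complex axiom -
#' every prescription has some part that is an administration or a dispensing
#' specification - plus one data association carrying the signing date. Its
#' reduction produces exactly one generated class with a union membership
#' constraint.
#'
#' @param path Optional file path for the functional-syntax document.
#' @return List with `ontology` (a `muonto`), `text` and `path`.
#' @export
worked_example <- function(path = NULL) {
  ns <- "http://example.org/rxonto#"
  onto <- muonto(prefixes = c(BUILTIN_PREFIXES, rxo = ns),
                 default_prefix = "rxo", iri = "http://example.org/rxonto")
  cl <- function(x) paste0(ns, x)
  onto$classes <- cl(c("Prescription", "DocumentPart",
                       "DrugAdministrationSpecification",
                       "DrugDispensingSpecification"))
  onto$object_properties <- cl("hasPart")
  onto$data_properties <- cl("dateSigned")
  onto$datatypes <- paste0(XSD_NS, "string")
  lab <- c(Prescription = "prescription", DocumentPart = "document_part",
           DrugAdministrationSpecification = "drug_administration_specification",
           DrugDispensingSpecification = "drug_dispensing_specification",
           hasPart = "has_part", dateSigned = "date_signed")
  for (nm in names(lab)) {
    onto <- onto_add_annotation(onto, cl(nm), RDFS_LABEL, lab[[nm]], "en")
  }
  onto <- onto_add_annotation(onto, cl("Prescription"), IAO_DEFINITION,
                              "A document that directs the administration or dispensing of drugs to a patient.",
                              "en")
  onto <- onto_add_annotation(onto, cl("hasPart"), IAO_DEFINITION,
                              "Relates a whole document to one of its parts.", "en")
  onto$axioms <- list(
    axiom_class_inheritance(ex_class(cl("DrugAdministrationSpecification")),
                            ex_class(cl("DocumentPart"))),
    axiom_class_inheritance(ex_class(cl("DrugDispensingSpecification")),
                            ex_class(cl("DocumentPart"))),
    # the one complex axiom: prescription hasPart[1..*] (DAS or DDS)
    axiom_class_association(ex_class(cl("Prescription")), cl("hasPart"), qt(1L, Inf),
                            ex_union(ex_class(cl("DrugAdministrationSpecification")),
                                     ex_class(cl("DrugDispensingSpecification")))),
    axiom_data_association(ex_class(cl("Prescription")), cl("dateSigned"),
                           qt(1L, 1L), paste0(XSD_NS, "string"))
  )
  text <- write_functional(onto, path)
  list(ontology = onto, text = text, path = path)
}
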