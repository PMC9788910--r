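# Axiom complexity reduction: rewrite every complex axiom into the simple
# canonical form {axiom ::= ID operator ID} by recursively replacing
# sub-expressions with uniquely named generated classes, while collecting the
# membership constraints that preserve semantic validity.
#
# The recursion has four cases:
#   1. a named class is its own representative, nothing is generated;
#   2. a union B OR C yields a fresh class Z with simple axioms B isa Z and
#      C isa Z plus the constraint ext(Z) = ext(B) + ext(C);
#   3. an intersection B AND C yields a fresh class Z with simple axioms
#      Z isa B and Z isa C plus the constraint ext(Z) = ext(B) * ext(C);
#   4. a quantified restriction at the top of an axiom's right-hand side is
#      peeled off by the caller: the property and quantifier become the
#      axiom's operator and the filler is reduced recursively. A restriction
#      nested strictly inside a union/intersection is materialized as a fresh
#      class Z with the simple association axiom Z p[qt] rep(filler); this
#      asserts the necessary direction of the restriction only (see the
#      methods vignette).

#' Generated-class registry
#'
#' Maps canonical expression serializations to generated class IRIs,
#' injectively and stably: the same canonical form always yields the same IRI
#' (deduplication across axioms), distinct forms always yield distinct IRIs.
#' Names follow `<prefix>_GEN_<zero-padded counter>` in first-encounter order.
#'
#' @param namespace IRI namespace under which generated classes are minted.
#' @param prefix Short ontology prefix embedded in the generated local name.
#' @param seed_map Named character vector (canonical form -> IRI) used to
#'   re-seed the registry, e.g. when re-reducing an already reduced ontology.
#' @return An environment of class `gen_registry`.
#' @export
gen_registry <- function(namespace = "http://example.org/onto#",
                         prefix = "onto", seed_map = character(0)) {
  e <- new.env(parent = emptyenv())
  e$map <- seed_map
  e$counter <- length(seed_map)
  e$namespace <- namespace
  e$prefix <- prefix
  class(e) <- c("gen_registry", "environment")
  e
}

registry_get <- function(registry, canonical) {
  hit <- registry$map[canonical]
  if (!is.na(hit)) return(unname(hit))
  registry$counter <- registry$counter + 1L
  iri <- sprintf("%sGEN_%04d", registry$namespace, registry$counter)
  registry$map[canonical] <- iri
  iri
}

membership_constraint <- function(kind, target, operands) {
  structure(list(kind = kind, target = target, operands = operands),
            class = "membership_constraint")
}

empty_reduction <- function(rep) {
  list(representative = rep, constraints = list(), new_axioms = list())
}

merge_reductions <- function(a, b) {
  list(representative = a$representative,
       constraints = c(a$constraints, b$constraints),
       new_axioms = c(a$new_axioms, b$new_axioms))
}

#' Reduce one class expression to a representative named class
#'
#' The core recursive reduction. Returns the representative class IRI, the
#' membership constraints that pin down the extensions of any generated
#' classes, and the new simple axioms that replace the expression structure.
#'
#' @param expr An `orf_expr`.
#' @param registry A [gen_registry()].
#' @return A list with elements `representative` (IRI), `constraints`
#'   (list of membership constraints) and `new_axioms` (list of simple
#'   `raw_axiom`s).
#' @examples
#' reg <- gen_registry("http://x.org/", "x")
#' r <- phi(ex_union(ex_class("http://x.org/A"), ex_class("http://x.org/B")), reg)
#' r$representative             # the generated class
#' length(r$new_axioms)         # A isa Z, B isa Z
#' @export
phi <- function(expr, registry) {
  stopifnot(inherits(expr, "orf_expr"))
  switch(expr$node,
    class = empty_reduction(expr$iri),
    union = {
      l <- phi(expr$left, registry)
      r <- phi(expr$right, registry)
      z <- registry_get(registry, canonical_form(expr))
      ops <- c(l$representative, r$representative)
      list(representative = z,
           constraints = c(l$constraints, r$constraints,
                           list(membership_constraint("union", z, ops))),
           new_axioms = c(l$new_axioms, r$new_axioms,
                          list(axiom_class_inheritance(ex_class(ops[1]), ex_class(z)),
                               axiom_class_inheritance(ex_class(ops[2]), ex_class(z)))))
    },
    intersection = {
      l <- phi(expr$left, registry)
      r <- phi(expr$right, registry)
      z <- registry_get(registry, canonical_form(expr))
      ops <- c(l$representative, r$representative)
      list(representative = z,
           constraints = c(l$constraints, r$constraints,
                           list(membership_constraint("intersection", z, ops))),
           new_axioms = c(l$new_axioms, r$new_axioms,
                          list(axiom_class_inheritance(ex_class(z), ex_class(ops[1])),
                               axiom_class_inheritance(ex_class(z), ex_class(ops[2])))))
    },
    restriction = {
      inner <- phi(expr$operand, registry)
      z <- registry_get(registry, canonical_form(expr))
      list(representative = z,
           constraints = inner$constraints,
           new_axioms = c(inner$new_axioms,
                          list(axiom_class_association(ex_class(z), expr$property,
                                                       expr$qt,
                                                       ex_class(inner$representative)))))
    }
  )
}

# Reduce a single raw axiom; returns list(axioms = ..., constraints = ...).
reduce_axiom <- function(ax, registry) {
  if (ax$kind %in% c("property_inheritance", "other")) {
    return(list(axioms = list(ax), constraints = list()))
  }
  if (ax$kind == "class_inheritance" && inherits(ax$range, "orf_expr") &&
      ax$range$node == "restriction") {
    # top-level restriction on the right-hand side: reattach (p, qt) as the
    # axiom operator (case 4 of the recursion)
    ax <- axiom_class_association(ax$domain, ax$range$property, ax$range$qt,
                                  ax$range$operand)
  }
  d <- phi(ax$domain, registry)
  if (ax$kind == "data_association") {
    main <- axiom_data_association(ex_class(d$representative), ax$property, ax$qt, ax$range)
    return(list(axioms = c(d$new_axioms, list(main)), constraints = d$constraints))
  }
  r <- phi(ax$range, registry)
  main <- if (ax$kind == "class_inheritance") {
    axiom_class_inheritance(ex_class(d$representative), ex_class(r$representative))
  } else {
    axiom_class_association(ex_class(d$representative), ax$property, ax$qt,
                            ex_class(r$representative))
  }
  list(axioms = c(d$new_axioms, r$new_axioms, list(main)),
       constraints = c(d$constraints, r$constraints))
}

#' Reduce every complex axiom of an ontology to the simple canonical form
#'
#' Applies the recursive reduction to every axiom: after the call every axiom
#' relates two bare identifiers. Generated classes are added to the class set
#' (annotated with their canonical expression), replacement axioms substitute
#' the original complex ones, duplicated simple axioms and constraints are
#' collapsed, and the operation is idempotent: reducing an already reduced
#' ontology is a structural no-op.
#'
#' @param onto A `muonto` as returned by [parse_ontology()].
#' @return A list with elements `ontology` (the reduced `muonto`) and
#'   `constraints` (list of membership constraints for generated classes).
#' @export
reduce_ontology <- function(onto) {
  stopifnot(inherits(onto, "muonto"))
  prefix <- onto$default_prefix %||% "onto"
  namespace <- if (!is.null(onto$default_prefix) &&
                   onto$default_prefix %in% names(onto$prefixes)) {
    onto$prefixes[[onto$default_prefix]]
  } else {
    paste0(onto$iri %||% "http://example.org/onto", "#")
  }
  registry <- gen_registry(namespace, prefix, seed_map = onto$generated)

  axioms <- list()
  seen <- character(0)
  constraints <- list()
  cseen <- character(0)
  add_axiom <- function(ax) {
    key <- axiom_key(ax)
    if (!key %in% seen) {
      seen <<- c(seen, key)
      axioms[[length(axioms) + 1L]] <<- ax
    }
  }
  add_constraint <- function(con) {
    key <- paste(con$kind, con$target)
    if (!key %in% cseen) {
      cseen <<- c(cseen, key)
      constraints[[length(constraints) + 1L]] <<- con
    }
  }

  for (ax in onto$axioms) {
    if (ax$kind == "other") {
      onto <- onto_add_warning(onto, "UNSUPPORTED_CONSTRUCT",
                               sprintf("unsupported construct not reduced: %s",
                                       substr(ax$text, 1, 200)),
                               subject = ax$text)
      add_axiom(ax)
      next
    }
    red <- reduce_axiom(ax, registry)
    for (a in red$axioms) add_axiom(a)
    for (con in red$constraints) add_constraint(con)
  }

  new_gen <- setdiff(registry$map, onto$generated)
  for (canon in names(registry$map)) {
    iri <- registry$map[[canon]]
    if (iri %in% new_gen) {
      onto$classes <- union(onto$classes, iri)
      onto <- onto_add_annotation(onto, iri, ORF_CANONICAL, canon)
      # display name <prefix>_GEN_<counter>, assigned in first-encounter order
      onto <- onto_add_annotation(onto, iri, RDFS_LABEL,
                                  paste0(prefix, "_", iri_local_name(iri)))
    }
  }
  onto$generated <- registry$map
  onto$axioms <- axioms
  onto$reduced <- TRUE

  stopifnot(all(vapply(axioms, is_simple_axiom, logical(1))))
  list(ontology = onto, constraints = constraints)
}

#' @export
print.membership_constraint <- function(x, ...) {
  cat(sprintf("%s(%s; %s)\n", x$kind, x$target, paste(x$operands, collapse = ", ")))
  invisible(x)
}
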