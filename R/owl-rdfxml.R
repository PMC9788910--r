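# RDF/XML OWL reader built on xml2. Covers the constructs the converter
# understands: entity declarations, subclass/subproperty axioms with
# restriction / union / intersection expressions (rdf:parseType="Collection"),
# class assertions and literal annotations. Unsupported elements are retained
# as kind = "other" axioms with a warning.

RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
OWL_NS <- "http://www.w3.org/2002/07/owl#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"

rx_attr <- function(node, local) {
  a <- xml2::xml_attrs(node)
  hit <- which(names(a) == local | endsWith(names(a), paste0(":", local)))
  if (length(hit)) a[[hit[[1]]]] else NA_character_
}

# full IRI of the element's own name (namespace URI + local name)
rx_element_iri <- function(node, ns_map) {
  qn <- xml2::xml_name(node, ns_map)
  if (grepl(":", qn, fixed = TRUE)) {
    pfx <- sub(":.*$", "", qn)
    paste0(ns_map[[pfx]], sub("^[^:]*:", "", qn))
  } else {
    qn
  }
}

rdfxml_parse_document <- function(path, config, depth = 0L) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) orf_syntax_error(
                    sprintf("cannot parse RDF/XML document '%s': %s", path, conditionMessage(e))))
  ns_map <- tryCatch(xml2::xml_ns(doc), error = function(e) character(0))
  prefixes <- c(BUILTIN_PREFIXES, config$prefix_map)
  # adopt the document's own prefixes for namespaces not already mapped
  for (p in names(ns_map)) {
    if (!grepl("^d[0-9]+$", p) && !p %in% names(prefixes)) prefixes[[p]] <- ns_map[[p]]
  }
  default_prefix <- setdiff(names(prefixes), names(BUILTIN_PREFIXES))
  onto <- muonto(prefixes = prefixes,
                 default_prefix = if (length(default_prefix)) default_prefix[[1]],
                 iri = NULL)

  record_other <- function(node, what) {
    onto$axioms[[length(onto$axioms) + 1L]] <<- axiom_other(what)
    onto <<- onto_add_warning(onto, "UNSUPPORTED_CONSTRUCT",
                              sprintf("unsupported construct retained as-is: %s", what), what)
  }

  # Interpret an RDF/XML class-expression node (owl:Class with unionOf /
  # intersectionOf collection, owl:Restriction, or a node reference).
  as_expr <- function(node) {
    nm <- xml2::xml_name(node)
    about <- rx_attr(node, "about")
    if (!is.na(about) && nm %in% c("Class", "Description", "NamedIndividual")) {
      kids <- xml2::xml_children(node)
      if (length(kids) == 0L) return(ex_class(about))
    }
    if (nm == "Class" || nm == "Description") {
      kids <- xml2::xml_children(node)
      for (k in kids) {
        knm <- xml2::xml_name(k)
        if (knm %in% c("unionOf", "intersectionOf")) {
          ops <- lapply(xml2::xml_children(k), as_expr)
          ops <- Filter(Negate(is.null), ops)
          if (length(ops) < 2L) return(NULL)
          return(fold_nary(if (knm == "unionOf") "union" else "intersection", ops))
        }
      }
      if (!is.na(about)) return(ex_class(about))
      return(NULL)
    }
    if (nm == "Restriction") {
      prop <- NA_character_; filler <- NULL; quant <- NULL; on_class <- NULL
      for (k in xml2::xml_children(node)) {
        knm <- xml2::xml_name(k)
        res <- rx_attr(k, "resource")
        val <- xml2::xml_text(k)
        kid <- xml2::xml_children(k)
        sub_expr <- function() {
          if (!is.na(res)) ex_class(res)
          else if (length(kid)) as_expr(kid[[1]])
          else NULL
        }
        if (knm == "onProperty") {
          prop <- if (!is.na(res)) res else rx_attr(xml2::xml_children(k)[[1]], "about")
        } else if (knm == "someValuesFrom") {
          quant <- qt(1L, Inf); filler <- sub_expr()
        } else if (knm == "allValuesFrom") {
          quant <- qt(0L, Inf); filler <- sub_expr()
        } else if (knm %in% c("cardinality", "qualifiedCardinality")) {
          n <- as.integer(val); quant <- qt(n, n)
        } else if (knm %in% c("minCardinality", "minQualifiedCardinality")) {
          quant <- qt(as.integer(val), Inf)
        } else if (knm %in% c("maxCardinality", "maxQualifiedCardinality")) {
          quant <- qt(0L, as.integer(val))
        } else if (knm == "onClass" || knm == "onDataRange") {
          on_class <- if (!is.na(res)) ex_class(res) else if (length(kid)) as_expr(kid[[1]])
        }
      }
      if (is.null(filler)) filler <- on_class
      if (is.null(filler)) filler <- ex_class(OWL_THING)
      if (is.na(prop) || is.null(quant)) return(NULL)
      return(ex_restriction(prop, quant, filler))
    }
    about2 <- rx_attr(node, "about")
    if (!is.na(about2)) return(ex_class(about2))
    NULL
  }

  root_kids <- xml2::xml_children(doc)
  for (node in root_kids) {
    nm <- xml2::xml_name(node)
    about <- rx_attr(node, "about")
    if (nm == "Ontology") {
      onto$iri <- about
      for (k in xml2::xml_children(node)) {
        if (xml2::xml_name(k) == "imports") {
          imp <- rx_attr(k, "resource")
          cand <- file.path(dirname(path), basename(imp))
          if (file.exists(cand) && depth < 8L) {
            imported <- parse_any(cand, config, depth + 1L)
            onto <- merge_muonto(onto, imported)
          } else {
            onto <- onto_add_warning(onto, "IMPORT_UNRESOLVED",
                                     sprintf("import not resolved locally: %s", imp), imp)
          }
        }
      }
      next
    }
    if (is.na(about)) { record_other(node, xml2::xml_name(node, ns_map)); next }

    collect_annotations <- function() {
      for (k in xml2::xml_children(node)) {
        kiri <- rx_element_iri(k, ns_map)
        knm <- xml2::xml_name(k)
        if (knm %in% c("subClassOf", "subPropertyOf", "type", "imports",
                       "unionOf", "intersectionOf", "equivalentClass",
                       "disjointWith", "domain", "range")) next
        if (length(xml2::xml_children(k)) == 0L && nzchar(xml2::xml_text(k)) &&
            is.na(rx_attr(k, "resource"))) {
          lang <- rx_attr(k, "lang")
          onto <<- onto_add_annotation(onto, about, kiri, xml2::xml_text(k),
                                       if (is.na(lang)) NA_character_ else lang)
        }
      }
    }

    if (nm == "Class") {
      onto$classes <- union(onto$classes, about)
      collect_annotations()
      for (k in xml2::xml_children(node)) {
        knm <- xml2::xml_name(k)
        if (knm == "subClassOf") {
          res <- rx_attr(k, "resource")
          rhs <- if (!is.na(res)) ex_class(res) else {
            kid <- xml2::xml_children(k)
            if (length(kid)) as_expr(kid[[1]]) else NULL
          }
          if (is.null(rhs)) {
            record_other(k, sprintf("subClassOf of %s with unrecognized filler", about))
          } else if (rhs$node == "restriction") {
            # data vs object restriction: decided later, at finalization,
            # when the property sets are known
            onto$axioms[[length(onto$axioms) + 1L]] <-
              axiom_class_association(ex_class(about), rhs$property, rhs$qt, rhs$operand)
          } else {
            onto$axioms[[length(onto$axioms) + 1L]] <-
              axiom_class_inheritance(ex_class(about), rhs)
          }
        } else if (knm %in% c("equivalentClass", "disjointWith")) {
          record_other(k, sprintf("%s on %s", knm, about))
        }
      }
    } else if (nm == "ObjectProperty") {
      onto$object_properties <- union(onto$object_properties, about)
      collect_annotations()
      for (k in xml2::xml_children(node)) {
        knm <- xml2::xml_name(k)
        res <- rx_attr(k, "resource")
        if (knm == "subPropertyOf" && !is.na(res)) {
          onto$axioms[[length(onto$axioms) + 1L]] <- axiom_property_inheritance(about, res)
        } else if (knm == "domain" && !is.na(res)) {
          onto$axioms[[length(onto$axioms) + 1L]] <-
            axiom_class_association(ex_class(res), about, qt(0L, Inf), ex_class(OWL_THING))
        } else if (knm == "range" && !is.na(res)) {
          onto$axioms[[length(onto$axioms) + 1L]] <-
            axiom_class_association(ex_class(OWL_THING), about, qt(0L, Inf), ex_class(res))
        }
      }
    } else if (nm == "DatatypeProperty") {
      onto$data_properties <- union(onto$data_properties, about)
      collect_annotations()
      for (k in xml2::xml_children(node)) {
        if (xml2::xml_name(k) == "range") {
          res <- rx_attr(k, "resource")
          if (!is.na(res)) onto$datatypes <- union(onto$datatypes, res)
        }
      }
    } else if (nm == "AnnotationProperty") {
      collect_annotations()
    } else if (nm == "Datatype") {
      onto$datatypes <- union(onto$datatypes, about)
    } else if (nm == "NamedIndividual") {
      if (is.null(onto$individuals[[about]])) onto$individuals[[about]] <- character(0)
      collect_annotations()
      for (k in xml2::xml_children(node)) {
        if (xml2::xml_name(k) == "type") {
          res <- rx_attr(k, "resource")
          if (!is.na(res) && res != paste0(OWL_NS, "NamedIndividual")) {
            onto$individuals[[about]] <- union(onto$individuals[[about]], res)
          }
        }
      }
    } else {
      record_other(node, xml2::xml_name(node, ns_map))
    }
  }

  # A restriction over a data property parsed as a class association is
  # re-typed as a data association now that the property sets are known.
  onto$axioms <- lapply(onto$axioms, function(ax) {
    if (ax$kind == "class_association" && ax$property %in% onto$data_properties &&
        is_class_expr(ax$range)) {
      onto$datatypes <<- union(onto$datatypes, ax$range$iri)
      return(axiom_data_association(ax$domain, ax$property, ax$qt, ax$range$iri))
    }
    ax
  })
  onto$datatypes <- setdiff(onto$datatypes, onto$classes)
  onto
}
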