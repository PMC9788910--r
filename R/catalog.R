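# The mapping catalog (OntoRelCat): one entry per converted ontological
# construct tying it to exactly one relational construct, in both directions
# (structural reversibility).

catalog_entry <- function(construct_iri, construct_kind, relational_kind,
                          relational_id, extra = NA_character_) {
  list(construct_iri = construct_iri, construct_kind = construct_kind,
       relational_kind = relational_kind, relational_id = relational_id,
       extra = extra)
}

#' Build the ontology-to-schema mapping catalog
#'
#' Enumerates every converted construct of an assembled model: relations
#' (classes, generated classes, object properties, association and data
#' axioms), referential keys (inheritance axioms and the per-association key
#' roles), SQL domains (datatypes) and constraints. The mapping is a
#' bijection: construct identifiers and relational identifiers are both
#' unique, and generated classes carry their canonical expression text.
#'
#' @param ontorel An assembled `ontorel`.
#' @return An `ontorelcat` object (ordered list of entries + lookup index).
#' @export
build_catalog <- function(ontorel) {
  schema <- ontorel$schema
  qual <- function(name) paste0(schema, ".", name)
  onto <- ontorel$onto
  entries <- list()
  add <- function(e) entries[[length(entries) + 1L]] <<- e

  for (id in names(ontorel$relations)) {
    rel <- ontorel$relations[[id]]
    kind <- switch(rel$origin_kind,
                   class = "class", generated_class = "generated_class",
                   object_property = "object_property",
                   class_axiom = "class_axiom", data_axiom = "data_axiom")
    extra <- NA_character_
    if (rel$origin_kind == "generated_class") {
      canon <- names(onto$generated)[match(rel$origin, onto$generated)]
      if (!is.na(canon)) extra <- canon
    }
    ciri <- if (id == "Thing") OWL_THING else rel$origin
    add(catalog_entry(ciri, kind, "relation", qual(rel$name), extra))
  }

  # referential keys: class/property inheritance axioms map to their key;
  # the three keys of an association axiom and the key of a data axiom are
  # distinguished by a role suffix on the construct id
  role_counter <- new.env(parent = emptyenv())
  for (k in ontorel$keys) {
    src <- ontorel$relations[[k$source]]
    if (k$kind == "isa") {
      src_iri <- if (k$source == "Thing") OWL_THING else src$origin
      tgt <- ontorel$relations[[k$target]]
      tgt_iri <- if (k$target == "Thing") "Thing" else
        iri_short(tgt$origin, onto$prefixes)
      ckind <- if (src$kind == "object_property") "property_axiom" else "class_axiom"
      add(catalog_entry(paste(expr_ref(src_iri, onto), "\u2291", tgt_iri),
                        ckind, "referential_key", qual(k$name)))
    } else {
      role <- switch(k$kind, op = "#property", dp = "#class", assoc = NULL)
      if (is.null(role)) {
        # two assoc keys per association: disambiguate by endpoint role
        n <- get0(k$source, envir = role_counter, ifnotfound = 0L) + 1L
        assign(k$source, n, envir = role_counter)
        role <- if (n == 1L) "#domain" else "#range"
      }
      add(catalog_entry(paste0(src$origin, role),
                        if (src$origin_kind == "data_axiom") "data_axiom" else "class_axiom",
                        "referential_key", qual(k$name)))
    }
  }

  for (dom_id in names(ontorel$domains)) {
    d <- ontorel$domains[[dom_id]]
    add(catalog_entry(d$source, "datatype", "domain", qual(d$name)))
  }

  for (con in ontorel$qconstraints) {
    rel <- ontorel$relations[[con$relation]]
    add(catalog_entry(paste0(con$axiom, "#qt"),
                      if (rel$origin_kind == "data_axiom") "data_axiom" else "class_axiom",
                      "constraint", qual(con$name)))
  }
  for (con in ontorel$mconstraints) {
    add(catalog_entry(paste0(con$target, "#membership"), "generated_class",
                      "constraint", qual(con$name)))
  }

  ciri <- vapply(entries, function(e) e$construct_iri, character(1))
  rid <- vapply(entries, function(e) e$relational_id, character(1))
  ckey <- paste(ciri, vapply(entries, function(e) e$construct_kind, character(1)))
  if (anyDuplicated(ckey)) {
    orf_consistency_error(paste0("duplicate catalog construct entries: ",
                                 paste(unique(ckey[duplicated(ckey)]), collapse = "; ")))
  }
  if (anyDuplicated(rid)) {
    orf_consistency_error(paste0("duplicate catalog relational entries: ",
                                 paste(unique(rid[duplicated(rid)]), collapse = "; ")))
  }
  structure(list(entries = entries,
                 by_construct = stats::setNames(seq_along(entries), ciri),
                 by_relational = stats::setNames(seq_along(entries), rid),
                 schema = schema),
            class = "ontorelcat")
}

expr_ref <- function(x, onto) {
  if (startsWith(x, "http://") || startsWith(x, "https://") || startsWith(x, "urn:")) {
    iri_short(x, onto$prefixes)
  } else x
}

#' Look up a catalog entry in either direction
#'
#' Accepts a construct IRI (ontology to schema) or a schema-qualified
#' relational identifier (schema to ontology) and returns the unique entry;
#' an unknown key raises a not-found condition, never an empty success.
#'
#' @param catalog An `ontorelcat`.
#' @param key Construct IRI or relational identifier.
#' @return A catalog entry (named list).
#' @export
catalog_lookup <- function(catalog, key) {
  i <- catalog$by_construct[key]
  if (is.na(i)) i <- catalog$by_relational[key]
  if (is.na(i)) {
    orf_notfound_error(sprintf("no catalog entry for '%s'", key))
  }
  catalog$entries[[unname(i)]]
}

#' @export
print.ontorelcat <- function(x, ...) {
  cat(sprintf("Mapping catalog for schema '%s': %d entries\n",
              x$schema, length(x$entries)))
  invisible(x)
}

#' Write the mapping catalog as JSON
#'
#' @param catalog An `ontorelcat`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  doc <- list(schema = catalog$schema,
              entries = lapply(catalog$entries, function(e) {
                e$extra <- if (is.na(e$extra)) NULL else e$extra
                Filter(Negate(is.null), e)
              }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Validate a serialized catalog against the published schema
#'
#' Structural validation against the JSON schema shipped at
#' `system.file("extdata", "ontorelcat-schema.json", package = "ontorelforge")`:
#' required fields, enumerated kinds and entry uniqueness.
#'
#' @param path Path to a catalog JSON file.
#' @return `TRUE` invisibly; raises an error describing the first violation.
#' @export
validate_catalog_file <- function(path) {
  schema <- jsonlite::read_json(system.file("extdata", "ontorelcat-schema.json",
                                            package = "ontorelforge"))
  doc <- jsonlite::read_json(path)
  for (req in names(schema$properties)) {
    if (req %in% unlist(schema$required) && is.null(doc[[req]])) {
      orf_consistency_error(sprintf("catalog missing required field '%s'", req))
    }
  }
  entry_schema <- schema$properties$entries$items
  kinds <- unlist(entry_schema$properties$construct_kind$enum)
  rkinds <- unlist(entry_schema$properties$relational_kind$enum)
  required <- unlist(entry_schema$required)
  for (e in doc$entries) {
    for (req in required) {
      if (is.null(e[[req]])) {
        orf_consistency_error(sprintf("catalog entry missing field '%s'", req))
      }
    }
    if (!e$construct_kind %in% kinds) {
      orf_consistency_error(sprintf("invalid construct_kind '%s'", e$construct_kind))
    }
    if (!e$relational_kind %in% rkinds) {
      orf_consistency_error(sprintf("invalid relational_kind '%s'", e$relational_kind))
    }
  }
  rids <- vapply(doc$entries, function(e) e$relational_id, character(1))
  if (anyDuplicated(rids)) orf_consistency_error("catalog relational ids are not unique")
  invisible(TRUE)
}
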