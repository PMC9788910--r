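# The normalized ontology model ("muonto"): the converter's internal
# representation of classes, properties, datatypes, individuals, annotations
# and axioms. Axioms may hold complex expressions until the reducer rewrites
# them to the simple ID-operator-ID form.

#' Ontology configuration
#'
#' Parameters of the ingestion stage.
#'
#' @param prefix_map Named character vector mapping prefix to IRI namespace.
#' @param language_priority Ordered character vector of language tags used to
#'   resolve labels and definitions (must be non-empty).
#' @param class_filter Optional character vector of root class IRIs (full or
#'   prefixed against `prefix_map`); only these classes and their descendants
#'   are kept.
#' @param reuse_thing Should the universal class be materialized as the root
#'   `Thing` relation (default `TRUE`)?
#' @return An `ontology_config` object.
#' @export
ontology_config <- function(prefix_map = character(0),
                            language_priority = "en",
                            class_filter = NULL,
                            reuse_thing = TRUE) {
  if (length(language_priority) == 0L) {
    orf_config_error("language_priority must be non-empty")
  }
  structure(list(prefix_map = prefix_map,
                 language_priority = as.character(language_priority),
                 class_filter = class_filter,
                 reuse_thing = isTRUE(reuse_thing)),
            class = "ontology_config")
}

#' Read an ontology configuration from a YAML file
#'
#' Recognized keys: `prefixes` (map prefix -> namespace),
#' `language_priority` (list), `class_filter` (list of IRIs), `reuse_thing`
#' (logical).
#'
#' @param path Path to a YAML file.
#' @return An [ontology_config()].
#' @export
read_ontology_config <- function(path) {
  if (!file.exists(path)) orf_input_error(sprintf("configuration file not found: %s", path))
  y <- yaml::read_yaml(path)
  ontology_config(
    prefix_map = unlist(y$prefixes %||% list()),
    language_priority = unlist(y$language_priority %||% "en"),
    class_filter = if (!is.null(y$class_filter)) unlist(y$class_filter),
    reuse_thing = y$reuse_thing %||% TRUE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- raw axioms -------------------------------------------------------------

#' Raw axiom constructors
#'
#' A raw axiom relates a domain expression to a range through an operator:
#' inheritance, or a property qualified by a quantifier. `kind = "other"`
#' records constructs outside the supported grammar so they are warned about,
#' never silently dropped.
#'
#' @param domain,range `orf_expr` trees (for property inheritance and
#'   data associations, bare IRIs are wrapped/kept as documented below).
#' @return A `raw_axiom` object.
#' @keywords internal
axiom_class_inheritance <- function(domain, range) {
  structure(list(kind = "class_inheritance", domain = domain, range = range),
            class = "raw_axiom")
}

axiom_property_inheritance <- function(sub_iri, super_iri) {
  structure(list(kind = "property_inheritance", domain = sub_iri, range = super_iri),
            class = "raw_axiom")
}

axiom_class_association <- function(domain, property, quantifier, range) {
  structure(list(kind = "class_association", domain = domain,
                 property = property, qt = quantifier, range = range),
            class = "raw_axiom")
}

axiom_data_association <- function(domain, property, quantifier, datatype) {
  structure(list(kind = "data_association", domain = domain,
                 property = property, qt = quantifier, range = datatype),
            class = "raw_axiom")
}

axiom_other <- function(text) {
  structure(list(kind = "other", text = text), class = "raw_axiom")
}

expr_or_iri_text <- function(x) {
  if (inherits(x, "orf_expr")) canonical_form(x) else as.character(x)
}

# Stable identity key for an axiom: used for deduplication and as the
# ontological construct id of axiom-derived relational constructs.
axiom_key <- function(ax) {
  switch(ax$kind,
    class_inheritance = paste(expr_or_iri_text(ax$domain), "\u2291",
                              expr_or_iri_text(ax$range)),
    property_inheritance = paste(ax$domain, "\u2291", ax$range),
    class_association = paste(expr_or_iri_text(ax$domain), ax$property,
                              qt_text(ax$qt), expr_or_iri_text(ax$range)),
    data_association = paste(expr_or_iri_text(ax$domain), ax$property,
                             qt_text(ax$qt), ax$range),
    other = paste("other:", ax$text)
  )
}

#' @export
print.raw_axiom <- function(x, ...) {
  cat(axiom_key(x), "\n")
  invisible(x)
}

#' Is an axiom in the simple canonical form?
#'
#' Simple means both sides are bare identifiers: inheritance between two named
#' constructs, or an association whose domain and range are named classes (or
#' a datatype for data associations).
#'
#' @param ax A `raw_axiom`.
#' @return Logical scalar.
#' @export
is_simple_axiom <- function(ax) {
  switch(ax$kind,
    class_inheritance = is_class_expr(ax$domain) && is_class_expr(ax$range),
    property_inheritance = TRUE,
    class_association = is_class_expr(ax$domain) && is_class_expr(ax$range),
    data_association = is_class_expr(ax$domain),
    other = TRUE
  )
}

# ---- the model --------------------------------------------------------------

# Construct an empty normalized ontology.
muonto <- function(prefixes = character(0), default_prefix = NULL, iri = NULL) {
  structure(list(
    iri = iri,
    prefixes = prefixes,
    default_prefix = default_prefix,
    classes = character(0),
    object_properties = character(0),
    data_properties = character(0),
    datatypes = character(0),
    individuals = list(),          # named list: iri -> character of class IRIs
    annotations = data.frame(subject = character(0), property = character(0),
                             lang = character(0), value = character(0),
                             stringsAsFactors = FALSE),
    axioms = list(),
    warnings = data.frame(code = character(0), message = character(0),
                          subject = character(0), stringsAsFactors = FALSE),
    generated = character(0),      # named: canonical form -> generated IRI
    reduced = FALSE
  ), class = "muonto")
}

onto_add_warning <- function(onto, code, message, subject = NA_character_) {
  onto$warnings <- rbind(onto$warnings,
                         data.frame(code = code, message = message,
                                    subject = subject, stringsAsFactors = FALSE))
  onto
}

onto_add_annotation <- function(onto, subject, property, value, lang = NA_character_) {
  onto$annotations <- rbind(onto$annotations,
                            data.frame(subject = subject, property = property,
                                       lang = lang, value = value,
                                       stringsAsFactors = FALSE))
  onto
}

onto_short <- function(onto) {
  prefixes <- onto$prefixes
  function(iri) iri_short(iri, prefixes)
}

#' @export
print.muonto <- function(x, ...) {
  cat("Normalized ontology",
      if (!is.null(x$iri)) paste0("<", x$iri, ">"), "\n")
  cat(sprintf("  classes: %d (%d generated)  object properties: %d  data properties: %d\n",
              length(x$classes), length(x$generated),
              length(x$object_properties), length(x$data_properties)))
  cat(sprintf("  datatypes: %d  individuals: %d  axioms: %d (%s)  warnings: %d\n",
              length(x$datatypes), length(x$individuals), length(x$axioms),
              if (x$reduced) "reduced" else "pre-reduction", nrow(x$warnings)))
  invisible(x)
}

#' Resolve the display label of an IRI
#'
#' Returns the `rdfs:label` in the highest-priority language available
#' according to the configuration; falls back to an untagged label, then to
#' the IRI local name. Never fails.
#'
#' @param onto A parsed `muonto`.
#' @param iri Full IRI.
#' @param config An [ontology_config()].
#' @return Length-1 character.
#' @export
resolve_label <- function(onto, iri, config = ontology_config()) {
  ann <- onto$annotations
  rows <- ann[ann$subject == iri & ann$property == RDFS_LABEL, , drop = FALSE]
  if (nrow(rows)) {
    for (lang in config$language_priority) {
      hit <- rows$value[!is.na(rows$lang) & rows$lang == lang]
      if (length(hit)) return(hit[[1]])
    }
    untagged <- rows$value[is.na(rows$lang)]
    if (length(untagged)) return(untagged[[1]])
    return(rows$value[[1]])
  }
  iri_local_name(iri)
}

# Highest-priority definition text for an IRI (NA when absent). Definition
# annotation properties are tried in DEFINITION_PROPS order.
resolve_definition <- function(onto, iri, config = ontology_config()) {
  ann <- onto$annotations
  for (prop in DEFINITION_PROPS) {
    rows <- ann[ann$subject == iri & ann$property == prop, , drop = FALSE]
    if (!nrow(rows)) next
    for (lang in config$language_priority) {
      hit <- rows$value[!is.na(rows$lang) & rows$lang == lang]
      if (length(hit)) return(hit[[1]])
    }
    untagged <- rows$value[is.na(rows$lang)]
    if (length(untagged)) return(untagged[[1]])
    return(rows$value[[1]])
  }
  NA_character_
}

# Entity-closure check: every IRI referenced by an axiom must be declared.
# Returns a character vector of undeclared IRIs (empty when closed).
onto_undeclared <- function(onto) {
  declared <- c(onto$classes, onto$object_properties, onto$data_properties,
                onto$datatypes, OWL_THING)
  refs <- character(0)
  for (ax in onto$axioms) {
    refs <- c(refs, switch(ax$kind,
      class_inheritance = c(expr_class_iris(ax$domain), expr_class_iris(ax$range),
                            expr_property_iris(ax$domain), expr_property_iris(ax$range)),
      property_inheritance = c(ax$domain, ax$range),
      class_association = c(expr_class_iris(ax$domain), expr_class_iris(ax$range),
                            expr_property_iris(ax$domain), expr_property_iris(ax$range),
                            ax$property),
      data_association = c(expr_class_iris(ax$domain),
                           expr_property_iris(ax$domain), ax$property, ax$range),
      other = character(0)
    ))
  }
  setdiff(unique(refs), declared)
}
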