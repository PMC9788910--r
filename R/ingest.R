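# Ingestion front-end: format detection, parsing, class filtering and
# entity-closure validation producing the pre-reduction normalized ontology.

detect_owl_format <- function(path) {
  head <- tryCatch(paste(readLines(path, n = 60L, warn = FALSE), collapse = "\n"),
                   error = function(e) orf_input_error(
                     sprintf("cannot read ontology file '%s': %s", path, conditionMessage(e))))
  if (grepl("^\\s*<\\?xml", head) || grepl("<rdf:RDF", head, fixed = TRUE)) return("rdfxml")
  if (grepl("Ontology\\s*\\(", head)) return("functional")
  if (grepl("@prefix|@base|PREFIX\\s", head)) return("turtle")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    owl = "rdfxml", rdf = "rdfxml", xml = "rdfxml",
    ofn = "functional", owx = "rdfxml",
    ttl = "turtle",
    "unknown")
}

parse_any <- function(path, config, depth = 0L) {
  fmt <- detect_owl_format(path)
  if (fmt == "turtle") {
    orf_input_error(paste0("Turtle serialization is not supported; ",
                           "supply RDF/XML or OWL functional-style syntax: ", path))
  }
  if (fmt == "unknown") {
    orf_syntax_error(sprintf("cannot determine OWL serialization of '%s'", path))
  }
  if (fmt == "rdfxml") {
    rdfxml_parse_document(path, config, depth = depth)
  } else {
    text <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
    ofn_parse_document(text, config, source_dir = dirname(path), depth = depth)
  }
}

#' Parse an OWL ontology into the normalized ontology model
#'
#' Reads an OWL document (RDF/XML or functional-style syntax), loads local
#' imports transitively, applies the configured class filter and returns the
#' pre-reduction normalized ontology: entity sets, annotations and raw axioms.
#' Constructs outside the supported grammar are retained as `kind = "other"`
#' axioms and reported in the warning table, never silently dropped.
#'
#' @param path Path to the ontology document.
#' @param config An [ontology_config()].
#' @return A `muonto` object.
#' @examples
#' f <- tempfile(fileext = ".ofn")
#' writeLines(c(
#'   "Prefix(ex:=<http://example.org/onto#>)",
#'   "Ontology(<http://example.org/onto>",
#'   "Declaration(Class(ex:A))",
#'   "Declaration(Class(ex:B))",
#'   "SubClassOf(ex:A ex:B)",
#'   ")"), f)
#' onto <- parse_ontology(f)
#' onto$classes
#' @export
parse_ontology <- function(path, config = ontology_config()) {
  if (!file.exists(path)) {
    orf_input_error(sprintf("ontology file not found: %s", path))
  }
  onto <- parse_any(path, config)

  # resolve the class filter up front so unknown prefixes fail loudly
  if (!is.null(config$class_filter) && length(config$class_filter)) {
    roots <- iri_expand(config$class_filter, onto$prefixes)
    onto <- filter_classes(onto, roots)
  }

  # entity closure: declare referenced-but-undeclared class IRIs with a warning
  undeclared <- onto_undeclared(onto)
  for (iri in undeclared) {
    onto$classes <- union(onto$classes, iri)
    onto <- onto_add_warning(onto, "UNDECLARED_ENTITY",
                             sprintf("IRI referenced in an axiom but not declared; assumed to be a class: %s", iri),
                             iri)
  }
  onto
}

# Keep only the filter roots and their subclass descendants; axioms touching
# excluded classes are dropped with a warning.
filter_classes <- function(onto, roots) {
  missing <- setdiff(roots, onto$classes)
  for (m in missing) {
    onto <- onto_add_warning(onto, "FILTER_ROOT_ABSENT",
                             sprintf("class_filter root not found in ontology: %s", m), m)
  }
  parents <- list()
  for (ax in onto$axioms) {
    if (ax$kind == "class_inheritance" && is_class_expr(ax$domain) && is_class_expr(ax$range)) {
      parents[[ax$domain$iri]] <- c(parents[[ax$domain$iri]], ax$range$iri)
    }
  }
  children_of <- list()
  for (child in names(parents)) {
    for (p in parents[[child]]) children_of[[p]] <- c(children_of[[p]], child)
  }
  keep <- character(0)
  queue <- intersect(roots, onto$classes)
  while (length(queue)) {
    x <- queue[[1]]; queue <- queue[-1L]
    if (x %in% keep) next
    keep <- c(keep, x)
    queue <- c(queue, children_of[[x]] %||% character(0))
  }
  dropped <- setdiff(onto$classes, keep)
  onto$classes <- intersect(onto$classes, keep)
  keep_ax <- logical(length(onto$axioms))
  for (i in seq_along(onto$axioms)) {
    ax <- onto$axioms[[i]]
    refs <- switch(ax$kind,
      class_inheritance = c(expr_class_iris(ax$domain), expr_class_iris(ax$range)),
      class_association = c(expr_class_iris(ax$domain), expr_class_iris(ax$range)),
      data_association = expr_class_iris(ax$domain),
      character(0))
    refs <- setdiff(refs, OWL_THING)
    keep_ax[i] <- all(refs %in% onto$classes)
  }
  if (any(!keep_ax)) {
    onto <- onto_add_warning(onto, "FILTERED_AXIOMS",
                             sprintf("%d axioms dropped by class_filter", sum(!keep_ax)))
  }
  onto$axioms <- onto$axioms[keep_ax]
  onto$individuals <- lapply(onto$individuals, function(m) intersect(m, onto$classes))
  onto$annotations <- onto$annotations[!(onto$annotations$subject %in% dropped), , drop = FALSE]
  onto
}
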