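# OWL 2 functional-style syntax: tokenizer, recursive-descent parser and
# serializer. The subset covered is the one the converter consumes: entity
# declarations, SubClassOf / SubObjectPropertyOf axioms with union,
# intersection and quantified-restriction expressions, data restrictions,
# class assertions and annotation assertions. Anything else is recorded as an
# unsupported construct and warned about.

# ---- tokenizer --------------------------------------------------------------

ofn_tokenize <- function(text) {
  # strip comments (# to end of line, outside strings handled crudely: OWL
  # functional files from this package never embed '#' in strings unquoted)
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  line <- 1L
  push <- function(type, value, lang = NA_character_) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value,
                                           lang = lang, line = line)
  }
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch == "\n") { line <- line + 1L; i <- i + 1L; next }
    if (grepl("^[ \t\r]$", ch)) { i <- i + 1L; next }
    if (ch == "#") { while (i <= n && substr(text, i, i) != "\n") i <- i + 1L; next }
    if (ch == "(") { push("LPAR", "("); i <- i + 1L; next }
    if (ch == ")") { push("RPAR", ")"); i <- i + 1L; next }
    if (substr(text, i, i + 1L) == ":=") { push("EQ", ":="); i <- i + 2L; next }
    if (ch == "<") {
      j <- regexpr(">", substr(text, i, n), fixed = TRUE)
      if (j < 0) orf_syntax_error(sprintf("line %d: unterminated IRI", line))
      push("IRI", substr(text, i + 1L, i + j - 2L))
      i <- i + j
      next
    }
    if (ch == "\"") {
      j <- i + 1L
      buf <- character(0)
      while (j <= n) {
        cj <- substr(text, j, j)
        if (cj == "\\") { buf <- c(buf, substr(text, j + 1L, j + 1L)); j <- j + 2L; next }
        if (cj == "\"") break
        if (cj == "\n") line <- line + 1L
        buf <- c(buf, cj)
        j <- j + 1L
      }
      if (j > n) orf_syntax_error(sprintf("line %d: unterminated string", line))
      val <- paste(buf, collapse = "")
      j <- j + 1L
      lang <- NA_character_
      if (substr(text, j, j) == "@") {
        m <- regmatches(substr(text, j, n), regexpr("^@[A-Za-z][A-Za-z0-9-]*", substr(text, j, n)))
        lang <- substring(m, 2L)
        j <- j + nchar(m)
      } else if (substr(text, j, j + 1L) == "^^") {
        # typed literal: consume the datatype token, keep the lexical form
        j <- j + 2L
        m <- regmatches(substr(text, j, n),
                        regexpr("^(<[^>]*>|[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_.-]+)", substr(text, j, n)))
        j <- j + nchar(m)
      }
      push("STRING", val, lang)
      i <- j
      next
    }
    m <- regmatches(substr(text, i, n),
                    regexpr("^[A-Za-z_][A-Za-z0-9_.-]*(:[A-Za-z0-9_.-]+)?|^[0-9]+",
                            substr(text, i, n)))
    if (length(m) && nzchar(m)) {
      if (grepl("^[0-9]+$", m)) push("NUM", m) else push("NAME", m)
      i <- i + nchar(m)
      next
    }
    orf_syntax_error(sprintf("line %d: unexpected character '%s'", line, ch))
  }
  tokens
}

# Parse the token stream into generic s-expression nodes:
# list(head = <name>, args = list(...), line) or leaf tokens.
ofn_parse_sexprs <- function(tokens) {
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  advance <- function() { t <- tokens[[pos]]; pos <<- pos + 1L; t }
  parse_node <- function() {
    t <- advance()
    if (t$type == "NAME" && !is.null(peek()) && peek()$type == "LPAR") {
      advance()  # consume LPAR
      args <- list()
      repeat {
        nxt <- peek()
        if (is.null(nxt)) orf_syntax_error(sprintf("line %d: unclosed '%s('", t$line, t$value))
        if (nxt$type == "RPAR") { advance(); break }
        args[[length(args) + 1L]] <- parse_node()
      }
      return(list(head = t$value, args = args, line = t$line, sexp = TRUE))
    }
    t
  }
  out <- list()
  while (!is.null(peek())) out[[length(out) + 1L]] <- parse_node()
  out
}

is_sexp <- function(x, head = NULL) {
  isTRUE(x$sexp) && (is.null(head) || x$head == head)
}

# Serialize an s-expression node back to text (used in warning messages).
ofn_deparse <- function(x) {
  if (isTRUE(x$sexp)) {
    paste0(x$head, "(", paste(vapply(x$args, ofn_deparse, character(1)), collapse = " "), ")")
  } else if (x$type == "IRI") {
    paste0("<", x$value, ">")
  } else if (x$type == "STRING") {
    paste0("\"", x$value, "\"", if (!is.na(x$lang)) paste0("@", x$lang) else "")
  } else {
    x$value
  }
}

# ---- document interpretation ------------------------------------------------

BUILTIN_PREFIXES <- c(
  owl  = "http://www.w3.org/2002/07/owl#",
  rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  xsd  = "http://www.w3.org/2001/XMLSchema#",
  skos = "http://www.w3.org/2004/02/skos/core#"
)

ofn_parse_document <- function(text, config, source_dir = NULL, depth = 0L) {
  nodes <- ofn_parse_sexprs(ofn_tokenize(text))
  prefixes <- c(BUILTIN_PREFIXES, config$prefix_map)
  onto_nodes <- NULL
  onto_iri <- NULL
  for (node in nodes) {
    if (is_sexp(node, "Prefix")) {
      # Prefix(ex:=<http://...>) tokenizes as NAME("ex") EQ IRI
      leafs <- Filter(function(x) !isTRUE(x$sexp), node$args)
      name_tok <- Filter(function(x) x$type == "NAME", leafs)
      iri_tok <- Filter(function(x) x$type == "IRI", leafs)
      if (length(name_tok) == 1L && length(iri_tok) == 1L) {
        pfx <- sub(":$", "", name_tok[[1]]$value)
        prefixes[[pfx]] <- iri_tok[[1]]$value
      } else {
        orf_syntax_error(sprintf("line %d: malformed Prefix declaration", node$line))
      }
    } else if (is_sexp(node, "Ontology")) {
      onto_nodes <- node$args
      if (length(node$args) && !isTRUE(node$args[[1]]$sexp) &&
          node$args[[1]]$type == "IRI") {
        onto_iri <- node$args[[1]]$value
        onto_nodes <- node$args[-1L]
        # optional version IRI
        if (length(onto_nodes) && !isTRUE(onto_nodes[[1]]$sexp) &&
            onto_nodes[[1]]$type == "IRI") {
          onto_nodes <- onto_nodes[-1L]
        }
      }
    }
  }
  if (is.null(onto_nodes)) orf_syntax_error("no Ontology(...) element found")

  default_prefix <- NULL
  user_pfx <- setdiff(names(prefixes), names(BUILTIN_PREFIXES))
  if (length(user_pfx)) default_prefix <- user_pfx[[1]]
  onto <- muonto(prefixes = prefixes, default_prefix = default_prefix, iri = onto_iri)

  expand <- function(tok) {
    if (tok$type == "IRI") return(tok$value)
    if (tok$type == "NAME") return(iri_expand(tok$value, prefixes))
    orf_syntax_error(sprintf("line %d: expected an IRI, got '%s'", tok$line, tok$value))
  }

  # expression interpreter; returns orf_expr or a data-restriction marker
  as_expr <- function(node) {
    if (!isTRUE(node$sexp)) {
      iri <- expand(node)
      return(ex_class(iri))
    }
    a <- node$args
    switch(node$head,
      ObjectUnionOf = ,
      ObjectIntersectionOf = {
        if (length(a) < 2L) orf_syntax_error(sprintf("line %d: %s needs >= 2 operands", node$line, node$head))
        fold_nary(if (node$head == "ObjectUnionOf") "union" else "intersection",
                  lapply(a, as_expr))
      },
      ObjectSomeValuesFrom = ex_restriction(expand(a[[1]]), qt(1L, Inf), as_expr(a[[2]])),
      ObjectAllValuesFrom = ex_restriction(expand(a[[1]]), qt(0L, Inf), as_expr(a[[2]])),
      ObjectMinCardinality = ex_restriction(expand(a[[2]]), qt(as.integer(a[[1]]$value), Inf),
                                            if (length(a) >= 3L) as_expr(a[[3]]) else ex_class(OWL_THING)),
      ObjectMaxCardinality = ex_restriction(expand(a[[2]]), qt(0L, as.integer(a[[1]]$value)),
                                            if (length(a) >= 3L) as_expr(a[[3]]) else ex_class(OWL_THING)),
      ObjectExactCardinality = {
        k <- as.integer(a[[1]]$value)
        ex_restriction(expand(a[[2]]), qt(k, k),
                       if (length(a) >= 3L) as_expr(a[[3]]) else ex_class(OWL_THING))
      },
      orf_syntax_error(sprintf("line %d: unsupported class expression %s", node$line, node$head))
    )
  }

  # data restriction at the top of a SubClassOf right-hand side
  as_data_restriction <- function(node) {
    a <- node$args
    dt_or_default <- function(tok) if (is.null(tok)) paste0(XSD_NS, "string") else expand(tok)
    switch(node$head,
      DataSomeValuesFrom = list(property = expand(a[[1]]), qt = qt(1L, Inf),
                                datatype = expand(a[[2]])),
      DataAllValuesFrom = list(property = expand(a[[1]]), qt = qt(0L, Inf),
                               datatype = expand(a[[2]])),
      DataMinCardinality = list(property = expand(a[[2]]),
                                qt = qt(as.integer(a[[1]]$value), Inf),
                                datatype = dt_or_default(if (length(a) >= 3L) a[[3]])),
      DataMaxCardinality = list(property = expand(a[[2]]),
                                qt = qt(0L, as.integer(a[[1]]$value)),
                                datatype = dt_or_default(if (length(a) >= 3L) a[[3]])),
      DataExactCardinality = {
        k <- as.integer(a[[1]]$value)
        list(property = expand(a[[2]]), qt = qt(k, k),
             datatype = dt_or_default(if (length(a) >= 3L) a[[3]]))
      },
      NULL
    )
  }

  data_heads <- c("DataSomeValuesFrom", "DataAllValuesFrom", "DataMinCardinality",
                  "DataMaxCardinality", "DataExactCardinality")

  record_other <- function(node) {
    txt <- ofn_deparse(node)
    onto$axioms[[length(onto$axioms) + 1L]] <<- axiom_other(txt)
    onto <<- onto_add_warning(onto, "UNSUPPORTED_CONSTRUCT",
                              sprintf("line %d: unsupported construct retained as-is: %s",
                                      node$line, substr(txt, 1, 200)),
                              subject = txt)
  }

  for (node in onto_nodes) {
    if (!isTRUE(node$sexp)) next
    h <- node$head
    a <- node$args
    tryCatch({
      if (h == "Import") {
        imp_iri <- expand(a[[1]])
        resolved <- FALSE
        if (!is.null(source_dir) && depth < 8L) {
          cand <- file.path(source_dir, basename(imp_iri))
          if (file.exists(cand)) {
            imported <- ofn_parse_document(paste(readLines(cand, warn = FALSE), collapse = "\n"),
                                           config, source_dir = source_dir, depth = depth + 1L)
            onto <- merge_muonto(onto, imported)
            resolved <- TRUE
          }
        }
        if (!resolved) {
          onto <- onto_add_warning(onto, "IMPORT_UNRESOLVED",
                                   sprintf("import not resolved locally: %s", imp_iri), imp_iri)
        }
      } else if (h == "Declaration") {
        d <- a[[1]]
        iri <- expand(d$args[[1]])
        switch(d$head,
          Class = { onto$classes <- union(onto$classes, iri) },
          ObjectProperty = { onto$object_properties <- union(onto$object_properties, iri) },
          DataProperty = { onto$data_properties <- union(onto$data_properties, iri) },
          Datatype = { onto$datatypes <- union(onto$datatypes, iri) },
          NamedIndividual = {
            if (is.null(onto$individuals[[iri]])) onto$individuals[[iri]] <- character(0)
          },
          AnnotationProperty = { NULL },
          record_other(node)
        )
      } else if (h == "SubClassOf") {
        rhs <- a[[2]]
        if (isTRUE(rhs$sexp) && rhs$head %in% data_heads) {
          dr <- as_data_restriction(rhs)
          onto$datatypes <- union(onto$datatypes, dr$datatype)
          onto$axioms[[length(onto$axioms) + 1L]] <-
            axiom_data_association(as_expr(a[[1]]), dr$property, dr$qt, dr$datatype)
        } else {
          lhs <- as_expr(a[[1]])
          rhse <- as_expr(rhs)
          if (rhse$node == "restriction") {
            # top-level restriction: the property + quantifier become the
            # axiom operator, per the simple-axiom grammar
            onto$axioms[[length(onto$axioms) + 1L]] <-
              axiom_class_association(lhs, rhse$property, rhse$qt, rhse$operand)
          } else {
            onto$axioms[[length(onto$axioms) + 1L]] <- axiom_class_inheritance(lhs, rhse)
          }
        }
      } else if (h == "SubObjectPropertyOf") {
        onto$axioms[[length(onto$axioms) + 1L]] <-
          axiom_property_inheritance(expand(a[[1]]), expand(a[[2]]))
      } else if (h == "ObjectPropertyDomain") {
        if (!isTRUE(a[[2]]$sexp)) {
          onto$axioms[[length(onto$axioms) + 1L]] <-
            axiom_class_association(ex_class(expand(a[[2]])), expand(a[[1]]),
                                    qt(0L, Inf), ex_class(OWL_THING))
        } else record_other(node)
      } else if (h == "ObjectPropertyRange") {
        if (!isTRUE(a[[2]]$sexp)) {
          onto$axioms[[length(onto$axioms) + 1L]] <-
            axiom_class_association(ex_class(OWL_THING), expand(a[[1]]),
                                    qt(0L, Inf), ex_class(expand(a[[2]])))
        } else record_other(node)
      } else if (h == "DataPropertyRange") {
        onto$datatypes <- union(onto$datatypes, expand(a[[2]]))
      } else if (h == "ClassAssertion") {
        if (isTRUE(a[[1]]$sexp)) { record_other(node) } else {
          cls <- expand(a[[1]]); ind <- expand(a[[2]])
          onto$individuals[[ind]] <- union(onto$individuals[[ind]] %||% character(0), cls)
        }
      } else if (h == "AnnotationAssertion") {
        prop <- expand(a[[1]]); subj <- expand(a[[2]])
        val <- a[[3]]
        if (!isTRUE(val$sexp) && val$type == "STRING") {
          onto <- onto_add_annotation(onto, subj, prop, val$value, val$lang)
        } else {
          onto <- onto_add_annotation(onto, subj, prop, ofn_deparse(val))
        }
      } else {
        record_other(node)
      }
    }, orf_syntax_error = function(e) stop(e))
  }
  onto
}

# Merge an imported ontology into the importing one (entities, axioms,
# annotations, warnings). Prefixes of the importer win on clash.
merge_muonto <- function(a, b) {
  a$prefixes <- c(a$prefixes, b$prefixes[setdiff(names(b$prefixes), names(a$prefixes))])
  a$classes <- union(a$classes, b$classes)
  a$object_properties <- union(a$object_properties, b$object_properties)
  a$data_properties <- union(a$data_properties, b$data_properties)
  a$datatypes <- union(a$datatypes, b$datatypes)
  for (ind in names(b$individuals)) {
    a$individuals[[ind]] <- union(a$individuals[[ind]] %||% character(0),
                                  b$individuals[[ind]])
  }
  a$annotations <- rbind(a$annotations, b$annotations)
  a$axioms <- c(a$axioms, b$axioms)
  a$warnings <- rbind(a$warnings, b$warnings)
  a
}

# ---- serializer -------------------------------------------------------------

ofn_iri_ref <- function(iri, prefixes) {
  s <- iri_short(iri, prefixes)
  if (startsWith(s, "<")) s else s
}

ofn_expr <- function(expr, prefixes) {
  sh <- function(iri) ofn_iri_ref(iri, prefixes)
  switch(expr$node,
    class = sh(expr$iri),
    union = sprintf("ObjectUnionOf(%s %s)",
                    ofn_expr(expr$left, prefixes), ofn_expr(expr$right, prefixes)),
    intersection = sprintf("ObjectIntersectionOf(%s %s)",
                           ofn_expr(expr$left, prefixes), ofn_expr(expr$right, prefixes)),
    restriction = ofn_restriction(expr$property, expr$qt,
                                  ofn_expr(expr$operand, prefixes), prefixes, data = FALSE)
  )
}

ofn_restriction <- function(property, quant, filler, prefixes, data = FALSE) {
  p <- ofn_iri_ref(property, prefixes)
  pre <- if (data) "Data" else "Object"
  if (quant$min == 1L && is.infinite(quant$max)) {
    sprintf("%sSomeValuesFrom(%s %s)", pre, p, filler)
  } else if (quant$min == 0L && is.infinite(quant$max)) {
    sprintf("%sAllValuesFrom(%s %s)", pre, p, filler)
  } else if (is.infinite(quant$max)) {
    sprintf("%sMinCardinality(%d %s %s)", pre, quant$min, p, filler)
  } else if (quant$min == 0L) {
    sprintf("%sMaxCardinality(%d %s %s)", pre, quant$max, p, filler)
  } else if (quant$min == quant$max) {
    sprintf("%sExactCardinality(%d %s %s)", pre, quant$min, p, filler)
  } else {
    sprintf("%sIntersectionOf(%sMinCardinality(%d %s %s) %sMaxCardinality(%d %s %s))",
            if (data) "Data" else "Object",
            pre, quant$min, p, filler, pre, quant$max, p, filler)
  }
}

#' Serialize a normalized ontology to OWL functional-style syntax
#'
#' Writes the model back out as a functional-syntax document; this is the
#' format used both for generated fixtures and for the post-reduction
#' normalized-ontology dump.
#'
#' @param onto A `muonto`.
#' @param path Optional file path; when `NULL` the text is returned invisibly
#'   without writing.
#' @return The document text, invisibly.
#' @export
write_functional <- function(onto, path = NULL) {
  prefixes <- onto$prefixes
  sh <- function(iri) ofn_iri_ref(iri, prefixes)
  lines <- character(0)
  user <- prefixes[setdiff(names(prefixes), names(BUILTIN_PREFIXES))]
  for (p in names(BUILTIN_PREFIXES)) {
    lines <- c(lines, sprintf("Prefix(%s:=<%s>)", p, BUILTIN_PREFIXES[[p]]))
  }
  for (p in names(user)) {
    lines <- c(lines, sprintf("Prefix(%s:=<%s>)", p, user[[p]]))
  }
  lines <- c(lines, "", sprintf("Ontology(%s",
                                if (!is.null(onto$iri)) paste0("<", onto$iri, ">") else ""))
  decl <- function(kind, iris) {
    vapply(iris, function(i) sprintf("Declaration(%s(%s))", kind, sh(i)), character(1))
  }
  lines <- c(lines,
             decl("Class", onto$classes),
             decl("ObjectProperty", onto$object_properties),
             decl("DataProperty", onto$data_properties),
             decl("Datatype", onto$datatypes),
             decl("NamedIndividual", names(onto$individuals)))
  for (ax in onto$axioms) {
    lines <- c(lines, switch(ax$kind,
      class_inheritance = sprintf("SubClassOf(%s %s)",
                                  ofn_expr(ax$domain, prefixes), ofn_expr(ax$range, prefixes)),
      property_inheritance = sprintf("SubObjectPropertyOf(%s %s)", sh(ax$domain), sh(ax$range)),
      class_association = sprintf("SubClassOf(%s %s)", ofn_expr(ax$domain, prefixes),
                                  ofn_restriction(ax$property, ax$qt,
                                                  ofn_expr(ax$range, prefixes), prefixes)),
      data_association = sprintf("SubClassOf(%s %s)", ofn_expr(ax$domain, prefixes),
                                 ofn_restriction(ax$property, ax$qt, sh(ax$range),
                                                 prefixes, data = TRUE)),
      other = paste0("# unsupported: ", ax$text)
    ))
  }
  for (ind in names(onto$individuals)) {
    for (cls in onto$individuals[[ind]]) {
      lines <- c(lines, sprintf("ClassAssertion(%s %s)", sh(cls), sh(ind)))
    }
  }
  ann <- onto$annotations
  if (nrow(ann)) {
    for (k in seq_len(nrow(ann))) {
      lang <- if (!is.na(ann$lang[k])) paste0("@", ann$lang[k]) else ""
      val <- gsub("\"", "\\\\\"", ann$value[k])
      lines <- c(lines, sprintf("AnnotationAssertion(%s %s \"%s\"%s)",
                                sh(ann$property[k]), sh(ann$subject[k]), val, lang))
    }
  }
  lines <- c(lines, ")")
  text <- paste(lines, collapse = "\n")
  if (!is.null(path)) writeLines(text, path, useBytes = TRUE)
  invisible(text)
}
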