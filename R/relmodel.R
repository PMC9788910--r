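# Conversion of the reduced normalized ontology into the ontological-
# relational model: one relational construct per ontological construct.
#   class                  -> relation with a single iid attribute (PK)
#   object property        -> relation (subject_iid, object_iid), PK on both
#   inheritance axiom      -> "isa" referential key sub -> super
#   class association axiom-> association relation + 3 referential keys
#                             (+ quantification constraint when bounded)
#   data association axiom -> data relation + 1 referential key
#   datatype               -> SQL domain (user-defined type)
#   annotation             -> comment on the relational construct
#   individual             -> tuples in its class relations (optional)

#' Relational database configuration
#'
#' Parameters of the conversion and DDL generation stages.
#'
#' @param schema_name Target SQL schema name.
#' @param max_identifier_length Identifier length limit (>= 16); longer names
#'   are truncated with a deterministic hash suffix.
#' @param iid_base_type SQL base type of the individual-identifier domain;
#'   `NULL` picks the dialect default (`uuid` on PostgreSQL, `TEXT` on
#'   SQLite), matching the recommendation that iids be GUIDs.
#' @param type_map Named character vector mapping datatype IRIs to SQL base
#'   types; see [default_type_map()].
#' @param default_type Fallback SQL base type for unmapped datatypes.
#' @param comment_language_priority Language tags tried, in order, when
#'   selecting definition texts for SQL comments.
#' @param view_languages Language tags for which label views are emitted.
#' @param dialect `"postgresql"` (default) or `"sqlite"`.
#' @param include_individuals Should individuals be converted into insertion
#'   tuples? Off by default.
#' @return An `rdb_config` object.
#' @export
rdb_config <- function(schema_name = "ontorel",
                       max_identifier_length = 63L,
                       iid_base_type = NULL,
                       type_map = default_type_map(),
                       default_type = "TEXT",
                       comment_language_priority = "en",
                       view_languages = "en",
                       dialect = "postgresql",
                       include_individuals = FALSE) {
  max_identifier_length <- as.integer(max_identifier_length)
  if (is.na(max_identifier_length) || max_identifier_length < 16L) {
    orf_config_error("max_identifier_length must be at least 16")
  }
  structure(list(schema_name = schema_name,
                 max_identifier_length = max_identifier_length,
                 iid_base_type = iid_base_type,
                 type_map = type_map,
                 default_type = default_type,
                 comment_language_priority = comment_language_priority,
                 view_languages = view_languages,
                 dialect = dialect,
                 include_individuals = isTRUE(include_individuals)),
            class = "rdb_config")
}

#' Read an RDB configuration from a YAML file
#'
#' Recognized keys: `schema`, `max_identifier_length`, `iid_base_type`,
#' `type_map` (map datatype IRI -> SQL base type, merged over the defaults),
#' `default_type`, `comment_language_priority`, `view_languages`, `dialect`,
#' `include_individuals`.
#'
#' @param path Path to a YAML file.
#' @return An [rdb_config()].
#' @export
read_rdb_config <- function(path) {
  if (!file.exists(path)) orf_input_error(sprintf("configuration file not found: %s", path))
  y <- yaml::read_yaml(path)
  tm <- default_type_map()
  if (!is.null(y$type_map)) {
    user <- unlist(y$type_map)
    tm[names(user)] <- user
  }
  rdb_config(
    schema_name = y$schema %||% "ontorel",
    max_identifier_length = y$max_identifier_length %||% 63L,
    iid_base_type = y$iid_base_type,
    type_map = tm,
    default_type = y$default_type %||% "TEXT",
    comment_language_priority = unlist(y$comment_language_priority %||% "en"),
    view_languages = unlist(y$view_languages %||% "en"),
    dialect = y$dialect %||% "postgresql",
    include_individuals = y$include_individuals %||% FALSE
  )
}

#' Default OWL-to-SQL type mapping
#'
#' Named character vector mapping XSD datatype IRIs to SQL base types; the
#' string type maps to `TEXT` so that the generated domain reads
#' `CREATE DOMAIN "xsd:String" AS TEXT`.
#'
#' @return Named character vector.
#' @export
default_type_map <- function() {
  x <- function(l) paste0(XSD_NS, l)
  stats::setNames(
    c("TEXT", "TEXT", "TEXT", "TEXT", "BOOLEAN", "INTEGER", "INTEGER", "BIGINT",
      "SMALLINT", "INTEGER", "INTEGER", "NUMERIC", "DOUBLE PRECISION", "REAL",
      "TIMESTAMP", "DATE", "TIME", "TEXT"),
    c(x("string"), x("normalizedString"), x("token"), x("anyURI"), x("boolean"),
      x("integer"), x("int"), x("long"), x("short"), x("nonNegativeInteger"),
      x("positiveInteger"), x("decimal"), x("double"), x("float"),
      x("dateTime"), x("date"), x("time"),
      "http://www.w3.org/2000/01/rdf-schema#Literal"))
}

# Domain display name for a datatype: short IRI with the local name's first
# letter capitalized ("xsd:string" -> "xsd:String"), matching the convention
# that user-defined types are named after the ontology datatype.
datatype_domain_name <- function(iri, prefixes) {
  s <- iri_short(iri, prefixes)
  if (startsWith(s, "<")) s <- iri_local_name(iri)
  parts <- strsplit(s, ":", fixed = TRUE)[[1]]
  local <- parts[length(parts)]
  local <- paste0(toupper(substr(local, 1, 1)), substring(local, 2))
  if (length(parts) > 1L) paste0(paste(parts[-length(parts)], collapse = ":"), ":", local)
  else local
}

attribute <- function(name, domain, role, origin_iri = NULL) {
  list(name = name, domain = domain, role = role, origin_iri = origin_iri)
}

relation <- function(id, name, origin, origin_kind, attributes, primary_key, kind) {
  structure(list(id = id, name = name, origin = origin, origin_kind = origin_kind,
                 attributes = attributes, primary_key = primary_key, kind = kind),
            class = "orf_relation")
}

referential_key <- function(name, kind, source, source_attrs, target, target_attrs) {
  structure(list(name = name, kind = kind, source = source,
                 source_attrs = source_attrs, target = target,
                 target_attrs = target_attrs),
            class = "orf_refkey")
}

# base token for attribute names derived from an IRI: short form with
# non-identifier characters replaced ("ex:Person" -> "ex_Person")
attr_base <- function(iri, prefixes) {
  s <- iri_short(iri, prefixes)
  if (startsWith(s, "<")) s <- iri_local_name(iri)
  gsub("[^A-Za-z0-9]+", "_", s)
}

IID_DOMAIN <- "iid_type"

# ---- per-construct conversions ---------------------------------------------

#' Convert one class into its relation
#'
#' A class becomes a relation with a single individual-identifier attribute
#' named `<shortIri>_iid`, typed by the shared iid domain and forming the
#' primary key.
#'
#' @param iri Class IRI (or `"Thing"` for the universal root relation).
#' @param onto The reduced `muonto` (for labels and prefixes).
#' @param config An [ontology_config()].
#' @param name Optional pre-sanitized relation name (defaults to the resolved
#'   label).
#' @return An `orf_relation`.
#' @export
convert_class <- function(iri, onto, config = ontology_config(), name = NULL) {
  if (identical(iri, "Thing") || identical(iri, OWL_THING)) {
    return(relation("Thing", name %||% "Thing", "Thing", "class",
                    list(attribute("Thing_iid", IID_DOMAIN, "iid")),
                    "Thing_iid", "class"))
  }
  nm <- name %||% resolve_label(onto, iri, config)
  aname <- paste0(attr_base(iri, onto$prefixes), "_iid")
  gen <- iri %in% onto$generated
  relation(iri, nm, iri, if (gen) "generated_class" else "class",
           list(attribute(aname, IID_DOMAIN, "iid", iri)), aname, "class")
}

#' Convert one object property into its relation
#'
#' An object property becomes a relation with two iid attributes,
#' `subject_iid` and `object_iid`, whose pair is the primary key.
#'
#' @inheritParams convert_class
#' @return An `orf_relation`.
#' @export
convert_object_property <- function(iri, onto, config = ontology_config(), name = NULL) {
  nm <- name %||% resolve_label(onto, iri, config)
  relation(iri, nm, iri, "object_property",
           list(attribute("subject_iid", IID_DOMAIN, "iid"),
                attribute("object_iid", IID_DOMAIN, "iid")),
           c("subject_iid", "object_iid"), "object_property")
}

#' Convert an inheritance axiom into an "isa" referential key
#'
#' Class inheritance links the subclass relation's iid to the superclass
#' relation's iid; property inheritance links the (subject_iid, object_iid)
#' pair of the sub-property relation to that of the super-property relation.
#'
#' @param ax A simple `raw_axiom` of kind `class_inheritance` or
#'   `property_inheritance`.
#' @param relations Named list of already converted relations, keyed by id.
#' @param name Optional pre-sanitized key name.
#' @return An `orf_refkey`.
#' @export
convert_inheritance <- function(ax, relations, name = NULL) {
  if (ax$kind == "class_inheritance") {
    src_id <- if (identical(ax$domain$iri, OWL_THING)) "Thing" else ax$domain$iri
    tgt_id <- if (identical(ax$range$iri, OWL_THING)) "Thing" else ax$range$iri
  } else if (ax$kind == "property_inheritance") {
    src_id <- ax$domain; tgt_id <- ax$range
  } else {
    orf_type_error("convert_inheritance expects an inheritance axiom")
  }
  src <- relations[[src_id]]; tgt <- relations[[tgt_id]]
  if (is.null(src) || is.null(tgt)) {
    orf_consistency_error(sprintf("inheritance axiom endpoint not converted: %s",
                                  axiom_key(ax)))
  }
  referential_key(name %||% paste0(src$name, "_isa_", tgt$name), "isa",
                  src$id, src$primary_key, tgt$id, tgt$primary_key)
}

#' Convert a class association axiom
#'
#' `C0 p[qt] C1` becomes an association relation holding the iids of both
#' classes (composite primary key) plus three referential keys: to the
#' domain-class relation, to the range-class relation, and - as an
#' attribute-pair key - to the object-property relation. When the quantifier
#' is bounded (min > 0 or finite max) a quantification constraint is emitted.
#'
#' @param ax A simple `class_association` axiom.
#' @param relations Named list of converted relations keyed by id.
#' @param onto The reduced ontology.
#' @param name Optional pre-sanitized relation name.
#' @return List with `relation`, `keys` (3 `orf_refkey`s) and `constraint`
#'   (a quantification constraint or `NULL`).
#' @export
convert_class_association <- function(ax, relations, onto, name = NULL) {
  dom_id <- if (identical(ax$domain$iri, OWL_THING)) "Thing" else ax$domain$iri
  rng_id <- if (identical(ax$range$iri, OWL_THING)) "Thing" else ax$range$iri
  dom <- relations[[dom_id]]; rng <- relations[[rng_id]]; prop <- relations[[ax$property]]
  if (is.null(dom) || is.null(rng)) {
    orf_consistency_error(sprintf("association endpoint not converted: %s", axiom_key(ax)))
  }
  if (is.null(prop)) {
    orf_consistency_error(sprintf("object property not converted: %s", ax$property))
  }
  d_attr <- dom$primary_key
  r_attr <- rng$primary_key
  if (identical(d_attr, r_attr)) r_attr <- paste0(r_attr, "_o")
  nm <- name %||% paste(dom$name, prop$name, rng$name, sep = "_")
  id <- axiom_key(ax)
  rel <- relation(id, nm, id, "class_axiom",
                  list(attribute(d_attr, IID_DOMAIN, "iid",
                                 if (dom$id != "Thing") dom$origin),
                       attribute(r_attr, IID_DOMAIN, "iid",
                                 if (rng$id != "Thing") rng$origin)),
                  c(d_attr, r_attr), "association")
  keys <- list(
    referential_key(paste0(nm, "_domain"), "assoc", id, d_attr, dom$id, dom$primary_key),
    referential_key(paste0(nm, "_range"), "assoc", id, r_attr, rng$id, rng$primary_key),
    referential_key(paste0(nm, "_op"), "op", id, c(d_attr, r_attr),
                    prop$id, c("subject_iid", "object_iid"))
  )
  con <- NULL
  if (ax$qt$min > 0L || is.finite(ax$qt$max)) {
    con <- list(name = paste0("qc_", nm), relation = id, subject_relation = dom$id,
                subject_attr = dom$primary_key, group_attr = d_attr,
                min = ax$qt$min, max = ax$qt$max, axiom = id)
  }
  list(relation = rel, keys = keys, constraint = con)
}

#' Convert a data association axiom
#'
#' `C0 dp[qt] D` becomes a data relation with the class iid and a value
#' attribute typed by the datatype's SQL domain; its composite primary key
#' covers both attributes and a single referential key points back to the
#' class relation.
#'
#' @param ax A simple `data_association` axiom.
#' @param relations Named list of converted relations keyed by id.
#' @param dom_type The `SqlDomainType` (from [convert_datatype()]) of the
#'   value attribute.
#' @param onto The reduced ontology.
#' @param config An [ontology_config()].
#' @param name Optional pre-sanitized relation name.
#' @return List with `relation`, `key` and `constraint` (or `NULL`).
#' @export
convert_data_association <- function(ax, relations, dom_type, onto,
                                     config = ontology_config(), name = NULL) {
  cls_id <- if (identical(ax$domain$iri, OWL_THING)) "Thing" else ax$domain$iri
  cls <- relations[[cls_id]]
  if (is.null(cls)) {
    orf_consistency_error(sprintf("data association class not converted: %s", axiom_key(ax)))
  }
  if (is.null(dom_type)) {
    orf_type_error(sprintf("no SQL domain registered for datatype %s", ax$range))
  }
  prop_name <- gsub("[^A-Za-z0-9]+", "_", resolve_label(onto, ax$property, config))
  nm <- name %||% paste0(cls$name, "_", prop_name)
  id <- axiom_key(ax)
  val_attr <- prop_name
  rel <- relation(id, nm, id, "data_axiom",
                  list(attribute(cls$primary_key, IID_DOMAIN, "iid",
                                 if (cls$id != "Thing") cls$origin),
                       attribute(val_attr, dom_type$source, "value", ax$property)),
                  c(cls$primary_key, val_attr), "data")
  key <- referential_key(paste0(nm, "_dp"), "dp", id, cls$primary_key,
                         cls$id, cls$primary_key)
  con <- NULL
  if (ax$qt$min > 0L || is.finite(ax$qt$max)) {
    con <- list(name = paste0("qc_", nm), relation = id, subject_relation = cls$id,
                subject_attr = cls$primary_key, group_attr = cls$primary_key,
                min = ax$qt$min, max = ax$qt$max, axiom = id)
  }
  list(relation = rel, key = key, constraint = con)
}

#' Convert a datatype into an SQL domain
#'
#' One user-defined SQL domain per distinct ontology datatype; the base type
#' comes from the configurable type map, unmapped datatypes fall back to the
#' configured default with a warning flag.
#'
#' @param dt Datatype IRI.
#' @param cfg An [rdb_config()].
#' @param prefixes Prefix map used for the domain display name.
#' @return List with `name`, `base`, `source` and logical `fallback`.
#' @export
convert_datatype <- function(dt, cfg, prefixes = BUILTIN_PREFIXES) {
  base <- unname(cfg$type_map[dt])
  fallback <- is.na(base)
  if (fallback) base <- cfg$default_type
  list(name = datatype_domain_name(dt, prefixes), base = base,
       source = dt, fallback = fallback)
}

#' Convert an individual into insertion records
#'
#' Generates one reproducible GUID per individual and one insertion record
#' per membership class relation, propagated upward through the class
#' taxonomy and into the universal `Thing` relation so all relations agree on
#' the identifier.
#'
#' @param ind Individual IRI.
#' @param memberships Character vector of asserted class IRIs.
#' @param relations Named list of converted relations keyed by id.
#' @param superclasses Named list mapping a class IRI to its direct
#'   superclasses.
#' @return List of records `list(relation, attr, iid)`.
#' @export
convert_individual <- function(ind, memberships, relations, superclasses) {
  iid <- orf_guid(ind)
  all_classes <- character(0)
  queue <- memberships
  while (length(queue)) {
    x <- queue[[1]]; queue <- queue[-1L]
    if (x %in% all_classes) next
    if (!x %in% names(relations) && !identical(x, OWL_THING)) {
      orf_consistency_error(sprintf("individual %s is member of unconverted class %s", ind, x))
    }
    all_classes <- c(all_classes, x)
    queue <- c(queue, superclasses[[x]] %||% character(0))
  }
  targets <- c("Thing", setdiff(all_classes, OWL_THING))
  lapply(targets, function(cid) {
    rel <- relations[[cid]]
    list(relation = rel$id, attr = rel$primary_key, iid = iid)
  })
}

# ---- full assembly ----------------------------------------------------------

# direct superclass map from simple class-inheritance axioms
superclass_map <- function(axioms) {
  out <- list()
  for (ax in axioms) {
    if (ax$kind == "class_inheritance") {
      out[[ax$domain$iri]] <- union(out[[ax$domain$iri]] %||% character(0), ax$range$iri)
    }
  }
  out
}

# detect a cycle in the subclass graph; returns NULL or the cycle member IRIs
find_isa_cycle <- function(superclasses) {
  color <- new.env(parent = emptyenv())
  cycle <- NULL
  visit <- function(x, stack) {
    st <- get0(x, envir = color, ifnotfound = "white")
    if (st == "grey") {
      i <- match(x, stack)
      cycle <<- c(stack[i:length(stack)], x)
      return(TRUE)
    }
    if (st == "black") return(FALSE)
    assign(x, "grey", envir = color)
    for (p in superclasses[[x]] %||% character(0)) {
      if (visit(p, c(stack, x))) return(TRUE)
    }
    assign(x, "black", envir = color)
    FALSE
  }
  for (x in names(superclasses)) {
    if (visit(x, character(0))) break
  }
  cycle
}

#' Assemble the complete ontological-relational model
#'
#' Applies every conversion rule to every construct of a fully reduced
#' ontology exactly once and returns the OntoRel model: relations, referential
#' keys, SQL domains, quantification and membership constraints, and comments.
#'
#' @param onto A reduced `muonto` (see [reduce_ontology()]).
#' @param constraints Membership constraints from the reduction.
#' @param config An [ontology_config()].
#' @param cfg An [rdb_config()].
#' @return An `ontorel` object.
#' @export
assemble <- function(onto, constraints = list(), config = ontology_config(),
                     cfg = rdb_config()) {
  if (!isTRUE(onto$reduced)) {
    orf_consistency_error("assemble() requires a reduced ontology; call reduce_ontology() first")
  }
  supers <- superclass_map(onto$axioms)
  cyc <- find_isa_cycle(supers)
  if (!is.null(cyc)) {
    orf_cycle_error(paste0("cyclic subclass axioms detected: ",
                           paste(iri_short(cyc, onto$prefixes), collapse = " -> ")),
                    cycle = cyc)
  }

  taken <- character(0)
  claim <- function(raw) {
    nm <- sanitize_identifier(raw, cfg, taken)
    taken <<- c(taken, nm)
    nm
  }

  relations <- list()
  keys <- list()
  qconstraints <- list()
  warnings <- onto$warnings

  if (config$reuse_thing) {
    relations[["Thing"]] <- convert_class("Thing", onto, config, name = claim("Thing"))
  }

  for (cl in onto$classes) {
    relations[[cl]] <- convert_class(cl, onto, config,
                                     name = claim(resolve_label(onto, cl, config)))
  }
  for (p in onto$object_properties) {
    relations[[p]] <- convert_object_property(p, onto, config,
                                              name = claim(resolve_label(onto, p, config)))
  }

  # domains: the shared iid domain plus one per datatype in use
  dialect <- get_dialect(cfg)
  domains <- list()
  domains[[IID_DOMAIN]] <- list(name = IID_DOMAIN,
                                base = cfg$iid_base_type %||% dialect$iid_base,
                                source = "iid", fallback = FALSE)
  used_datatypes <- unique(c(onto$datatypes,
                             unlist(lapply(onto$axioms, function(ax)
                               if (ax$kind == "data_association") ax$range else NULL))))
  for (dt in used_datatypes) {
    d <- convert_datatype(dt, cfg, onto$prefixes)
    if (d$fallback) {
      warnings <- rbind(warnings, data.frame(
        code = "TYPE_FALLBACK",
        message = sprintf("datatype %s has no SQL mapping; using %s", dt, cfg$default_type),
        subject = dt, stringsAsFactors = FALSE))
    }
    domains[[dt]] <- d
  }

  # inheritance keys; track which classes have a named superclass
  has_super <- character(0)
  seen_keys <- character(0)
  for (ax in onto$axioms) {
    if (ax$kind == "class_inheritance") {
      k <- convert_inheritance(ax, relations, name = NULL)
      kk <- paste(k$source, "->", k$target)
      if (kk %in% seen_keys) next
      seen_keys <- c(seen_keys, kk)
      k$name <- claim(k$name)
      keys[[length(keys) + 1L]] <- k
      has_super <- c(has_super, ax$domain$iri)
    } else if (ax$kind == "property_inheritance") {
      k <- convert_inheritance(ax, relations, name = NULL)
      kk <- paste(k$source, "->", k$target)
      if (kk %in% seen_keys) next
      seen_keys <- c(seen_keys, kk)
      k$name <- claim(k$name)
      keys[[length(keys) + 1L]] <- k
    }
  }
  if (config$reuse_thing) {
    for (cl in setdiff(onto$classes, unique(has_super))) {
      k <- referential_key(claim(paste0(relations[[cl]]$name, "_isa_Thing")), "isa",
                           cl, relations[[cl]]$primary_key, "Thing", "Thing_iid")
      keys[[length(keys) + 1L]] <- k
    }
  }

  for (ax in onto$axioms) {
    if (ax$kind == "class_association") {
      res <- convert_class_association(ax, relations, onto, name = NULL)
      res$relation$name <- claim(res$relation$name)
      relations[[res$relation$id]] <- res$relation
      suffixes <- c("_domain", "_range", "_op")
      for (i in seq_along(res$keys)) {
        k <- res$keys[[i]]
        k$name <- claim(paste0(res$relation$name, suffixes[[i]]))
        keys[[length(keys) + 1L]] <- k
      }
      if (!is.null(res$constraint)) {
        res$constraint$name <- claim(paste0("qc_", res$relation$name))
        qconstraints[[length(qconstraints) + 1L]] <- res$constraint
      }
    } else if (ax$kind == "data_association") {
      res <- convert_data_association(ax, relations, domains[[ax$range]], onto, config)
      res$relation$name <- claim(res$relation$name)
      relations[[res$relation$id]] <- res$relation
      res$key$name <- claim(paste0(res$relation$name, "_dp"))
      keys[[length(keys) + 1L]] <- res$key
      if (!is.null(res$constraint)) {
        res$constraint$name <- claim(paste0("qc_", res$relation$name))
        qconstraints[[length(qconstraints) + 1L]] <- res$constraint
      }
    }
  }

  # membership constraints for generated classes
  mconstraints <- lapply(constraints, function(con) {
    tgt <- relations[[con$target]]
    ops <- lapply(con$operands, function(o) relations[[o]])
    if (is.null(tgt) || any(vapply(ops, is.null, logical(1)))) {
      orf_consistency_error(sprintf("membership constraint endpoint not converted: %s",
                                    con$target))
    }
    list(name = claim(paste0("mc_", con$kind, "_", tgt$name)),
         kind = con$kind, target = tgt$id,
         operands = vapply(ops, function(r) r$id, character(1)))
  })

  # comments: a definition annotation on a converted construct becomes a
  # comment on its relation, with the source IRI appended
  comments <- list()
  for (rel in relations) {
    if (rel$id == "Thing") next
    if (!rel$kind %in% c("class", "object_property")) next
    def <- resolve_definition(onto, rel$origin,
                              ontology_config(language_priority = cfg$comment_language_priority))
    if (rel$origin_kind == "generated_class") {
      canon_key <- names(onto$generated)[match(rel$origin, onto$generated)]
      if (!is.na(canon_key)) {
        def <- sprintf("Generated class representing the expression %s", canon_key)
      }
    }
    if (!is.na(def %||% NA_character_) && !is.null(def)) {
      comments[[length(comments) + 1L]] <-
        list(relation = rel$id,
             text = paste0(def, " [", iri_short(rel$origin, onto$prefixes), "]"))
    }
  }

  inserts <- list()
  if (cfg$include_individuals && length(onto$individuals)) {
    for (ind in names(onto$individuals)) {
      inserts <- c(inserts,
                   convert_individual(ind, onto$individuals[[ind]], relations, supers))
    }
  }

  structure(list(schema = cfg$schema_name,
                 relations = relations,
                 keys = keys,
                 domains = domains,
                 qconstraints = qconstraints,
                 mconstraints = mconstraints,
                 comments = comments,
                 inserts = inserts,
                 warnings = warnings,
                 onto = onto,
                 onto_config = config,
                 rdb_config = cfg),
            class = "ontorel")
}

#' @export
print.ontorel <- function(x, ...) {
  cat(sprintf("OntoRel schema '%s': %d relations, %d referential keys, %d domains\n",
              x$schema, length(x$relations), length(x$keys), length(x$domains)))
  cat(sprintf("  quantification constraints: %d  membership constraints: %d  comments: %d\n",
              length(x$qconstraints), length(x$mconstraints), length(x$comments)))
  invisible(x)
}

#' Summary counts of an assembled model
#'
#' @param ontorel An `ontorel`.
#' @return Named list of construct counts.
#' @export
ontorel_counts <- function(ontorel) {
  list(relations = length(ontorel$relations),
       referential_keys = length(ontorel$keys),
       domains = length(ontorel$domains),
       quantification_constraints = length(ontorel$qconstraints),
       membership_constraints = length(ontorel$mconstraints),
       comments = length(ontorel$comments))
}
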