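# DDL emission from the ontological-relational model: domains, tables in
# dependency order, referential keys, constraint verification routines,
# comments and per-language label views. The emitter is table-driven over a
# dialect descriptor; PostgreSQL (the primary target) and SQLite (used for
# live execution in tests) are shipped.

dquote <- function(x) paste0('"', gsub('"', '""', x), '"')
squote <- function(x) paste0("'", gsub("'", "''", x), "'")

get_dialect <- function(cfg) {
  switch(cfg$dialect,
    postgresql = list(
      name = "postgresql",
      iid_base = "uuid",
      supports_domains = TRUE,
      supports_comments = TRUE,
      fk_mode = "alter",        # foreign keys as ALTER after all tables
      check_mode = "function"   # verification routines as SQL functions
    ),
    sqlite = list(
      name = "sqlite",
      iid_base = "TEXT",
      supports_domains = FALSE, # base types are inlined in column defs
      supports_comments = FALSE,# comments stored in a metadata table
      fk_mode = "inline",       # SQLite cannot ALTER TABLE ... ADD CONSTRAINT
      check_mode = "view"       # verification routines as views
    ),
    orf_config_error(sprintf("unknown SQL dialect '%s'", cfg$dialect))
  )
}

#' Sanitize a raw name into a safe SQL identifier
#'
#' Replaces non-identifier characters, enforces the configured length limit
#' (truncating with a deterministic 6-character hash suffix) and guarantees
#' the result is not among already taken names.
#'
#' @param raw Raw name (label, IRI fragment, ...).
#' @param cfg An [rdb_config()] (supplies `max_identifier_length`).
#' @param taken Character vector of identifiers already in use.
#' @return A length-1 character identifier.
#' @examples
#' sanitize_identifier("person", rdb_config())
#' sanitize_identifier(strrep("long_label_", 10), rdb_config(max_identifier_length = 24))
#' @export
sanitize_identifier <- function(raw, cfg = rdb_config(), taken = character(0)) {
  stopifnot(is.character(raw), length(raw) == 1L, nzchar(raw))
  maxlen <- cfg$max_identifier_length
  base <- gsub("_+", "_", gsub("[^A-Za-z0-9_]", "_", raw))
  base <- sub("^_+", "", sub("_+$", "", base))
  if (!nzchar(base)) base <- "x"
  if (nchar(base) > maxlen) {
    base <- paste0(substr(base, 1L, maxlen - 7L), "_", orf_hash6(raw))
  }
  cand <- base
  i <- 0L
  while (cand %in% taken) {
    i <- i + 1L
    cand <- paste0(substr(base, 1L, maxlen - 7L), "_", orf_hash6(paste0(raw, "#", i)))
  }
  cand
}

#' Order relations so every reference target precedes its source
#'
#' Kahn's algorithm over the referential-key dependency graph; ties are
#' broken by the original relation order so the result is deterministic.
#'
#' @param ontorel An `ontorel`.
#' @return Character vector of relation ids in creation order.
#' @export
topo_order <- function(ontorel) {
  ids <- names(ontorel$relations)
  deps <- stats::setNames(vector("list", length(ids)), ids)
  for (k in ontorel$keys) {
    if (k$source != k$target) deps[[k$source]] <- union(deps[[k$source]], k$target)
  }
  placed <- character(0)
  remaining <- ids
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(id)
      all(deps[[id]] %in% placed), logical(1))]
    if (!length(ready)) {
      orf_cycle_error(paste0("referential dependency cycle among: ",
                             paste(remaining, collapse = ", ")),
                      cycle = remaining)
    }
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  placed
}

# SQL type text of an attribute under a dialect
attr_type <- function(attr, ontorel, dialect) {
  if (dialect$supports_domains) {
    dquote(if (attr$domain == IID_DOMAIN) IID_DOMAIN
           else ontorel$domains[[attr$domain]]$name)
  } else {
    if (attr$domain == IID_DOMAIN) {
      ontorel$rdb_config$iid_base_type %||% dialect$iid_base
    } else {
      ontorel$domains[[attr$domain]]$base
    }
  }
}

# ---- script builders ---------------------------------------------------------

emit_domains <- function(ontorel, dialect) {
  cfg <- ontorel$rdb_config
  lines <- c(sprintf("-- SQL domains for schema %s", cfg$schema_name))
  if (!dialect$supports_domains) {
    lines <- c(lines,
               "-- This dialect has no CREATE DOMAIN; base types are inlined in table definitions.")
    return(paste(lines, collapse = "\n"))
  }
  lines <- c(lines,
             sprintf("CREATE SCHEMA IF NOT EXISTS %s;", dquote(cfg$schema_name)),
             sprintf("SET search_path = %s;", dquote(cfg$schema_name)))
  iid <- ontorel$domains[[IID_DOMAIN]]
  lines <- c(lines, sprintf("CREATE DOMAIN %s AS %s;", dquote(iid$name), iid$base))
  rest <- ontorel$domains[setdiff(names(ontorel$domains), IID_DOMAIN)]
  for (d in rest) {
    lines <- c(lines, sprintf("CREATE DOMAIN %s AS %s;", dquote(d$name), d$base))
  }
  paste(lines, collapse = "\n")
}

emit_tables <- function(ontorel, dialect, order) {
  cfg <- ontorel$rdb_config
  lines <- c(sprintf("-- Tables for schema %s (dependency order)", cfg$schema_name))
  if (dialect$name == "postgresql") {
    lines <- c(lines, sprintf("SET search_path = %s;", dquote(cfg$schema_name)))
  }
  fks_by_source <- split(ontorel$keys,
                         vapply(ontorel$keys, function(k) k$source, character(1)))
  for (id in order) {
    rel <- ontorel$relations[[id]]
    cols <- vapply(rel$attributes, function(a)
      sprintf("  %s %s NOT NULL", dquote(a$name), attr_type(a, ontorel, dialect)),
      character(1))
    pk <- sprintf("  PRIMARY KEY (%s)",
                  paste(dquote(rel$primary_key), collapse = ", "))
    body <- c(cols, pk)
    if (dialect$fk_mode == "inline") {
      for (k in fks_by_source[[id]] %||% list()) {
        tgt <- ontorel$relations[[k$target]]
        body <- c(body, sprintf("  FOREIGN KEY (%s) REFERENCES %s (%s)",
                                paste(dquote(k$source_attrs), collapse = ", "),
                                dquote(tgt$name),
                                paste(dquote(k$target_attrs), collapse = ", ")))
      }
    }
    lines <- c(lines, sprintf("CREATE TABLE %s (\n%s\n);",
                              dquote(rel$name), paste(body, collapse = ",\n")))
  }
  paste(lines, collapse = "\n")
}

emit_keys <- function(ontorel, dialect) {
  cfg <- ontorel$rdb_config
  lines <- c(sprintf("-- Referential keys for schema %s", cfg$schema_name))
  if (dialect$fk_mode != "alter") {
    lines <- c(lines, "-- Foreign keys are inlined in the table definitions for this dialect.")
    return(paste(lines, collapse = "\n"))
  }
  lines <- c(lines, sprintf("SET search_path = %s;", dquote(cfg$schema_name)))
  for (k in ontorel$keys) {
    src <- ontorel$relations[[k$source]]
    tgt <- ontorel$relations[[k$target]]
    lines <- c(lines, sprintf(
      "ALTER TABLE %s ADD CONSTRAINT %s FOREIGN KEY (%s) REFERENCES %s (%s);",
      dquote(src$name), dquote(k$name),
      paste(dquote(k$source_attrs), collapse = ", "),
      dquote(tgt$name),
      paste(dquote(k$target_attrs), collapse = ", ")))
  }
  paste(lines, collapse = "\n")
}

# SELECT returning (iid, observed) rows violating one quantification constraint
qc_violation_select <- function(con, ontorel) {
  subj <- ontorel$relations[[con$subject_relation]]
  rel <- ontorel$relations[[con$relation]]
  conds <- character(0)
  if (con$min > 0L) conds <- c(conds, sprintf("count(r.%s) < %d", dquote(con$group_attr), con$min))
  if (is.finite(con$max)) conds <- c(conds, sprintf("count(r.%s) > %d", dquote(con$group_attr), con$max))
  sprintf(paste0(
    "SELECT c.%s AS iid, count(r.%s) AS observed\n",
    "FROM %s c LEFT JOIN %s r ON r.%s = c.%s\n",
    "GROUP BY c.%s\n",
    "HAVING %s"),
    dquote(subj$primary_key), dquote(con$group_attr),
    dquote(subj$name), dquote(rel$name), dquote(con$group_attr), dquote(subj$primary_key),
    dquote(subj$primary_key),
    paste(conds, collapse = " OR "))
}

# SELECT returning iids violating one membership (union/intersection) constraint
mc_violation_select <- function(con, ontorel) {
  tgt <- ontorel$relations[[con$target]]
  ops <- lapply(con$operands, function(o) ontorel$relations[[o]])
  exists_in <- function(r, ref) {
    sprintf("EXISTS (SELECT 1 FROM %s o WHERE o.%s = %s)",
            dquote(r$name), dquote(r$primary_key), ref)
  }
  tref <- sprintf("t.%s", dquote(tgt$primary_key))
  in_ops <- vapply(ops, exists_in, character(1), ref = tref)
  if (con$kind == "union") {
    # target must equal the union of the operands
    miss_target <- sprintf(
      "SELECT t.%s AS iid, 0 AS observed FROM %s t WHERE NOT (%s)",
      dquote(tgt$primary_key), dquote(tgt$name), paste(in_ops, collapse = " OR "))
  } else {
    miss_target <- sprintf(
      "SELECT t.%s AS iid, 0 AS observed FROM %s t WHERE NOT (%s)",
      dquote(tgt$primary_key), dquote(tgt$name), paste(in_ops, collapse = " AND "))
  }
  extra <- vapply(ops, function(r) {
    pref <- sprintf("t.%s", dquote(r$primary_key))
    in_others <- vapply(ops, exists_in, character(1), ref = pref)
    in_target <- exists_in(tgt, pref)
    if (con$kind == "union") {
      sprintf("SELECT t.%s AS iid, 0 AS observed FROM %s t WHERE NOT %s",
              dquote(r$primary_key), dquote(r$name), in_target)
    } else {
      sprintf("SELECT t.%s AS iid, 0 AS observed FROM %s t WHERE (%s) AND NOT %s",
              dquote(r$primary_key), dquote(r$name),
              paste(in_others, collapse = " AND "), in_target)
    }
  }, character(1))
  paste(c(miss_target, extra), collapse = "\nUNION\n")
}

emit_functions <- function(ontorel, dialect) {
  cfg <- ontorel$rdb_config
  lines <- c(sprintf("-- Constraint verification routines for schema %s", cfg$schema_name))
  if (dialect$name == "postgresql") {
    lines <- c(lines, sprintf("SET search_path = %s;", dquote(cfg$schema_name)))
  }
  all_cons <- c(
    lapply(ontorel$qconstraints, function(con)
      list(name = con$name, sql = qc_violation_select(con, ontorel),
           min = con$min, max = con$max)),
    lapply(ontorel$mconstraints, function(con)
      list(name = con$name, sql = mc_violation_select(con, ontorel),
           min = NA, max = NA))
  )
  for (con in all_cons) {
    if (dialect$check_mode == "function") {
      lines <- c(lines, sprintf(
        "CREATE FUNCTION %s() RETURNS TABLE (iid %s, observed bigint) AS $$\n%s\n$$ LANGUAGE sql STABLE;",
        dquote(con$name), dquote(IID_DOMAIN), con$sql))
    } else {
      lines <- c(lines, sprintf("CREATE VIEW %s AS\n%s;", dquote(con$name), con$sql))
    }
  }
  # aggregate verification report over every constraint
  bounds_literal <- function(v) {
    if (is.na(v) || is.infinite(v)) "NULL" else format(as.integer(v))
  }
  if (length(all_cons)) {
    parts <- vapply(all_cons, function(con) {
      if (dialect$check_mode == "function") {
        sprintf("SELECT %s AS constraint_name, f.iid, f.observed, %s::bigint AS min_required, %s::bigint AS max_allowed FROM %s() f",
                squote(con$name), bounds_literal(con$min), bounds_literal(con$max),
                dquote(con$name))
      } else {
        sprintf("SELECT %s AS constraint_name, f.iid, f.observed, %s AS min_required, %s AS max_allowed FROM %s f",
                squote(con$name), bounds_literal(con$min), bounds_literal(con$max),
                dquote(con$name))
      }
    }, character(1))
    union_sql <- paste(parts, collapse = "\nUNION ALL\n")
  } else {
    union_sql <- paste("SELECT NULL AS constraint_name, NULL AS iid,",
                       "NULL AS observed, NULL AS min_required, NULL AS max_allowed",
                       "WHERE 1 = 0")
  }
  if (dialect$check_mode == "function") {
    lines <- c(lines, sprintf(
      "CREATE FUNCTION %s() RETURNS TABLE (constraint_name text, iid %s, observed bigint, min_required bigint, max_allowed bigint) AS $$\n%s\n$$ LANGUAGE sql STABLE;",
      dquote("verification_report"), dquote(IID_DOMAIN), union_sql))
  } else {
    lines <- c(lines, sprintf("CREATE VIEW %s AS\n%s;",
                              dquote("verification_report"), union_sql))
  }
  paste(lines, collapse = "\n")
}

emit_comments <- function(ontorel, dialect) {
  cfg <- ontorel$rdb_config
  lines <- c(sprintf("-- Construct documentation for schema %s", cfg$schema_name))
  if (dialect$supports_comments) {
    lines <- c(lines, sprintf("SET search_path = %s;", dquote(cfg$schema_name)))
    for (cm in ontorel$comments) {
      rel <- ontorel$relations[[cm$relation]]
      lines <- c(lines, sprintf("COMMENT ON TABLE %s IS %s;",
                                dquote(rel$name), squote(cm$text)))
    }
  } else {
    lines <- c(lines,
               "CREATE TABLE \"ontorel_comments\" (\n  \"construct\" TEXT NOT NULL,\n  \"comment\" TEXT NOT NULL,\n  PRIMARY KEY (\"construct\")\n);")
    for (cm in ontorel$comments) {
      rel <- ontorel$relations[[cm$relation]]
      lines <- c(lines, sprintf("INSERT INTO \"ontorel_comments\" VALUES (%s, %s);",
                                squote(rel$name), squote(cm$text)))
    }
  }
  paste(lines, collapse = "\n")
}

emit_views <- function(ontorel, dialect, lang) {
  cfg <- ontorel$rdb_config
  onto <- ontorel$onto
  lang_config <- ontology_config(language_priority = lang)
  lines <- c(sprintf("-- %s label views for schema %s", lang, cfg$schema_name))
  if (dialect$name == "postgresql") {
    lines <- c(lines, sprintf("SET search_path = %s;", dquote(cfg$schema_name)))
  }
  taken <- character(0)
  label_of <- function(iri) resolve_label(onto, iri, lang_config)
  for (id in names(ontorel$relations)) {
    rel <- ontorel$relations[[id]]
    vbase <- if (rel$id == "Thing") "Thing" else switch(rel$kind,
      class = label_of(rel$origin),
      object_property = label_of(rel$origin),
      rel$name)
    vname <- sanitize_identifier(paste0("v_", lang, "_", vbase), cfg, taken)
    taken <- c(taken, vname)
    cols <- vapply(rel$attributes, function(a) {
      alias <- if (!is.null(a$origin_iri)) {
        lbl <- gsub("[^A-Za-z0-9]+", "_", label_of(a$origin_iri))
        if (a$role == "iid") paste0(lbl, "_iid") else lbl
      } else a$name
      sprintf("%s AS %s", dquote(a$name), dquote(alias))
    }, character(1))
    lines <- c(lines, sprintf("CREATE VIEW %s AS SELECT %s FROM %s;",
                              dquote(vname), paste(cols, collapse = ", "),
                              dquote(rel$name)))
  }
  paste(lines, collapse = "\n")
}

emit_inserts <- function(ontorel, dialect, order) {
  lines <- c("-- Individual tuples")
  if (dialect$name == "postgresql") {
    lines <- c(lines, sprintf("SET search_path = %s;", dquote(ontorel$rdb_config$schema_name)))
  }
  by_rel <- split(ontorel$inserts,
                  vapply(ontorel$inserts, function(x) x$relation, character(1)))
  for (id in order) {
    for (ins in by_rel[[id]] %||% list()) {
      rel <- ontorel$relations[[id]]
      lines <- c(lines, sprintf("INSERT INTO %s (%s) VALUES (%s);",
                                dquote(rel$name), dquote(ins$attr), squote(ins$iid)))
    }
  }
  paste(lines, collapse = "\n")
}

#' Emit the executable DDL script set
#'
#' Produces the ordered script set: domains, tables (dependency order), keys,
#' constraint verification routines, comments and one label view script per
#' configured language; identical input yields byte-identical scripts.
#'
#' @param ontorel An assembled `ontorel`.
#' @param cfg Optional [rdb_config()] override (defaults to the one stored at
#'   assembly time).
#' @return A `ddl_script_set`: named ordered list of script texts.
#' @export
emit_ddl <- function(ontorel, cfg = NULL) {
  if (!is.null(cfg)) ontorel$rdb_config <- cfg
  cfg <- ontorel$rdb_config
  dialect <- get_dialect(cfg)
  order <- topo_order(ontorel)
  scripts <- list()
  scripts[["domains"]] <- emit_domains(ontorel, dialect)
  scripts[["tables"]] <- emit_tables(ontorel, dialect, order)
  scripts[["keys"]] <- emit_keys(ontorel, dialect)
  scripts[["functions"]] <- emit_functions(ontorel, dialect)
  scripts[["comments"]] <- emit_comments(ontorel, dialect)
  for (lang in cfg$view_languages) {
    scripts[[paste0("views_", lang)]] <- emit_views(ontorel, dialect, lang)
  }
  if (length(ontorel$inserts)) {
    scripts[["inserts"]] <- emit_inserts(ontorel, dialect, order)
  }
  structure(list(scripts = scripts, schema = cfg$schema_name,
                 dialect = dialect$name),
            class = "ddl_script_set")
}

#' Emit the standalone verification-suite script
#'
#' The aggregate routine invoking every per-constraint verification function
#' (or view) and returning one row per violation: constraint name, violating
#' iid, observed count and the bounds.
#'
#' @param ontorel An assembled `ontorel`.
#' @return Length-1 character (SQL script).
#' @export
emit_verification_suite <- function(ontorel) {
  emit_functions(ontorel, get_dialect(ontorel$rdb_config))
}

#' @export
print.ddl_script_set <- function(x, ...) {
  cat(sprintf("DDL script set for schema '%s' (%s dialect): %s\n",
              x$schema, x$dialect, paste(names(x$scripts), collapse = ", ")))
  invisible(x)
}

#' Write a DDL script set to files
#'
#' Files are named `<schema>_<script>.sql` in the output directory.
#'
#' @param scripts A `ddl_script_set`.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_ddl <- function(scripts, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(scripts$scripts)) {
    p <- file.path(out_dir, sprintf("%s_%s.sql", scripts$schema, nm))
    writeLines(scripts$scripts[[nm]], p, useBytes = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Execute a DDL script set on a live database connection
#'
#' Splits each script into statements and executes them in order on a DBI
#' connection. Intended for the sqlite dialect (whose scripts contain no
#' nested statement separators); enable `PRAGMA foreign_keys = ON` on the
#' connection to enforce the referential keys.
#'
#' @param scripts A `ddl_script_set`.
#' @param con A `DBI` connection.
#' @return Number of statements executed, invisibly.
#' @export
execute_ddl <- function(scripts, con) {
  if (!requireNamespace("DBI", quietly = TRUE)) {
    orf_input_error("execute_ddl() requires the DBI package")
  }
  n <- 0L
  for (sql in scripts$scripts) {
    stmts <- strsplit(paste(sql, collapse = "\n"), ";[ \t]*(\n|$)")[[1]]
    for (s in stmts) {
      s <- gsub("(^|\n)--[^\n]*", "", s)
      if (grepl("[^[:space:]]", s)) {
        DBI::dbExecute(con, s)
        n <- n + 1L
      }
    }
  }
  invisible(n)
}
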