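# Shared test helpers: tiny ontology builders and a functional-syntax writer
# into temp files.

EX_NS <- "http://example.org/onto#"
ex <- function(x) paste0(EX_NS, x)

write_ofn <- function(lines) {
  f <- tempfile(fileext = ".ofn")
  writeLines(c("Prefix(ex:=<http://example.org/onto#>)",
               "Ontology(<http://example.org/onto>", lines, ")"), f)
  f
}

# parse + reduce + assemble in one go
convert_file <- function(path, config = ontology_config(), cfg = rdb_config()) {
  onto <- parse_ontology(path, config)
  red <- reduce_ontology(onto)
  assemble(red$ontology, red$constraints, config, cfg)
}

# structural comparison of two normalized ontologies, ignoring the warning log
expect_same_onto <- function(a, b) {
  a$warnings <- NULL
  b$warnings <- NULL
  expect_identical(a, b)
}

# fresh in-memory SQLite with foreign keys enforced
sqlite_con <- function() {
  con <- DBI::dbConnect(RSQLite::SQLite())
  DBI::dbExecute(con, "PRAGMA foreign_keys = ON")
  con
}

relation_names <- function(ontorel) {
  unname(vapply(ontorel$relations, function(r) r$name, character(1)))
}
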