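# End-to-end pipeline: parse -> reduce -> convert -> catalog -> codegen,
# with a machine-readable run report and all-or-nothing output writing.

#' Run the full ontology-to-relational pipeline
#'
#' Executes the five stages on one ontology document and writes the DDL
#' script set, the mapping catalog, the reduced-ontology dump and the run
#' report into `out_dir`. On any fatal error the partial outputs written by
#' this run are removed before the condition propagates. Outputs carry no
#' timestamps, so identical inputs reproduce byte-identical artifacts; the
#' report is the only file with volatile fields (elapsed time).
#'
#' @param input Path to the ontology document (RDF/XML or functional syntax).
#' @param out_dir Output directory, created if needed.
#' @param config An [ontology_config()].
#' @param cfg An [rdb_config()].
#' @param quiet Suppress progress messages.
#' @return A `run_report` object, invisibly.
#' @export
run_pipeline <- function(input, out_dir, config = ontology_config(),
                         cfg = rdb_config(), quiet = FALSE) {
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  ok <- FALSE
  on.exit({
    if (!ok) unlink(written)
  }, add = TRUE)

  say("analyzing %s", input)
  onto <- parse_ontology(input, config)
  say("reducing %d axioms", length(onto$axioms))
  red <- reduce_ontology(onto)
  say("converting to the relational model")
  ontorel <- assemble(red$ontology, red$constraints, config, cfg)
  say("building the mapping catalog")
  catalog <- build_catalog(ontorel)
  say("generating SQL (%s dialect)", cfg$dialect)
  ddl <- emit_ddl(ontorel)

  written <- write_ddl(ddl, out_dir)
  cat_path <- file.path(out_dir, sprintf("%s_ontorelcat.json", cfg$schema_name))
  write_catalog(catalog, cat_path)
  written <- c(written, cat_path)
  dump_path <- file.path(out_dir, sprintf("%s_reduced.ofn", cfg$schema_name))
  write_functional(red$ontology, dump_path)
  written <- c(written, dump_path)

  # a construct warned at parse time may be re-warned by the reducer; the
  # report lists each problem exactly once
  warnings_df <- ontorel$warnings
  warnings_df <- warnings_df[!duplicated(paste(warnings_df$code, warnings_df$subject)), ,
                             drop = FALSE]
  rownames(warnings_df) <- NULL
  counts <- ontorel_counts(ontorel)
  counts$classes <- length(red$ontology$classes)
  counts$generated_classes <- length(red$ontology$generated)
  counts$object_properties <- length(red$ontology$object_properties)
  counts$axioms <- length(red$ontology$axioms)
  report <- structure(list(counts = counts,
                           warnings = warnings_df,
                           outputs = written,
                           elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
                      class = "run_report")
  report_path <- file.path(out_dir, sprintf("%s_report.json", cfg$schema_name))
  jsonlite::write_json(list(counts = counts,
                            warnings = warnings_df,
                            outputs = basename(written),
                            elapsed_seconds = report$elapsed),
                       report_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  report$outputs <- c(written, report_path)
  ok <- TRUE
  say("done: %d relations, %d referential keys, %d warnings",
      counts$relations, counts$referential_keys, nrow(warnings_df))
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report\n")
  cat(sprintf("  relations: %d  referential keys: %d  domains: %d\n",
              x$counts$relations, x$counts$referential_keys, x$counts$domains))
  cat(sprintf("  quantification constraints: %d  membership constraints: %d  comments: %d\n",
              x$counts$quantification_constraints, x$counts$membership_constraints,
              x$counts$comments))
  cat(sprintf("  warnings: %d  outputs: %d files  elapsed: %.2fs\n",
              nrow(x$warnings), length(x$outputs), x$elapsed))
  if (nrow(x$warnings)) {
    for (i in seq_len(min(nrow(x$warnings), 10L))) {
      cat(sprintf("  [%s] %s\n", x$warnings$code[i], x$warnings$message[i]))
    }
    if (nrow(x$warnings) > 10L) cat(sprintf("  ... and %d more\n", nrow(x$warnings) - 10L))
  }
  invisible(x)
}
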