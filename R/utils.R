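# Internal utilities: condition classes, IRI helpers, deterministic hashing.

# Well-known vocabulary IRIs used throughout the converter.
RDFS_LABEL   <- "http://www.w3.org/2000/01/rdf-schema#label"
RDFS_COMMENT <- "http://www.w3.org/2000/01/rdf-schema#comment"
IAO_DEFINITION <- "http://purl.obolibrary.org/obo/IAO_0000115"
SKOS_DEFINITION <- "http://www.w3.org/2004/02/skos/core#definition"
OWL_THING <- "http://www.w3.org/2002/07/owl#Thing"
XSD_NS <- "http://www.w3.org/2001/XMLSchema#"
# Annotation property under which the reducer stores the canonical expression
# text of a generated class, so the mapping catalog can expose it.
ORF_CANONICAL <- "urn:x-ontorel:canonical-form"

DEFINITION_PROPS <- c(IAO_DEFINITION, SKOS_DEFINITION, RDFS_COMMENT)

orf_abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "orf_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

orf_input_error <- function(msg, ...) orf_abort(msg, "orf_input_error", ...)
orf_syntax_error <- function(msg, ...) orf_abort(msg, "orf_syntax_error", ...)
orf_config_error <- function(msg, ...) orf_abort(msg, "orf_config_error", ...)
orf_consistency_error <- function(msg, ...) orf_abort(msg, "orf_consistency_error", ...)
orf_cycle_error <- function(msg, ...) orf_abort(msg, "orf_cycle_error", ...)
orf_type_error <- function(msg, ...) orf_abort(msg, "orf_type_error", ...)
orf_notfound_error <- function(msg, ...) orf_abort(msg, "orf_notfound_error", ...)

#' Local name of an IRI
#'
#' The fragment after `#`, or the last path segment when no fragment exists.
#'
#' @param iri Character vector of absolute IRIs.
#' @return Character vector of local names.
#' @keywords internal
iri_local_name <- function(iri) {
  vapply(iri, function(x) {
    if (grepl("#", x, fixed = TRUE)) {
      sub(".*#", "", x)
    } else {
      sub(".*[/:]", "", x)
    }
  }, character(1), USE.NAMES = FALSE)
}

# Prefix-qualified (short) form of a full IRI given a prefix map
# (named character vector prefix -> namespace). Falls back to the full IRI
# in angle brackets when no prefix matches. Longest namespace wins.
iri_short <- function(iri, prefixes) {
  vapply(iri, function(x) {
    if (length(prefixes)) {
      hits <- vapply(prefixes, function(ns) startsWith(x, ns), logical(1))
      if (any(hits)) {
        cands <- prefixes[hits]
        ns <- cands[which.max(nchar(cands))]
        return(paste0(names(ns), ":", substring(x, nchar(ns) + 1L)))
      }
    }
    paste0("<", x, ">")
  }, character(1), USE.NAMES = FALSE)
}

# Expand a prefixed name ("ex:A") against a prefix map; full IRIs (with or
# without angle brackets) pass through.
iri_expand <- function(qname, prefixes) {
  vapply(qname, function(x) {
    if (startsWith(x, "<") && endsWith(x, ">")) return(substr(x, 2L, nchar(x) - 1L))
    if (grepl("^[A-Za-z][A-Za-z0-9_.-]*:", x) && !grepl("^[a-z]+://", x)) {
      pfx <- sub(":.*$", "", x)
      rest <- sub("^[^:]*:", "", x)
      if (!pfx %in% names(prefixes)) {
        orf_config_error(sprintf("unknown prefix '%s' in '%s'", pfx, x))
      }
      return(paste0(prefixes[[pfx]], rest))
    }
    x
  }, character(1), USE.NAMES = FALSE)
}

# Deterministic 32-bit FNV-1a style hash, platform independent (arithmetic is
# done in doubles below 2^53, reduced mod 2^32 at each step).
orf_hash32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

# xor for doubles holding 32-bit unsigned values (split into 16-bit halves so
# base bitwXor on integers is exact)
bitwXor_dbl <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  as.double(hi) * 65536 + as.double(lo)
}

# Short base-36 digest (6 chars) used for identifier truncation suffixes.
orf_hash6 <- function(x) {
  h <- orf_hash32(x)
  digits <- c(0:9, letters)
  out <- character(6)
  for (i in 1:6) {
    out[i] <- digits[(h %% 36) + 1]
    h <- h %/% 36
  }
  paste(out, collapse = "")
}

# Deterministic pseudo-GUID (UUID v4 layout) derived from a seed string.
# Used for individual iid generation so repeated runs are reproducible.
orf_guid <- function(x) {
  hex <- "0123456789abcdef"
  chars <- character(32)
  h <- orf_hash32(x)
  for (i in 1:32) {
    if (i %% 8 == 1) h <- orf_hash32(paste0(x, "#", i, "#", h))
    chars[i] <- substr(hex, (h %% 16) + 1, (h %% 16) + 1)
    h <- h %/% 16
  }
  sprintf("%s-%s-4%s-a%s-%s",
          paste(chars[1:8], collapse = ""), paste(chars[9:12], collapse = ""),
          paste(chars[13:15], collapse = ""), paste(chars[16:18], collapse = ""),
          paste(chars[19:30], collapse = ""))
}

# Stable stringification of a quantifier interval, UNBOUNDED max printed "*".
qt_text <- function(qt) {
  mx <- if (is.finite(qt$max)) format(qt$max) else "*"
  sprintf("[%d..%s]", qt$min, mx)
}
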