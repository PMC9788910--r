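# Class-expression AST: identifiers, binary union / intersection, and
# quantified property restrictions. This is the abstract grammar the axiom
# reducer operates on; leaves are always named-class identifiers.

#' Quantifier interval
#'
#' A quantifier bounds how many range individuals a subject may be linked to
#' through a property. `max = Inf` encodes the unbounded upper limit.
#'
#' @param min Non-negative integer lower bound.
#' @param max Non-negative integer upper bound, or `Inf` for unbounded.
#' @return An object of class `orf_qt`.
#' @examples
#' qt(1)        # at least one
#' qt(0, 3)     # at most three
#' qt(2, 2)     # exactly two
#' @export
qt <- function(min = 0L, max = Inf) {
  min <- as.integer(min)
  if (is.na(min) || min < 0L) orf_type_error("quantifier min must be a non-negative integer")
  if (!is.infinite(max)) {
    max <- as.integer(max)
    if (is.na(max) || max < 0L) orf_type_error("quantifier max must be a non-negative integer or Inf")
    if (min > max) orf_type_error(sprintf("quantifier min (%d) exceeds max (%d)", min, max))
    max <- as.double(max)
  }
  structure(list(min = min, max = max), class = "orf_qt")
}

#' @export
print.orf_qt <- function(x, ...) {
  cat(qt_text(x), "\n")
  invisible(x)
}

#' Class-expression constructors
#'
#' Build expression trees over named classes: `ex_class()` wraps a class IRI,
#' `ex_union()` / `ex_intersection()` combine sub-expressions (n-ary calls are
#' right-folded into binary nodes), and `ex_restriction()` builds a quantified
#' property restriction over an operand expression.
#'
#' @param iri Absolute class IRI.
#' @return An object of class `orf_expr`.
#' @examples
#' a <- ex_class("http://example.org/onto#A")
#' b <- ex_class("http://example.org/onto#B")
#' ex_union(a, b)
#' ex_restriction("http://example.org/onto#p", qt(1), ex_intersection(a, b))
#' @export
ex_class <- function(iri) {
  stopifnot(is.character(iri), length(iri) == 1L, nzchar(iri))
  structure(list(node = "class", iri = iri), class = "orf_expr")
}

fold_nary <- function(node, args) {
  stopifnot(length(args) >= 2L)
  out <- args[[length(args)]]
  for (i in rev(seq_len(length(args) - 1L))) {
    out <- structure(list(node = node, left = args[[i]], right = out),
                     class = "orf_expr")
  }
  out
}

#' @rdname ex_class
#' @param ... Two or more `orf_expr` operands.
#' @export
ex_union <- function(...) fold_nary("union", list(...))

#' @rdname ex_class
#' @export
ex_intersection <- function(...) fold_nary("intersection", list(...))

#' @rdname ex_class
#' @param property Object-property IRI.
#' @param quantifier An [qt()] interval.
#' @param operand Filler expression.
#' @export
ex_restriction <- function(property, quantifier, operand) {
  stopifnot(is.character(property), length(property) == 1L,
            inherits(quantifier, "orf_qt"), inherits(operand, "orf_expr"))
  structure(list(node = "restriction", property = property,
                 qt = quantifier, operand = operand), class = "orf_expr")
}

is_class_expr <- function(x) inherits(x, "orf_expr") && x$node == "class"

#' Canonical serialization of a class expression
#'
#' Produces a deterministic text form used to key generated classes: the
#' operands of the commutative operators are serialized in lexicographic
#' order, so `A OR B` and `B OR A` yield the same canonical text.
#'
#' @param expr An `orf_expr`.
#' @param shorten Function mapping a full IRI to the name used in the output
#'   (identity by default; pass an IRI-shortener for display forms).
#' @return Length-1 character.
#' @examples
#' a <- ex_class("http://x.org/A"); b <- ex_class("http://x.org/B")
#' canonical_form(ex_union(b, a)) == canonical_form(ex_union(a, b))
#' @export
canonical_form <- function(expr, shorten = identity) {
  stopifnot(inherits(expr, "orf_expr"))
  switch(expr$node,
    class = shorten(expr$iri),
    union = ,
    intersection = {
      op <- if (expr$node == "union") " ⊔ " else " ⊓ "
      parts <- sort(enc2utf8(c(canonical_form(expr$left, shorten),
                               canonical_form(expr$right, shorten))),
                    method = "radix")
      enc2utf8(paste0("(", parts[1], op, parts[2], ")"))
    },
    restriction = paste0("(", shorten(expr$property), " ", qt_text(expr$qt),
                         " ", canonical_form(expr$operand, shorten), ")"),
    orf_type_error(sprintf("unknown expression node '%s'", expr$node))
  )
}

#' @export
print.orf_expr <- function(x, ...) {
  cat(canonical_form(x), "\n")
  invisible(x)
}

# All named class IRIs occurring in an expression.
expr_class_iris <- function(expr) {
  switch(expr$node,
    class = expr$iri,
    union = ,
    intersection = c(expr_class_iris(expr$left), expr_class_iris(expr$right)),
    restriction = expr_class_iris(expr$operand)
  )
}

# All object-property IRIs occurring in an expression.
expr_property_iris <- function(expr) {
  switch(expr$node,
    class = character(0),
    union = ,
    intersection = c(expr_property_iris(expr$left), expr_property_iris(expr$right)),
    restriction = c(expr$property, expr_property_iris(expr$operand))
  )
}

expr_depth <- function(expr) {
  switch(expr$node,
    class = 1L,
    union = ,
    intersection = 1L + max(expr_depth(expr$left), expr_depth(expr$right)),
    restriction = 1L + expr_depth(expr$operand)
  )
}
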