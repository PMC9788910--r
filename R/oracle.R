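# Brute-force small-model oracle: enumerate every interpretation of the named
# classes and object properties over a tiny individual domain and check that
# an interpretation satisfies the original (complex) axioms exactly when it
# satisfies the reduced simple axioms plus the membership constraints.
#
# The evaluator works directly on expression trees and never calls the
# reducer, so it is an independent check of the reduction rules, usable only
# at very small scale (the interpretation count is
# 2^(#classes * n) * 2^(#properties * n^2)).

# extension of an expression under an interpretation
# ext: named list class IRI -> logical vector length n
# rels: named list property IRI -> n x n logical matrix
eval_expr_ext <- function(expr, ext, rels, n) {
  switch(expr$node,
    class = ext[[expr$iri]] %||% rep(FALSE, n),
    union = eval_expr_ext(expr$left, ext, rels, n) | eval_expr_ext(expr$right, ext, rels, n),
    intersection = eval_expr_ext(expr$left, ext, rels, n) & eval_expr_ext(expr$right, ext, rels, n),
    restriction = {
      filler <- eval_expr_ext(expr$operand, ext, rels, n)
      rel <- rels[[expr$property]]
      counts <- as.vector(rel %*% as.numeric(filler))
      counts >= expr$qt$min & counts <= expr$qt$max
    }
  )
}

axiom_satisfied <- function(ax, ext, rels, n) {
  switch(ax$kind,
    class_inheritance = {
      d <- eval_expr_ext(ax$domain, ext, rels, n)
      r <- eval_expr_ext(ax$range, ext, rels, n)
      all(!d | r)
    },
    class_association = {
      d <- eval_expr_ext(ax$domain, ext, rels, n)
      r <- eval_expr_ext(ax$range, ext, rels, n)
      rel <- rels[[ax$property]]
      counts <- as.vector(rel %*% as.numeric(r))
      all(!d | (counts >= ax$qt$min & counts <= ax$qt$max))
    },
    TRUE
  )
}

# extensions of generated classes pinned down by the membership constraints;
# resolved iteratively because a constraint's operands may themselves be
# generated classes
resolve_generated <- function(constraints, ext, n) {
  pending <- constraints
  guard <- 0L
  while (length(pending)) {
    guard <- guard + 1L
    if (guard > length(constraints) + 2L) {
      orf_consistency_error("membership constraints do not form a resolvable hierarchy")
    }
    still <- list()
    for (con in pending) {
      ops <- lapply(con$operands, function(o) ext[[o]])
      if (any(vapply(ops, is.null, logical(1)))) {
        still[[length(still) + 1L]] <- con
        next
      }
      ext[[con$target]] <- if (con$kind == "union") {
        Reduce(`|`, ops)
      } else {
        Reduce(`&`, ops)
      }
    }
    pending <- still
  }
  ext
}

#' Check semantics preservation of the reduction by exhaustive enumeration
#'
#' Enumerates every interpretation of the ontology's named classes and object
#' properties over a domain of `n_individuals`, and verifies that the original
#' axiom set and the reduced axiom set (with generated-class extensions pinned
#' down by the membership constraints) are satisfied by exactly the same
#' interpretations. Only usable on tiny ontologies; the number of
#' interpretations grows as `2^(c*n + p*n^2)`.
#'
#' @param onto A pre-reduction `muonto` whose axioms are class inheritance /
#'   class association axioms (no data axioms).
#' @param n_individuals Domain size (keep at 2-5).
#' @param max_interpretations Safety cap; exceeding it raises an error rather
#'   than running forever.
#' @return A list with `equivalent` (logical), `n_interpretations`,
#'   `n_satisfying` and `n_disagreements`.
#' @export
check_reduction_semantics <- function(onto, n_individuals = 3L,
                                      max_interpretations = 2e5) {
  n <- as.integer(n_individuals)
  classes <- setdiff(onto$classes, unlist(onto$generated, use.names = FALSE))
  props <- unique(unlist(lapply(onto$axioms, function(ax) {
    c(switch(ax$kind,
             class_association = ax$property,
             character(0)),
      switch(ax$kind,
             class_inheritance = c(expr_property_iris(ax$domain), expr_property_iris(ax$range)),
             class_association = c(expr_property_iris(ax$domain), expr_property_iris(ax$range)),
             character(0)))
  })))
  original <- Filter(function(ax) ax$kind %in% c("class_inheritance", "class_association"),
                     onto$axioms)
  red <- reduce_ontology(onto)
  reduced <- Filter(function(ax) ax$kind %in% c("class_inheritance", "class_association"),
                    red$ontology$axioms)
  constraints <- red$constraints

  nc <- length(classes)
  np <- length(props)
  n_class_bits <- nc * n
  n_prop_bits <- np * n * n
  total <- 2^(n_class_bits + n_prop_bits)
  if (total > max_interpretations) {
    orf_input_error(sprintf(
      "interpretation space too large (%g > %g); use fewer classes/properties/individuals",
      total, max_interpretations))
  }

  n_sat <- 0L
  n_disagree <- 0L
  n_total <- 0L
  class_space <- 2^n_class_bits
  prop_space <- 2^n_prop_bits
  bit <- function(code, k) (code %/% 2^k) %% 2 == 1

  for (ci in seq_len(class_space) - 1) {
    ext <- list()
    for (j in seq_len(nc)) {
      ext[[classes[j]]] <- vapply(seq_len(n) - 1L,
                                  function(b) bit(ci, (j - 1L) * n + b), logical(1))
    }
    for (pi in seq_len(max(prop_space, 1)) - 1) {
      rels <- list()
      for (j in seq_len(np)) {
        bits <- vapply(seq_len(n * n) - 1L,
                       function(b) bit(pi, (j - 1L) * n * n + b), logical(1))
        rels[[props[j]]] <- matrix(bits, nrow = n, ncol = n)
      }
      n_total <- n_total + 1L
      sat_orig <- all(vapply(original, axiom_satisfied, logical(1),
                             ext = ext, rels = rels, n = n))
      ext2 <- resolve_generated(constraints, ext, n)
      sat_red <- all(vapply(reduced, axiom_satisfied, logical(1),
                            ext = ext2, rels = rels, n = n))
      if (sat_orig) n_sat <- n_sat + 1L
      if (sat_orig != sat_red) n_disagree <- n_disagree + 1L
    }
  }
  list(equivalent = n_disagree == 0L,
       n_interpretations = n_total,
       n_satisfying = n_sat,
       n_disagreements = n_disagree)
}
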