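---
title: "Compiling OWL ontologies into normalized relational schemas"
author: "ontorelforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compiling OWL ontologies into normalized relational schemas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontorelforge)
```

## The problem and the approach

Biomedical data are commonly described by OWL ontologies (classes,
object and data properties, axioms, datatypes, annotations) while the data
themselves live in relational databases. `ontorelforge` compiles an ontology
into a highly normalized relational schema that keeps the ontological
semantics attached to the storage structures: every relational construct is
derived from exactly one ontological construct by a uniform rule, and a
mapping catalog records the correspondence in both directions, so any table,
key or constraint can be traced back to the class, property or axiom it
implements.

The conversion rules are, per construct:

* **Class** `C` → relation with a single individual-identifier attribute
  `<shortIri>_iid : iid_type`, which is the primary key. The universal class
  is materialized as the root relation `Thing` holding every identifier, so
  an independent artificial key indexes all individuals.
* **Object property** `p` → relation `(subject_iid, object_iid)` with the
  pair as primary key.
* **Inheritance axiom** `C0 ⊑ C1` (or `p0 ⊑ p1`) → an *isa* referential key
  from the sub-construct relation's primary key to the super-construct
  relation's primary key. Classes without a named superclass key into
  `Thing`.
* **Class association axiom** `C0 p[qt] C1` → an association relation
  carrying both class identifiers (composite primary key) plus three
  referential keys: to the domain-class relation, to the range-class
  relation, and — as an attribute-pair key — to the property relation, so
  every association tuple must also appear in the property relation.
* **Data association axiom** `C0 dp[qt] D` → a data relation (class
  identifier + typed value attribute, composite primary key) with one key
  back to the class relation. One relation per data property: no nullable
  wide tables, hence no missing-information or redundancy anomalies.
* **Datatype** `D` → an SQL domain (user-defined type), e.g.
  `CREATE DOMAIN "xsd:String" AS TEXT`, reused uniformly by every value
  attribute of that datatype.
* **Quantifier** `[min..max]` → when `min > 0` or `max` is finite, a named
  verification routine returning the violating subject identifiers with
  their observed link counts.
* **Annotation** → an SQL comment on the generated construct (definition
  text in the configured language, with the source IRI appended) and, per
  requested language, a view layer renaming relations and attributes to
  their labels in that language.
* **Individual** → optionally, tuples carrying one reproducible GUID through
  all the class relations of its (transitive) memberships and `Thing`.

## Axiom complexity reduction

Real biomedical axioms are rarely simple. Before conversion, every axiom is
rewritten into the canonical form *identifier – operator – identifier* by a
recursive reduction over the expression grammar (identifiers, binary union
`⊔`, binary intersection `⊓`, quantified property restrictions; n-ary
operators are right-folded into binary nodes). The reduction returns three
things per expression: a *representative* named class, a set of *membership
constraints*, and a set of replacement *simple axioms*:

1. a named class represents itself;
2. a union `β ⊔ γ` is replaced by a fresh class `Z` with simple axioms
   `rep(β) ⊑ Z` and `rep(γ) ⊑ Z` and the constraint
   `ext(Z) = ext(rep(β)) ∪ ext(rep(γ))`;
3. an intersection `β ⊓ γ` is replaced by a fresh `Z` with `Z ⊑ rep(β)`,
   `Z ⊑ rep(γ)` and `ext(Z) = ext(rep(β)) ∩ ext(rep(γ))`;
4. a restriction at the top of an axiom's right-hand side is peeled off: its
   property and quantifier become the axiom operator and the filler is
   reduced recursively.

The subclass axioms emitted by cases 2 and 3 become ordinary foreign keys
and enforce the subset directions incrementally; the set-equality
constraints are generated as verification routines evaluated on demand
(deferred checking), because a minimum-cardinality or coverage condition
cannot hold row-by-row during incremental loading.

Two design points deserve emphasis:

* **These decompositions are verified, not assumed.** The test suite
  contains a brute-force small-model oracle that enumerates *every*
  interpretation of the named classes and properties over a tiny individual
  domain and checks that an interpretation satisfies the original complex
  axioms exactly when it satisfies the reduced axioms plus the membership
  constraints (with generated-class extensions pinned down by those
  constraints). The oracle evaluates expression trees directly and never
  calls the reducer. Fixture sizes are kept at ≤ 4 classes with 3–5
  individuals (no property) or ≤ 3 classes, 1 property and 2 individuals,
  i.e. about 1 000–33 000 interpretations per fixture — small enough to be
  exhaustive, large enough to kill wrong decompositions.
* **Nested restrictions are materialized one-directionally.** A restriction
  strictly inside a union or intersection is replaced by a fresh class `Z`
  with the simple association axiom `Z p[qt] rep(β)`. This asserts that
  every member of `Z` satisfies the restriction, but not the converse (the
  membership-constraint vocabulary covers union and intersection only).
  Totality and idempotence still hold for arbitrary nesting; exact semantic
  equivalence is claimed — and tested — for restrictions in operator
  position, the didactic case. Unions additionally assert coverage only
  (`Z ⊆ A ∪ B` and `A, B ⊆ Z`), not disjointness.

Generated classes are named `GEN_<zero-padded counter>` in first-encounter
order of canonical expression serializations (commutative operands are
serialized in lexicographic order, so `A ⊔ B` and `B ⊔ A` share one class),
carry a label `<prefix>_GEN_<counter>` and an annotation holding their
canonical form, which the catalog exposes. Identical sub-expressions across
axioms therefore deduplicate to a single class, and reduction is idempotent
and byte-stable across runs.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `schema_name` | `ontorel` | target SQL schema |
| `max_identifier_length` | 63 | PostgreSQL's limit; longer names are truncated with a deterministic 6-character base-36 hash suffix, collisions included |
| `iid_base_type` | `uuid` (PostgreSQL), `TEXT` (SQLite) | identifiers are 128-bit GUIDs so loading never needs a central counter |
| `type_map` | XSD → SQL table | `xsd:string → TEXT`, `xsd:integer → INTEGER`, …; unmapped datatypes fall back to `TEXT` with a warning. Domain names capitalize the local name (`"xsd:String"`) |
| `language_priority` | `en` | label/definition selection; falls back to untagged labels, then IRI local names |
| `view_languages` | `en` | one label-view layer per language |
| `reuse_thing` | `TRUE` | materialize the universal root relation |
| `include_individuals` | `FALSE` | the individual rule is implemented but off by default; most production loads come from ETL, not from asserted individuals |
| `dialect` | `postgresql` | `sqlite` is also shipped: it inlines base types and foreign keys (SQLite has neither `CREATE DOMAIN` nor `ALTER TABLE … ADD CONSTRAINT`), renders verification routines as views and comments as a metadata table |

Ontology ingestion reads RDF/XML and OWL functional-style syntax, loading
`owl:imports` transitively when the imported document sits next to the input
file (anything else is warned). Turtle input is rejected with a clear error:
no RDF parsing library for R is available in this package's dependency
footprint, and hand-rolling a Turtle reader was judged out of proportion to
its value here. OWL restrictions map onto integer quantifier intervals:
`someValuesFrom → [1..*]`, `min n → [n..*]`, `max n → [0..n]`,
`exactly n → [n..n]`, `allValuesFrom → [0..*]` (the range typing is carried
by the association's referential key to the range class). Bare property
domain/range declarations are translated into `[0..*]` associations bounded
by `Thing` when both ends are named, and warned otherwise. Constructs
outside this grammar — equivalence, disjointness, property characteristics —
are retained as "other" axioms and surfaced exactly once in the warning
report, never silently dropped.

## What the synthetic generator emulates

`gen_fixture()` builds ontologies with exactly realized construct counts:
`c` classes, `p` object properties, `s` subclass axioms (always pointing
from a higher-indexed class to a lower-indexed one, so the taxonomy is
acyclic by construction), sub-property axioms, class associations with
quantifiers drawn from `{[0..*], [1..*], [1..1], [0..3]}`, data associations
over string/integer/dateTime datatypes, and complex axioms as random
expression trees up to a requested depth. The domain class of a complex
axiom always sits strictly above every class in its expression, the same
orientation as the taxonomy; this guarantees that the isa edges introduced
by the reduction can never close a referential cycle, so every generated
fixture converts to an executable schema. A companion arithmetic oracle
predicts the relational construct counts (`1 + c + p + a + d` relations;
`s` isa keys + one per root class into `Thing` + one per sub-property axiom
+ `3a + d`) for fixtures without complex axioms — with complex axioms the
expected counts would depend on canonical-form deduplication, which would
make the "oracle" a reimplementation of the reduction rather than an
independent check.

What passing these tests does *not* show about real data: fixtures contain
no equivalence axioms, no property characteristics, no punning, no
annotation-heavy OBO metadata beyond labels and definitions, and their
taxonomies are shallow random DAGs rather than the deep, multiply-inheriting
hierarchies of real OBO ontologies. The converter processes such ontologies
(unsupported constructs become warnings), but the count laws and semantics
checks quantify behaviour only over the supported grammar.

Problem sizes used by the shipped checks: 200 randomized ontologies at
expression depth ≤ 6 for reduction totality; 12 fixture families for
idempotence; five exhaustively enumerated oracle fixtures (≈ 43 000
interpretations in total); 50 random parameter sets for the counting laws;
six schemas executed end-to-end against SQLite with engine-catalog
verification. These sizes were chosen so the whole suite exercises every
rule combination while completing in well under a minute.

## Numerical and structural choices

* **Determinism everywhere.** Relations are emitted in declaration order,
  generated names in first-encounter order, canonical forms sort operands
  byte-wise (`enc2utf8` + radix ordering, independent of locale collation),
  and no artifact contains a timestamp; two runs on the same input are
  byte-identical, which the tests assert file-by-file.
* **Identifier collisions.** Truncation appends a hash of the *raw* name, so
  two distinct long labels truncating identically stay distinct, and
  re-running cannot flip names.
* **Table creation order** is a Kahn topological sort over the referential
  dependency graph with declaration-order tie-breaking. Cyclic subclass
  axioms are rejected up front with a diagnostic naming the cycle; note that
  a self-referential intersection axiom (`C ⊑ C ⊓ B`) reduces to an isa
  cycle and is likewise rejected — rewriting such axioms (here, to `C ⊑ B`)
  is axiom *redundancy* reduction, which is out of scope.
* **Degenerate inputs.** An empty ontology yields just the `Thing` relation;
  `[0..*]` quantifiers produce no constraint; a union with two identical
  operands degenerates gracefully (one isa axiom, a tautological
  constraint); individuals without asserted classes land in `Thing` only.

## Known limitations

Beyond the nested-restriction directionality discussed above: no reasoning
or consistency checking of the ontology itself; no SWRL, property chains or
punning; no axiom-redundancy elimination; no secondary keys, no
functional/transitive property constraints, no data-modification procedures;
no tuple-level reversibility (exporting stored rows as ontology assertions);
comments rely on the target engine supporting `COMMENT ON`. The PostgreSQL
scripts target version 9.6 and later; within the package's tests they are
checked textually while the SQLite dialect is executed against a live
engine.
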