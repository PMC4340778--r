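---
title: "An extended EAV storage model for hierarchical clinical documents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An extended EAV storage model for hierarchical clinical documents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eavrecord)
```

## Why an EAV store

A digital patient care record has to absorb reports from many senders —
hospitals, physicians, nursing services — each using its own standard,
template or template version. Two properties make a conventional wide
schema a poor fit. First, *heterogeneity*: every new template would require
a schema migration. Second, *sparsity*: for any one patient, almost all
fields any template could carry are absent, so wide rows would be mostly
NULL. The entity-attribute-value model inverts the layout: the structure of
the information is stored as data, one row per fact that is actually
present. New document shapes need no schema change, and storage grows with
the number of present facts, never with the number of possible fields.

The price is paid at query time — structure has to be recomposed — which is
acceptable here because a care record holds the documents of one patient
(or a small set), keeping result sets small.

## The schema, and the choices inside it

`eav_open()` creates the relations:

* `entity(entity_id, name, parent_id, sibling_pos)`
* `attribute(attribute_id, name UNIQUE)`
* `string_value`, `integer_value`, `real_value`, `boolean_value`,
  `date_value`, `timestamp_value` — each
  `(value_id, entity_id, attribute_id, source_doc_id, lexical, typed,
  metadata, version, current)`
* `source_doc(source_doc_id, author, doc_type, template, received_at,
  digest, version, root_entity_id, raw)`
* `entity_path(entity_id, source_doc_id, path)` — a materialized path cache
* `view_spec` / `grant_tbl` — access control

Several design points deserve their rationale:

**Entities are per-occurrence, attributes are a dictionary.** `parent_id`
and `sibling_pos` are properties of one element *instance*, so entity rows
cannot be shared. Attribute names, by contrast, recur massively across CDA
documents (`code`, `codeSystem`, `root`, `extension`, ...); a shared
dictionary avoids storing the same name again per entity. There is no
direct entity–attribute relation: which attributes an entity has is
derivable from the value rows, and a direct link would only duplicate that
information.

**`sibling_pos` counts all sibling nodes** — elements and text
pseudo-nodes alike — 1-based in document order. Counting only same-named
siblings was the alternative; counting all nodes was chosen because it
makes `(parent_id, sibling_pos)` a total order on children, so the stored
rows alone reproduce mixed content (`<a>t1<b/>t2</a>`) exactly.
Same-named indexing, when a consumer needs it, is derivable downstream.

**Text nodes become `#text` pseudo-entities** with one fact under the
reserved attribute `#text`. The uniform rule (element → entity, any value →
fact) keeps narrative blocks with mixed content lossless without a special
case for "element text".

**Both the lexical and the typed value are stored.** Type inference maps
`"042"` to integer 42; emitting `42` on reconstruction would silently
change the document. Reconstruction therefore always emits the verbatim
lexical; the typed column exists for typed comparisons and range queries.

**Datatype registry.** The six built-in tags are a representative subset of
the primitive healthcare datatypes (character strings, integers, reals,
booleans, dates, timestamps); `register_datatype()` adds a tag and its
value table at run time. Full coverage of composite healthcare datatypes
(intervals, coded values with qualifiers) is out of scope.

**Entities without facts** (e.g. `<section/>` wrappers) are recorded by
their entity row alone. Their document membership follows the root chain:
each document's root entity id is stored in `source_doc`, and the path
cache carries the document id for every entity.

**Duplicate documents** are detected by an MD5 digest of the raw text;
the default policy rejects re-import, `on_duplicate = "version"` stores
the document again with an incremented version (minimal versioning
support; fact-level updates likewise version rather than overwrite).

## Import

`import_document()` runs extract–transform–load in one transaction:
parsing (xml2), a single-pass shred, and a batched load; a failure at any
point leaves the store untouched.

Rules applied during shredding:

* whitespace-only text nodes are dropped — pretty-printing must not create
  facts. Comments and processing instructions are dropped too; both rules
  are mirrored by the canonical-equality notion below, which is exactly why
  round-trip equality can be stated at all.
* namespace declarations are stored as ordinary attribute facts
  (`xmlns`, `xmlns:p`); element and attribute names keep their prefixed
  qualified form. The XML library synthesizes `d1:`-style prefixes for
  default namespaces; these are stripped back using the `xmlns`
  declarations so stored names match the source. (A source that declares a
  *real* prefix matching `d<digits>` for a URI that is also
  default-declared would be mis-stripped — accepted as pathological.)
* datatype inference is per value with fixed precedence
  boolean → integer → real → date → timestamp → string (empty string →
  string). No schema or XSD is consulted: the engine must accept documents
  whose schema it has never seen, and the precedence makes inference a
  total, deterministic function. Integer lexicals longer than 15 digits
  fall through to string rather than lose precision.
* header/body classification: a fact is *body* iff its entity lies strictly
  below the body root, the first element reached through the configured
  `component/structuredBody` chain. Everything else — including a document
  with no body root at all, and the body-root element's own attributes —
  is header metadata. The strict-descendant reading is a contract choice;
  in practice the body root carries no attributes in this dialect.

## Queries

The entity path is composed by a recursive common table expression
following `parent_id` to the root, concatenating `name[sibling_pos]`
segments. Paths are materialized into `entity_path` once per import (and
recomputed on demand for facts loaded through the low-level API), mirroring
a materialized-view strategy without depending on any vendor feature.

Two evaluation queries are provided: `all_tuples()` (every
`{entity path, attribute, value}` tuple, in stable document/path/attribute
order — the ordering is a choice, none is prescribed) and the
attribute-centric pair `find_documents()` + `tuples_for_documents()`
(all tuples of the documents containing a search term). Term matching is
case-insensitive substring over stored lexical values; matching over raw
document bytes was rejected because it would also hit element and
attribute *names*, which are structure, not content.

`timed_query()`/`bench_query()` split response time into the three phases
relevant for an embedded store: acquiring the connection, executing the
SQL and fetching, and traversing rows into result tuples — reported as
first run next to the run average, since later runs benefit from caching.
For an in-memory store the connection cannot be re-acquired, so the first
phase only validates the handle.

## Export

`reconstruct_document()` rebuilds a document purely from the EAV rows.
Equality with the input is checked in **canonical form**: attribute order,
the XML declaration, whitespace-only text, comments and processing
instructions are ignored; text is compared decoded; namespace declarations
and qualified names are kept. This is precisely the information the
importer preserves, making "lossless" a testable statement rather than a
claim.

Generating *new* standardized reports runs the five-step loop: preselect →
(manual) select → transform by rules → completeness check → generate,
repeated until nothing required is missing. Decisions made where the
design was open:

* **Rule language.** A rule maps a fact pattern to a target slot. Patterns
  use `*` for a name segment and `[*]` for any position, with `/@name` for
  an attribute (text content is the reserved `#text`). The target path is
  a template: wildcards are instantiated from the source match in order.
  Value transforms are named total functions from a registry (`identity`,
  `uppercase`, `date_de`, code-table lookups via `make_code_lookup()`).
  Two rules writing different values to one slot raise an error naming
  both rules; equal writes are idempotent.
* **The manual selection step is an injected callback**,
  `selector(selection, missing)`, clamped to the preselection. That makes
  the loop testable without a UI: a scripted selector that repairs one
  missing fact per pass converges in exactly `missing + 1` iterations, and
  a selector that never repairs hits the configurable iteration bound with
  an error listing what is still missing.
* **Completeness** is a list of required target-slot patterns plus a root
  name check; the check returns exactly the unmet patterns, so the loop's
  progress is observable and monotone when the selector only adds facts.

## Access control

Views are horizontal fragments (predicates on receipt time, document type,
header/body flag) intersected with vertical fragments (path patterns,
attribute names); grants attach per-role subsets of
read/add/delete/update to a view. Enforcement happens in the engine's
query layer — the role's readable set is the union of its granted
fragments, intersected with any query result — rather than in DBMS view
objects, so the contract is backend-independent and works at the
granularity of a single fact: one value can be hidden while its siblings
show. Write rights are checked against the same fragment predicates;
updates version rather than overwrite, deletes retire the row.

## The synthetic corpus generator

No real document corpus can be shipped, so `generate_corpus()` produces
CDA-like nursing transition reports: a header with document, patient and
author metadata; a body of five main sections (nursing process, social
information, home care status, legal references, medical information) with
subsections nested to `max_depth` (default 4); per section a configurable
number of optional fields, each present with probability `fill_rate` and
cycling through the six datatypes; optionally, search terms planted into
an exact number of documents. Word pools are filtered so no other lexical
contains a planted term, keeping planted counts exact. Everything is a
deterministic function of the seed, and a manifest records every fact
(path, attribute, lexical, header/body flag, section) as ground truth,
built during construction and therefore independent of the import
machinery it is used to check.

Default study conditions: five sections, depth 4, sparse optional fields,
and corpus scales of 10/20/100/129 documents with 9- and 30-document term
plantings for the query checks; the compactness check uses 50 documents
with 40 possible fields per section at 5% fill. These sizes are the
package's test conditions, chosen to match the document scales the engine
is designed around.

What the generator does **not** emulate — and hence what passing tests do
not show: schema-valid CDA (no schema validation is performed anywhere),
real clinical narrative, terminology codings (ICNP, NANDA-I), multi-level
namespace usage beyond a default namespace on the root, and documents
large enough to stress query performance. The engine handles arbitrary
well-formed XML; the tests exercise the dialect described above plus
hand-written micro-documents for mixed content, namespaces and escaping.

## Numerical and degenerate-input choices

* Dates/timestamps are validated strictly (a `2013-13-40` is a string);
  timestamps accept `T` or space separators, optional seconds, fractions
  and zone designators.
* `fill_rate` is in (0, 1]; a corpus of zero documents is legal and empty.
* An empty store yields empty tuple sets; empty preselection criteria mean
  "everything"; an empty completeness spec accepts any well-formed tree.
* Sibling collisions and dangling parents are rejected at insert;
  referential integrity of facts is enforced by foreign keys.
* The iteration bound of the export loop defaults to 20 passes.

## Known limitations

* Attribute *order* within an element is not part of canonical equality
  (XML defines it as insignificant); reconstruction emits attributes in
  original document order anyway.
* CDATA sections are preserved as their text content, not as CDATA.
* Only primitive datatypes ship; composite healthcare types are an
  extension point.
* Fragments are evaluated in R over the fact frame; for the intended
  per-patient data volumes this is well below query cost, but it is not a
  push-down into SQL.
* Authentication, encryption and audit logging are out of scope: the
  access layer models authorization structure only.
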