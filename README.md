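# eavrecord

An entity-attribute-value (EAV) storage engine for integrating
heterogeneous, hierarchical healthcare documents into a single digital
patient care record.

## The problem

Home-healthcare information arrives as standardized XML reports
(HL7-CDA-style documents such as the German ePflegebericht nursing
transition report): a *header* with metadata about the document, the
patient and the authors, and a *body* whose clinical content is organized
into nested sections. Different senders use different standards, templates
and template versions, and per-patient data is highly sparse — a wide fixed
relational schema would be mostly empty and would break with every new
template. The classic answer is the EAV model: store the *structure* of the
information as data, one row per present fact, so that new document shapes
need no schema change and sparse data stays compact.

`eavrecord` implements an extended EAV schema for exactly this setting and
everything around it: lossless import, structure-aware queries, exact
reconstruction, rule-based export into new target formats, and view-based
access control — plus a seeded generator for synthetic CDA-like corpora to
test against.

## The model

Three core relations, extended for hierarchical documents:

- **entity** — one row per XML element *occurrence* (or text pseudo-node
  `#text`), with `parent_id` and `sibling_pos` columns. `sibling_pos` is the
  1-based position among **all** siblings in document order, so the stored
  rows fully determine the tree, and the path of an entity is recovered by
  recursively composing `name[sibling_pos]` segments up the parent chain
  (a recursive common table expression):
  `/ClinicalDocument[1]/recordTarget[8]/patientRole[1]/...`
- **attribute** — a deduplicated dictionary of attribute names. There is
  deliberately *no* entity↔attribute link: the pairing exists only in the
  value rows.
- **`<tag>_value`** — one table per registered datatype (`string`,
  `integer`, `real`, `boolean`, `date`, `timestamp`; extensible). Each row
  ties an entity, an attribute and a source document, stores the **verbatim
  lexical form** next to the parsed typed value, and carries a boolean
  `metadata` flag: header fact or body fact.
- **source_doc** — provenance per imported document (author, type,
  template, receipt time, digest) plus the raw text, so every document is
  restorable byte-for-byte.

Import shreds a document in one pass (element → entity row, XML attribute →
value fact, non-whitespace text node → `#text` pseudo-entity + fact);
reconstruction inverts it, and canonical XML equality (attribute-order- and
insignificant-whitespace-insensitive) of input and reconstruction is the
operational meaning of "no data is lost".

## Worked example

```r
library(eavrecord)

params <- gen_params(seed = 42, n_docs = 10, planted_terms = c(hemoglobin = 3))
corpus <- generate_corpus(params)

store <- eav_open(":memory:")
for (doc in corpus$docs) print(import_document(store, doc, author = "Nurse A"))
#> <import> doc 1: 99 entities, 46 values (21 header / 25 body), 7 new attributes
#> <import> doc 2: 108 entities, 51 values (21 header / 30 body), 0 new attributes
#> ...
```

Ten documents of the same template contribute attribute rows only once
(7 distinct names in the whole corpus); entity rows are per-occurrence:

```r
store
#> <eav_store> (in-memory)
#>   documents: 10  entities: 1047  datatypes: boolean, date, integer, real, string, timestamp

tuples <- all_tuples(store)           # {entity path, attribute, value} per fact
head(tuples[tuples$source_doc_id == 1, ], 3)
#>                                     entity_path attribute          value ...
#> 1                          /ClinicalDocument[1]     xmlns urn:hl7-org:v3
#> 2 /ClinicalDocument[1]/author[9]/.../family[2]/#text[1]  #text     Meyer
#> 3 /ClinicalDocument[1]/author[9]/.../given[1]/#text[1]   #text      Karl
```

The attribute-centric query finds exactly the three documents the term was
planted into, and reconstruction is canonically exact:

```r
find_documents(store, "hemoglobin")
#> [1]  5  7 10

identical(canonical_xml(reconstruct_document(store, 1)),
          canonical_xml(corpus$docs[[1]]))
#> [1] TRUE
```

The benchmark harness reports the three response-time phases (connecting,
executing, traversing the result set), first run next to the 10-run
average:

```r
bench_query(store, query_spec("term", "hemoglobin"), repeats = 10)
#> query: term (term: "hemoglobin")  rows: 146  runs: 10
#>            phase first_run_ms avg_ms min_ms max_ms
#>  before_querying            0    0.0      0      0
#>         querying            5    5.0      4      7
#>   after_querying            1    0.2      0      1
```

Exporting into a new target format applies declarative transformation
rules and loops selection → transform → completeness check until the
required content is present (see `?export_document` and the vignette).

A thin CLI wraps the same functions
(`inst/cli/eavrecord gen|import|query|bench|restore|export`).

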