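# Import pipeline: parsing, shredding rules, header/body classification,
# atomic loading, conservation against the walk oracle.

test_that("parsing keeps element order, attributes and mixed content", {
  t1 <- parse_document("<a x=\"1\"/>")
  b1 <- shred_document(t1)
  expect_identical(nrow(b1$entities), 1L)
  expect_identical(b1$facts$attribute, "x")

  b2 <- shred_document(parse_document("<a>t1<b/>t2</a>"))
  expect_identical(b2$entities$name, c("a", "#text", "b", "#text"))
  expect_identical(b2$entities$sibling_pos, c(1L, 1L, 2L, 3L))
  expect_identical(b2$facts$lexical, c("t1", "t2"))

  # whitespace-only text nodes are dropped; comments and PIs carry no facts
  b3 <- shred_document(parse_document("<a>\n  <b/>\n  <!-- note --><?pi x?>\n</a>"))
  expect_identical(b3$entities$name, c("a", "b"))
  expect_identical(nrow(b3$facts), 0L)

  expect_error(parse_document("<a><b></a>"), class = "eav_parse_error")
})

test_that("shredding counts match hand-derived parse events", {
  b <- shred_document(parse_document("<a x=\"1\"><b/></a>"))
  expect_identical(nrow(b$entities), 2L)
  expect_identical(b$attribute_names, "x")
  expect_identical(nrow(b$facts), 1L)

  b <- shred_document(parse_document("<a>hi</a>"))
  expect_identical(nrow(b$entities), 2L)
  expect_identical(b$facts$attribute, "#text")
  expect_identical(b$facts$lexical, "hi")

  b <- shred_document(parse_document("<a/>"))
  expect_identical(nrow(b$entities), 1L)
  expect_identical(nrow(b$facts), 0L)
})

test_that("namespace declarations become facts and prefixed names survive", {
  xml <- "<doc xmlns=\"urn:hl7-org:v3\" xmlns:x=\"urn:x\"><x:b x:y=\"2\" z=\"3\"/></doc>"
  b <- shred_document(parse_document(xml))
  expect_identical(b$entities$name, c("doc", "x:b"))
  expect_setequal(b$facts$attribute, c("xmlns", "xmlns:x", "x:y", "z"))
  store <- eav_open(":memory:")
  on.exit(eav_close(store))
  rep <- import_document(store, xml)
  expect_identical(canonical_xml(reconstruct_document(store, rep$source_doc_id)),
                   canonical_xml(xml))
})

test_that("facts are classified header or body relative to the body root", {
  cfg <- eav_import_config()
  expect_true(classify_header_body("/ClinicalDocument[1]/recordTarget[9]/id[1]", cfg))
  expect_false(classify_header_body(
    "/ClinicalDocument[1]/component[12]/structuredBody[1]/component[2]/section[1]", cfg))
  # a document with no body root is all header
  expect_true(classify_header_body("/note[1]/content[2]", cfg))
  xml <- "<r><component><structuredBody><s v=\"1\"/></structuredBody></component><t v=\"2\"/></r>"
  store <- eav_open(":memory:")
  on.exit(eav_close(store))
  rep <- import_document(store, xml)
  expect_identical(rep$n_body_values, 1L)
  expect_identical(rep$n_header_values, 1L)
  expect_identical(rep$n_values, rep$n_header_values + rep$n_body_values)
})

test_that("a failed import leaves no partial state", {
  store <- eav_open(":memory:")
  on.exit(eav_close(store))
  import_document(store, "<a x=\"1\"/>")
  before <- store_counts(store)
  expect_error(import_document(store, "<a><unclosed></a>"), class = "eav_parse_error")
  expect_error(import_document(store, "<a x=\"1\"/>"), "duplicate")
  expect_identical(store_counts(store), before)
})

test_that("conservation holds against the walk oracle on a generated corpus", {
  p <- gen_params(seed = 101, n_docs = 8, fill_rate = 0.6)
  corp <- generate_corpus(p)
  store <- import_corpus(corp)
  on.exit(eav_close(store))
  o <- lapply(corp$docs, oracle_walk)
  expect_identical(store_counts(store)[["entities"]],
                   sum(vapply(o, function(x) x$n_elements + x$n_texts, 1)))
  expect_identical(store_counts(store)[["values"]],
                   sum(vapply(o, function(x) x$n_attrs + x$n_texts, 1)))
  # reading children back by sibling_pos reproduces document order
  tu <- all_tuples(store)
  first_doc <- tu[tu$source_doc_id == 1L, ]
  expect_identical(tuple_keys(first_doc),
                   tuple_keys(NULL, 1L, o[[1L]]$facts$path,
                              o[[1L]]$facts$attribute, o[[1L]]$facts$lexical))
})

test_that("re-importing the same bytes in versioning mode gives an isomorphic tree", {
  xml <- generate_corpus(gen_params(seed = 5, n_docs = 1))$docs[[1L]]
  store <- eav_open(":memory:")
  on.exit(eav_close(store))
  r1 <- import_document(store, xml)
  r2 <- import_document(store, xml, on_duplicate = "version")
  expect_identical(r1$n_entities, r2$n_entities)
  expect_identical(r1$n_values, r2$n_values)
  t1 <- tuples_for_documents(store, r1$source_doc_id)
  t2 <- tuples_for_documents(store, r2$source_doc_id)
  expect_identical(t1[c("entity_path", "attribute", "value")],
                   t2[c("entity_path", "attribute", "value")])
})
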