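# Core schema contracts: idempotent open, attribute dedup, hierarchy
# invariants, value routing, raw-document identity and duplicate policy.

test_that("opening a store creates the schema and re-opening sees prior data", {
  path <- file.path(tempdir(), "store-reopen.sqlite")
  on.exit(unlink(path))
  s1 <- eav_open(path)
  tabs <- DBI::dbListTables(s1$con)
  expect_true(all(c("entity", "attribute", "source_doc",
                    paste0(registered_datatypes(s1), "_value")) %in% tabs))
  expect_length(grep("_value$", tabs), 6L)  # one value table per default tag
  import_document(s1, "<a x=\"1\"/>")
  eav_close(s1)
  s2 <- eav_open(path)
  expect_identical(nrow(all_tuples(s2)), 1L)
  eav_close(s2)
  expect_error(eav_open("/nonexistent-dir-zz/x.sqlite"), "not writable")
})

test_that("an in-memory store starts empty", {
  store <- eav_open(":memory:")
  on.exit(eav_close(store))
  expect_identical(nrow(all_tuples(store)), 0L)
  expect_identical(unname(store_counts(store)[c("entities", "values")]), c(0, 0))
})

test_that("attribute names are deduplicated", {
  store <- eav_open(":memory:")
  on.exit(eav_close(store))
  id1 <- upsert_attribute(store, "code")
  id2 <- upsert_attribute(store, "code")
  id3 <- upsert_attribute(store, "codeSystem")
  expect_identical(id1, id2)
  expect_false(id1 == id3)
  expect_identical(store_counts(store)[["attributes"]], 2)
  expect_error(upsert_attribute(store, ""), "nonempty")
})

test_that("entity hierarchy invariants are enforced at insert", {
  store <- eav_open(":memory:")
  on.exit(eav_close(store))
  root <- insert_entity(store, "ClinicalDocument", NULL, 1L)
  expect_identical(ancestor_path(store, root), "/ClinicalDocument[1]")
  c1 <- insert_entity(store, "section", root, 1L)
  c2 <- insert_entity(store, "section", root, 2L)
  expect_identical(ancestor_path(store, c2), "/ClinicalDocument[1]/section[2]")
  expect_error(insert_entity(store, "late", root, 1L), "already taken")
  expect_error(insert_entity(store, "orphan", 9999L, 1L), "does not exist")
  expect_error(insert_entity(store, "bad", root, 0L), ">= 1")
})

test_that("facts route to the value table of their datatype", {
  store <- eav_open(":memory:")
  on.exit(eav_close(store))
  doc <- register_source_doc(store, "<a/>")
  e <- insert_entity(store, "a", NULL, 1L)
  a <- upsert_attribute(store, "flag")
  insert_value(store, value_fact(e, a, doc, "true", is_metadata = TRUE))
  expect_identical(
    DBI::dbGetQuery(store$con, "SELECT COUNT(*) AS n FROM boolean_value")$n, 1L)
  # header-only filter sees it
  tu <- all_tuples(store)
  expect_true(tu$is_metadata[tu$attribute == "flag"])
  expect_error(
    insert_value(store, structure(list(entity_id = e, attribute_id = a,
                                source_doc_id = doc, lexical = "x",
                                datatype = "nosuch", typed_value = "x",
                                is_metadata = FALSE), class = "value_fact")),
    "not registered")
})

test_that("raw documents are stored byte-identically with a duplicate policy", {
  store <- eav_open(":memory:")
  on.exit(eav_close(store))
  raw <- "<a>\n  <b code=\"äö\"/>\n</a>"
  id <- register_source_doc(store, raw, author = "Nurse A")
  expect_identical(get_raw(store, id), raw)
  expect_identical(source_docs(store, id)$author, "Nurse A")
  expect_error(register_source_doc(store, raw), "duplicate")
  id2 <- register_source_doc(store, raw, on_duplicate = "version")
  expect_identical(source_docs(store, id2)$version, 2L)
  expect_error(get_raw(store, 999L), "unknown")
})
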