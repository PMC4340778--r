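# Query engine: path composition, the two evaluation queries, timing harness.

test_that("ancestor paths compose name and sibling position up to the root", {
  store <- eav_open(":memory:")
  on.exit(eav_close(store))
  import_document(store, "<a><b/><b><c x=\"1\"/></b></a>")
  paths <- DBI::dbGetQuery(store$con, "SELECT entity_id, path FROM entity_path")
  # recursive composition agrees with the per-import materialized cache
  for (i in seq_len(nrow(paths))) {
    expect_identical(ancestor_path(store, paths$entity_id[[i]]), paths$path[[i]])
  }
  expect_setequal(paths$path, c("/a[1]", "/a[1]/b[1]", "/a[1]/b[2]", "/a[1]/b[2]/c[1]"))
  expect_error(ancestor_path(store, 12345L), "unknown entity")
})

test_that("all_tuples enumerates one tuple per fact in stable order", {
  store <- eav_open(":memory:")
  on.exit(eav_close(store))
  expect_identical(nrow(all_tuples(store)), 0L)
  import_document(store, "<a x=\"1\"/>")
  tu <- all_tuples(store)
  expect_identical(tu$entity_path, "/a[1]")
  expect_identical(tu$attribute, "x")
  expect_identical(tu$value, "1")
  import_document(store, "<z b=\"2\" a=\"3\"/>")
  tu <- all_tuples(store)
  expect_identical(tu$attribute, c("x", "a", "b"))  # doc, then path, then attribute
})

test_that("term search returns exactly the documents holding the term", {
  p <- gen_params(seed = 77, n_docs = 12, planted_terms = c(insulin = 4))
  corp <- generate_corpus(p)
  store <- import_corpus(corp)
  on.exit(eav_close(store))
  expect_identical(find_documents(store, "insulin"), corp$manifest$terms$insulin)
  expect_identical(find_documents(store, "INSULIN"), corp$manifest$terms$insulin)
  expect_identical(find_documents(store, "zz-not-there"), integer(0))
  expect_error(find_documents(store, ""), "nonempty")
  # a term planted in the header is still found (search spans header and body)
  ph <- gen_params(seed = 78, n_docs = 6, planted_terms = c(dyspnoe = 2),
                   plant_in_header = TRUE)
  ch <- generate_corpus(ph)
  sh <- import_corpus(ch)
  on.exit(eav_close(sh), add = TRUE)
  expect_identical(find_documents(sh, "dyspnoe"), ch$manifest$terms$dyspnoe)
  hit <- tuples_for_documents(sh, find_documents(sh, "dyspnoe"))
  expect_true(all(hit$is_metadata[grepl("dyspnoe", hit$value)]))
})

test_that("tuples_for_documents equals the doc-membership filter of all_tuples", {
  p <- gen_params(seed = 31, n_docs = 6)
  corp <- generate_corpus(p)
  store <- import_corpus(corp)
  on.exit(eav_close(store))
  tu <- all_tuples(store)
  sub <- tuples_for_documents(store, c(2L, 5L))
  expect_identical(tuple_keys(sub),
                   tuple_keys(tu[tu$source_doc_id %in% c(2L, 5L), ]))
  # disjoint doc sets give disjoint, additive tuple sets
  s1 <- tuples_for_documents(store, c(1L, 3L))
  s2 <- tuples_for_documents(store, c(4L, 6L))
  expect_identical(nrow(s1) + nrow(s2), nrow(tuples_for_documents(store, c(1L, 3L, 4L, 6L))))
  expect_length(intersect(tuple_keys(s1), tuple_keys(s2)), 0L)
  expect_error(tuples_for_documents(store, 99L), "unknown source document")
})

test_that("timed queries return the untimed result with three phase timings", {
  path <- file.path(tempdir(), "timing.sqlite")
  on.exit(unlink(path))
  store <- eav_open(path)
  corp <- generate_corpus(gen_params(seed = 9, n_docs = 4, planted_terms = c(demenz = 2)))
  for (d in corp$docs) import_document(store, d)
  for (spec in list(query_spec("all"), query_spec("term", "demenz"))) {
    timed <- timed_query(store, spec)
    plain <- if (spec$type == "all") all_tuples(store) else
      tuples_for_documents(store, find_documents(store, spec$term))
    expect_identical(timed$result, plain)
    expect_identical(timed$timings$n_rows, nrow(plain))
    expect_true(all(unlist(timed$timings[c("before_ms", "query_ms", "after_ms")]) >= 0))
  }
  eav_close(store)
})
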