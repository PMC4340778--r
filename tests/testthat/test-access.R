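# View-based access fragments and per-role rights.

make_access_fixture <- function() {
  p <- gen_params(seed = 55, n_docs = 5)
  corp <- generate_corpus(p)
  store <- eav_open(":memory:")
  # spread receipt times over consecutive days so horizontal windows bite
  for (i in seq_along(corp$docs)) {
    import_document(store, corp$docs[[i]],
                    received_at = sprintf("2013-02-%02d 09:00:00", i))
  }
  list(store = store, corp = corp)
}

test_that("views evaluate to exactly their fragment", {
  fx <- make_access_fixture()
  store <- fx$store
  on.exit(eav_close(store))
  tu <- all_tuples(store)

  define_view(store, view_spec("previous-day",
                               received_from = "2013-02-02 00:00:00",
                               received_to = "2013-02-02 23:59:59"))
  frag <- view_fragment(store, "previous-day")
  expect_identical(sort(unique(frag$source_doc_id)), 2L)

  define_view(store, view_spec("medication-section", path_patterns =
    "/ClinicalDocument[1]/component[*]/structuredBody[1]/component[5]"))
  frag2 <- view_fragment(store, "medication-section")
  mf <- manifest_facts(fx$corp$manifest)
  oracle <- mf[!is.na(mf$section) & mf$section == "Medical Information", ]
  expect_identical(nrow(frag2), nrow(oracle))

  define_view(store, view_spec("everything"))
  expect_identical(nrow(view_fragment(store, "everything")), nrow(tu))

  expect_error(define_view(store, view_spec("everything")), "already defined")
})

test_that("read grants union their fragments and missing grants deny", {
  fx <- make_access_fixture()
  store <- fx$store
  on.exit(eav_close(store))
  define_view(store, view_spec("header-only", metadata = TRUE))
  define_view(store, view_spec("doc-1", received_to = "2013-02-01 23:59:59"))
  define_view(store, view_spec("everything"))

  g1 <- grant_view(store, "nurse", "header-only", "read")
  g2 <- grant_view(store, "nurse", "doc-1", "read")
  vis <- query_as(store, "nurse")
  tu <- all_tuples(store)
  oracle <- tu[tu$is_metadata | tu$source_doc_id == 1L, ]
  expect_identical(tuple_keys(vis), tuple_keys(oracle))

  expect_error(query_as(store, "stranger"), class = "eav_auth_error")
  expect_error(grant_view(store, "x", "header-only", character(0)), "nonempty")
  expect_error(grant_view(store, "x", "no-such-view", "read"), "unknown view")

  # revoking the sole remaining grant leaves the role with nothing readable
  revoke_grant(store, g2)
  expect_true(all(query_as(store, "nurse")$is_metadata))
  revoke_grant(store, g1)
  expect_error(query_as(store, "nurse"), class = "eav_auth_error")
})

test_that("rights are enforced per operation at fact granularity", {
  fx <- make_access_fixture()
  store <- fx$store
  on.exit(eav_close(store))
  define_view(store, view_spec("header-only", metadata = TRUE))
  define_view(store, view_spec("everything"))
  grant_view(store, "reader", "header-only", "read")
  grant_view(store, "editor", "everything", c("read", "update", "delete"))

  some_fact <- DBI::dbGetQuery(store$con,
    "SELECT value_id FROM string_value WHERE metadata = 0 LIMIT 1")$value_id
  # read-only role may not delete, and may not touch body facts at all
  expect_error(delete_value_as(store, "reader", "string", some_fact),
               class = "eav_auth_error")

  n_before <- nrow(all_tuples(store))
  delete_value_as(store, "editor", "string", some_fact)
  expect_identical(nrow(all_tuples(store)), n_before - 1L)

  # update creates a new version; the original row survives non-current
  target <- DBI::dbGetQuery(store$con,
    "SELECT value_id, lexical FROM string_value WHERE current = 1 LIMIT 1")
  new_id <- update_value_as(store, "editor", "string", target$value_id, "revised")
  row <- DBI::dbGetQuery(store$con,
    "SELECT lexical, version, current FROM string_value WHERE value_id = ?",
    params = list(new_id))
  expect_identical(row$lexical, "revised")
  expect_identical(row$version, 2L)
  old <- DBI::dbGetQuery(store$con,
    "SELECT current, lexical FROM string_value WHERE value_id = ?",
    params = list(target$value_id))
  expect_identical(old$current, 0L)
  expect_identical(old$lexical, target$lexical)
})

test_that("query_as is contained in the unrestricted result and grants are monotone", {
  fx <- make_access_fixture()
  store <- fx$store
  on.exit(eav_close(store))
  tu <- all_tuples(store)
  views <- c("v-header", "v-body", "v-sec5", "v-early", "v-all")
  define_view(store, view_spec("v-header", metadata = TRUE))
  define_view(store, view_spec("v-body", metadata = FALSE))
  define_view(store, view_spec("v-sec5", path_patterns =
    "/ClinicalDocument[1]/component[*]/structuredBody[1]/component[5]"))
  define_view(store, view_spec("v-early", received_to = "2013-02-03 23:59:59"))
  define_view(store, view_spec("v-all"))

  set.seed(99)
  prev <- character(0)
  for (k in seq_len(20L)) {
    grant_view(store, "grown", sample(views, 1L), "read")
    vis <- tuple_keys(query_as(store, "grown"))
    expect_true(all(vis %in% tuple_keys(tu)))  # containment
    expect_true(all(prev %in% vis))            # monotone under added grants
    prev <- vis
  }
})
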