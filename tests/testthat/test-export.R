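# Exporter: reconstruction/round-trip, preselection, the rule language,
# completeness checking and the export loop.

test_that("reconstruction preserves mixed content and lexical forms", {
  store <- eav_open(":memory:")
  on.exit(eav_close(store))
  xml <- "<a n=\"042\">t1<b k=\"x &amp; y\"/>t2</a>"
  rep <- import_document(store, xml)
  rec <- reconstruct_document(store, rep$source_doc_id)
  expect_identical(canonical_xml(rec), canonical_xml(xml))
  expect_match(rec, "n=\"042\"", fixed = TRUE)   # lexical, not the parsed 42
  expect_match(rec, ">t1<", fixed = TRUE)
  expect_error(reconstruct_document(store, 42L), "unknown")
})

test_that("canonical form ignores attribute order, whitespace and comments", {
  a <- "<r><s x=\"1\" y=\"2\">v</s></r>"
  b <- "<r>\n  <s y=\"2\" x=\"1\"><!-- c -->v</s>\n</r>"
  expect_identical(canonical_xml(a), canonical_xml(b))
  expect_false(identical(canonical_xml(a), canonical_xml("<r><s x=\"1\">v</s></r>")))
})

test_that("preselection filters by doc, flag and path pattern", {
  p <- gen_params(seed = 21, n_docs = 4)
  corp <- generate_corpus(p)
  store <- import_corpus(corp)
  on.exit(eav_close(store))
  body <- preselect(store, list(metadata = FALSE))
  expect_true(all(!body$metadata))
  one <- preselect(store, list(doc_ids = 2L))
  expect_true(all(one$source_doc_id == 2L))
  sec5 <- preselect(store, list(
    path_patterns = "/ClinicalDocument[1]/component[*]/structuredBody[1]/component[5]"))
  mf <- manifest_facts(corp$manifest)
  oracle <- mf[!is.na(mf$section) & mf$section == "Medical Information", ]
  expect_identical(nrow(sec5), nrow(oracle))
  expect_setequal(sec5$lexical, oracle$lexical)
  expect_identical(nrow(preselect(store, list(doc_ids = integer(0)))), 0L)
})

test_that("rules place transformed values and conflicts are reported", {
  store <- eav_open(":memory:")
  on.exit(eav_close(store))
  import_document(store, "<a x=\"1\"><b d=\"2013-02-04\"/></a>")
  sel <- preselect(store)
  tree <- apply_rules(sel, list(
    transform_rule("/a[1]/@x", "/out[1]/item[1]/@x"),
    transform_rule("/a[1]/b[*]/@d", "/out[1]/when[1]/#text", transform = "date_de")
  ), store, quiet = TRUE)
  expect_identical(tree$slots[["/out[1]/item[1]/@x"]]$value, "1")
  expect_identical(tree$slots[["/out[1]/when[1]/#text"]]$value, "04.02.2013")
  xml <- generate_target(tree)
  expect_match(xml, "<when>04.02.2013</when>", fixed = TRUE)
  # empty selection -> empty tree
  empty <- apply_rules(preselect(store, list(doc_ids = integer(0))),
                       list(transform_rule("/a[1]/@x", "/out[1]/@x")), store)
  expect_length(empty$slots, 0L)
  # conflicting writes name both rules
  expect_error(
    apply_rules(sel, list(
      transform_rule("/a[1]/@x", "/out[1]/@v"),
      transform_rule("/a[1]/b[*]/@d", "/out[1]/@v")
    ), store, quiet = TRUE),
    "rule #1.*rule #2")
  # unmatched selected facts are skipped with a notice
  expect_message(apply_rules(sel, list(transform_rule("/a[1]/@x", "/out[1]/@x")), store),
                 "matched no rule")
})

test_that("wildcard captures instantiate the target template", {
  store <- eav_open(":memory:")
  on.exit(eav_close(store))
  import_document(store, "<a><e v=\"1\"/><e v=\"2\"/><e v=\"3\"/></a>")
  tree <- apply_rules(preselect(store),
                      list(transform_rule("/a[1]/e[*]/@v", "/out[1]/item[*]/@v")),
                      store, quiet = TRUE)
  expect_setequal(names(tree$slots),
                  c("/out[1]/item[1]/@v", "/out[1]/item[2]/@v", "/out[1]/item[3]/@v"))
  expect_match(generate_target(tree), "<item v=\"2\"/>", fixed = TRUE)
})

test_that("completeness check returns exactly the unmet requirements", {
  store <- eav_open(":memory:")
  on.exit(eav_close(store))
  import_document(store, "<a x=\"1\" y=\"2\"/>")
  tree <- apply_rules(preselect(store), list(
    transform_rule("/a[1]/@x", "/out[1]/p[1]/@x")), store, quiet = TRUE)
  spec <- completeness_spec(c("/out[1]/p[1]/@x", "/out[1]/p[1]/@y", "/out[1]/q[1]"),
                            root = "out")
  missing <- check_completeness(tree, spec)
  expect_identical(as.character(missing), c("/out[1]/p[1]/@y", "/out[1]/q[1]"))
  expect_length(check_completeness(tree, completeness_spec()), 0L)
  bad_root <- check_completeness(tree, completeness_spec(root = "report"))
  expect_match(attr(bad_root, "problems"), "expected 'report'")
})

test_that("the export loop iterates until complete and is deterministic", {
  store <- eav_open(":memory:")
  on.exit(eav_close(store))
  import_document(store, "<a p=\"1\" q=\"2\" r=\"3\"/>")
  rules <- list(
    transform_rule("/a[1]/@p", "/out[1]/@p"),
    transform_rule("/a[1]/@q", "/out[1]/@q"),
    transform_rule("/a[1]/@r", "/out[1]/@r"))
  spec <- completeness_spec(c("/out[1]/@p", "/out[1]/@q", "/out[1]/@r"))
  # complete on the first pass
  res <- export_document(store, list(), rules, spec)
  expect_identical(res$iterations, 1L)
  expect_length(check_completeness(res$tree, spec), 0L)
  # scripted selector: starts 2 short, adds one fact per pass -> 3 iterations
  pre <- preselect(store)
  scripted <- local({
    added <- "p"
    function(selection, missing) {
      if (!is.null(missing)) added <<- c(added, setdiff(c("q", "r"), added)[1L])
      pre[pre$attribute %in% added, ]
    }
  })
  res2 <- export_document(store, list(), rules, spec, selector = scripted)
  expect_identical(res2$iterations, 3L)
  # determinism: identical inputs give byte-identical output
  res3 <- export_document(store, list(), rules, spec)
  expect_identical(res$document, res3$document)
  # a selector that never completes hits the iteration bound
  stuck <- function(selection, missing) selection[selection$attribute == "p", ]
  err <- tryCatch(
    export_document(store, list(), rules, spec, selector = stuck,
                    max_iterations = 4L),
    error = function(e) e)
  expect_s3_class(err, "eav_export_incomplete")
  expect_setequal(err$missing, c("/out[1]/@q", "/out[1]/@r"))
})

test_that("rule and completeness configs round-trip through JSON files", {
  rules_file <- file.path(tempdir(), "rules.json")
  spec_file <- file.path(tempdir(), "spec.json")
  on.exit(unlink(c(rules_file, spec_file)))
  writeLines('[{"source": "/a[1]/@x", "target": "/out[1]/@x", "required": true}]',
             rules_file)
  writeLines('{"required_paths": ["/out[1]/@x"], "root": "out"}', spec_file)
  rules <- read_rules_file(rules_file)
  expect_length(rules, 1L)
  expect_true(rules[[1L]]$required)
  spec <- read_completeness_file(spec_file)
  expect_identical(spec$required_paths, "/out[1]/@x")
  expect_identical(spec$root, "out")
})
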