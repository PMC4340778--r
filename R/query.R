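# Query engine: recursive ancestor-path composition, the general all-tuples
# query, the attribute-centric term search, and a three-phase timing harness
# (connection / execution / result traversal).

#' Compose the ancestor path of an entity
#'
#' Follows parent links to the root with a recursive common table expression
#' and joins each ancestor's name with its sibling position:
#' `/ClinicalDocument[1]/recordTarget[2]/...`.
#'
#' @param store an `eav_store`.
#' @param entity_id an entity id.
#' @return the path string.
#' @export
ancestor_path <- function(store, entity_id) {
  rows <- DBI::dbGetQuery(store$con,
    "WITH RECURSIVE anc(entity_id, name, parent_id, sibling_pos, depth) AS (
       SELECT entity_id, name, parent_id, sibling_pos, 0
       FROM entity WHERE entity_id = ?
       UNION ALL
       SELECT e.entity_id, e.name, e.parent_id, e.sibling_pos, anc.depth + 1
       FROM entity e JOIN anc ON e.entity_id = anc.parent_id)
     SELECT name, sibling_pos FROM anc ORDER BY depth DESC",
    params = list(entity_id))
  if (!nrow(rows)) stop("unknown entity: ", entity_id, call. = FALSE)
  make_path(rows$name, rows$sibling_pos)
}

as_tuples <- function(df) {
  out <- df[, c("path", "attribute", "lexical", "source_doc_id", "metadata")]
  names(out) <- c("entity_path", "attribute", "value", "source_doc_id", "is_metadata")
  rownames(out) <- NULL
  out
}

#' All entity-attribute-value tuples in the store
#'
#' The general query: one `{entity path, attribute, value}` tuple per stored
#' fact, in a stable (document, path, attribute) order. The source document
#' id and the header/body flag are carried as extra columns.
#'
#' @param store an `eav_store`.
#' @return data.frame with columns `entity_path`, `attribute`, `value`,
#'   `source_doc_id`, `is_metadata`.
#' @export
all_tuples <- function(store) {
  as_tuples(fact_frame(store))
}

#' Documents containing a search term
#'
#' The subquery of the attribute-centric evaluation query: ids of all source
#' documents with at least one fact whose lexical contains the term
#' (case-insensitive substring, header and body alike).
#'
#' @param store an `eav_store`.
#' @param term nonempty search string.
#' @return integer vector of document ids (no duplicates).
#' @export
find_documents <- function(store, term) {
  if (!is.character(term) || length(term) != 1L || !nzchar(term)) {
    stop("search term must be a nonempty string", call. = FALSE)
  }
  sql <- sprintf(
    "SELECT DISTINCT source_doc_id FROM (%s)
     WHERE instr(lower(lexical), lower(?)) > 0
     ORDER BY source_doc_id", value_union_sql(store))
  DBI::dbGetQuery(store$con, sql, params = list(term))$source_doc_id
}

#' All tuples of a set of documents
#'
#' Equals [all_tuples()] restricted to the given documents; combined with
#' [find_documents()] it forms the attribute-centric query.
#'
#' @param store an `eav_store`.
#' @param doc_ids document ids (must exist).
#' @return data.frame as in [all_tuples()].
#' @export
tuples_for_documents <- function(store, doc_ids) {
  if (length(doc_ids)) {
    known <- DBI::dbGetQuery(store$con, sprintf(
      "SELECT source_doc_id FROM source_doc WHERE source_doc_id IN (%s)",
      paste(as.integer(doc_ids), collapse = ",")))$source_doc_id
    missing <- setdiff(as.integer(doc_ids), known)
    if (length(missing)) {
      stop("unknown source document(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  as_tuples(fact_frame(store, doc_ids = doc_ids))
}

#' Specify a query for the timing harness
#'
#' @param type `"all"` (the general query) or `"term"` (the attribute-centric
#'   term search, returning all tuples of the matching documents).
#' @param term search term, required for `type = "term"`.
#' @return an `eav_query_spec`.
#' @export
query_spec <- function(type = c("all", "term"), term = NULL) {
  type <- match.arg(type)
  if (type == "term" && (is.null(term) || !nzchar(term))) {
    stop("type = \"term\" requires a nonempty term", call. = FALSE)
  }
  structure(list(type = type, term = term), class = "eav_query_spec")
}

run_query_spec <- function(store, spec) {
  switch(spec$type,
    all = all_tuples(store),
    term = tuples_for_documents(store, find_documents(store, spec$term)))
}

#' Run a query with three-phase timing
#'
#' Splits the wall time into the phases used for response-time evaluation:
#' *Before Querying* (acquiring a database connection), *Querying* (executing
#' the SQL and fetching rows) and *After Querying* (traversing the fetched
#' rows into result tuples). The result is identical to the untimed
#' operation. For an in-memory store the connection cannot be re-acquired, so
#' the before-phase only validates the existing connection.
#'
#' @param store an `eav_store`.
#' @param spec an [query_spec()].
#' @return list with `result` and `timings` (`before_ms`, `query_ms`,
#'   `after_ms`, `n_rows`).
#' @export
timed_query <- function(store, spec) {
  stopifnot(inherits(spec, "eav_query_spec"))
  ms <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    force(expr)
    (proc.time()[["elapsed"]] - t0) * 1000
  }

  own_con <- NULL
  before_ms <- ms({
    if (store$path != ":memory:") {
      own_con <- DBI::dbConnect(RSQLite::SQLite(), store$path)
      DBI::dbExecute(own_con, "PRAGMA foreign_keys = ON")
    } else {
      stopifnot(DBI::dbIsValid(store$con))
    }
  })
  qstore <- if (is.null(own_con)) store else {
    structure(list(con = own_con, path = store$path), class = "eav_store")
  }
  on.exit(if (!is.null(own_con)) DBI::dbDisconnect(own_con))

  raw <- NULL
  query_ms <- ms({
    raw <- if (spec$type == "all") {
      fact_frame(qstore)
    } else {
      fact_frame(qstore, doc_ids = find_documents(qstore, spec$term))
    }
  })

  result <- NULL
  after_ms <- ms({
    result <- as_tuples(raw)
    n_rows <- nrow(result)
  })

  list(result = result,
       timings = list(before_ms = before_ms, query_ms = query_ms,
                      after_ms = after_ms, n_rows = nrow(result)))
}

#' Benchmark the evaluation queries
#'
#' Runs a query repeatedly and reports the three timing phases separately,
#' as the first run next to the average over all runs (the first run is the
#' one least affected by caching).
#'
#' @param store an `eav_store`.
#' @param spec an [query_spec()].
#' @param repeats number of consecutive runs (default 10).
#' @return an `eav_bench` data.frame: one row per phase with columns
#'   `phase`, `first_run_ms`, `avg_ms`, `min_ms`, `max_ms`, plus attributes
#'   `n_rows` and `repeats`.
#' @export
bench_query <- function(store, spec, repeats = 10L) {
  stopifnot(repeats >= 1L)
  runs <- vector("list", repeats)
  n_rows <- NA_integer_
  for (i in seq_len(repeats)) {
    r <- timed_query(store, spec)
    runs[[i]] <- unlist(r$timings[c("before_ms", "query_ms", "after_ms")])
    n_rows <- r$timings$n_rows
  }
  m <- do.call(rbind, runs)
  out <- data.frame(
    phase = c("before_querying", "querying", "after_querying"),
    first_run_ms = m[1L, ],
    avg_ms = colMeans(m),
    min_ms = apply(m, 2L, min),
    max_ms = apply(m, 2L, max),
    row.names = NULL)
  structure(out, class = c("eav_bench", "data.frame"),
            n_rows = n_rows, repeats = repeats,
            query = spec$type, term = spec$term)
}

#' @export
print.eav_bench <- function(x, ...) {
  cat("query: ", attr(x, "query"),
      if (!is.null(attr(x, "term"))) paste0(" (term: \"", attr(x, "term"), "\")"),
      "  rows: ", attr(x, "n_rows"), "  runs: ", attr(x, "repeats"), "\n", sep = "")
  print.data.frame(cbind(x[1L], round(x[-1L], 2L)), row.names = FALSE)
  invisible(x)
}
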