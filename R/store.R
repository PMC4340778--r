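# Core extended-EAV schema and its low-level operations.
#
# The relational layout follows the classic three-relation EAV design,
# extended for hierarchical documents:
#   entity     - one row per XML element occurrence (or text pseudo-node),
#                with Parent and Sibling_Pos columns carrying the hierarchy;
#   attribute  - deduplicated dictionary of attribute names; there is NO
#                direct entity<->attribute link: the pairing lives only in
#                the value tables;
#   <tag>_value - one table per registered datatype, each row tying an
#                entity, an attribute and a source document, with the
#                verbatim lexical form, the typed value and a header/body
#                (metadata) flag;
#   source_doc - provenance per imported document, including the raw text
#                (restorability) and its digest.

#' Open (or create) an EAV store
#'
#' Creates all schema tables on first open; re-opening an existing store is
#' idempotent and sees previously imported data. Use `path = ":memory:"` for
#' an in-memory store.
#'
#' @param path file path of the SQLite database, or `":memory:"`.
#' @return an `eav_store` handle.
#' @examples
#' store <- eav_open(":memory:")
#' nrow(all_tuples(store))  # 0
#' eav_close(store)
#' @export
eav_open <- function(path = ":memory:") {
  if (path != ":memory:") {
    dir <- dirname(path)
    if (!dir.exists(dir) || file.access(dir, 2L) != 0L) {
      stop("store location is not writable: ", dir, call. = FALSE)
    }
  }
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  DBI::dbExecute(con, "PRAGMA foreign_keys = ON")
  store <- structure(list(con = con, path = path), class = "eav_store")
  create_schema(store)
  store
}

#' @export
print.eav_store <- function(x, ...) {
  n_docs <- DBI::dbGetQuery(x$con, "SELECT COUNT(*) AS n FROM source_doc")$n
  n_ent <- DBI::dbGetQuery(x$con, "SELECT COUNT(*) AS n FROM entity")$n
  cat("<eav_store> ", if (x$path == ":memory:") "(in-memory)" else x$path,
      "\n  documents: ", n_docs, "  entities: ", n_ent,
      "  datatypes: ", paste(registered_datatypes(x), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Close an EAV store
#' @param store an `eav_store` handle.
#' @export
eav_close <- function(store) {
  stopifnot(inherits(store, "eav_store"))
  DBI::dbDisconnect(store$con)
  invisible(NULL)
}

create_schema <- function(store) {
  con <- store$con
  stmts <- c(
    "CREATE TABLE IF NOT EXISTS datatype (
       tag TEXT PRIMARY KEY,
       sql_type TEXT NOT NULL)",
    "CREATE TABLE IF NOT EXISTS source_doc (
       source_doc_id INTEGER PRIMARY KEY,
       author TEXT,
       doc_type TEXT,
       template TEXT,
       received_at TEXT,
       digest TEXT NOT NULL,
       version INTEGER NOT NULL DEFAULT 1,
       root_entity_id INTEGER,
       raw TEXT NOT NULL)",
    "CREATE TABLE IF NOT EXISTS entity (
       entity_id INTEGER PRIMARY KEY,
       name TEXT NOT NULL,
       parent_id INTEGER REFERENCES entity(entity_id),
       sibling_pos INTEGER NOT NULL CHECK (sibling_pos >= 1))",
    "CREATE UNIQUE INDEX IF NOT EXISTS idx_entity_sibling
       ON entity(parent_id, sibling_pos) WHERE parent_id IS NOT NULL",
    "CREATE TABLE IF NOT EXISTS attribute (
       attribute_id INTEGER PRIMARY KEY,
       name TEXT NOT NULL UNIQUE)",
    "CREATE TABLE IF NOT EXISTS entity_path (
       entity_id INTEGER PRIMARY KEY REFERENCES entity(entity_id),
       source_doc_id INTEGER NOT NULL REFERENCES source_doc(source_doc_id),
       path TEXT NOT NULL)",
    "CREATE TABLE IF NOT EXISTS view_spec (
       view_id INTEGER PRIMARY KEY,
       name TEXT NOT NULL UNIQUE,
       spec_json TEXT NOT NULL)",
    "CREATE TABLE IF NOT EXISTS grant_tbl (
       grant_id INTEGER PRIMARY KEY,
       role TEXT NOT NULL,
       view_id INTEGER NOT NULL REFERENCES view_spec(view_id),
       rights TEXT NOT NULL)"
  )
  for (s in stmts) DBI::dbExecute(con, s)
  existing <- DBI::dbGetQuery(con, "SELECT tag FROM datatype")$tag
  for (tag in names(.builtin_datatypes)) {
    if (!tag %in% existing) {
      register_datatype(store, tag, .builtin_datatypes[[tag]]$sql_type)
    }
  }
  # Tags registered by an earlier session: make sure their tables exist.
  for (tag in setdiff(existing, names(.builtin_datatypes))) {
    ensure_value_table(store, tag,
                       DBI::dbGetQuery(con,
                         "SELECT sql_type FROM datatype WHERE tag = ?",
                         params = list(tag))$sql_type)
  }
  invisible(store)
}

value_table <- function(tag) paste0(tag, "_value")

ensure_value_table <- function(store, tag, sql_type) {
  DBI::dbExecute(store$con, sprintf(
    "CREATE TABLE IF NOT EXISTS %s (
       value_id INTEGER PRIMARY KEY,
       entity_id INTEGER NOT NULL REFERENCES entity(entity_id),
       attribute_id INTEGER NOT NULL REFERENCES attribute(attribute_id),
       source_doc_id INTEGER NOT NULL REFERENCES source_doc(source_doc_id),
       lexical TEXT NOT NULL,
       typed %s,
       metadata INTEGER NOT NULL DEFAULT 0,
       version INTEGER NOT NULL DEFAULT 1,
       current INTEGER NOT NULL DEFAULT 1)",
    value_table(tag), sql_type))
}

#' Register an additional datatype tag
#'
#' Extends the typed-value-table registry beyond the built-in representative
#' set (string, integer, real, boolean, date, timestamp). A new value table is
#' created for the tag. `parse` maps a lexical to the typed value and returns
#' `NULL` for invalid lexicals; it defaults to identity (string semantics).
#'
#' @param store an `eav_store`.
#' @param tag new unique tag name.
#' @param sql_type SQL column type for the typed value.
#' @param parse optional parser function.
#' @return the tag, invisibly.
#' @export
register_datatype <- function(store, tag, sql_type = "TEXT", parse = NULL) {
  stopifnot(is.character(tag), length(tag) == 1L, nzchar(tag))
  if (!grepl("^[a-zA-Z][a-zA-Z0-9_]*$", tag)) {
    stop("datatype tag must be a simple identifier: ", tag, call. = FALSE)
  }
  known <- DBI::dbGetQuery(store$con, "SELECT tag FROM datatype WHERE tag = ?",
                           params = list(tag))$tag
  if (!length(known)) {
    DBI::dbExecute(store$con, "INSERT INTO datatype(tag, sql_type) VALUES (?, ?)",
                   params = list(tag, sql_type))
  }
  ensure_value_table(store, tag, sql_type)
  if (!is.null(parse)) {
    .eav_runtime$extra_datatypes[[tag]] <- list(sql_type = sql_type, parse = parse)
  }
  invisible(tag)
}

#' List the datatype tags registered in a store
#' @param store an `eav_store`.
#' @return character vector of tags.
#' @export
registered_datatypes <- function(store) {
  DBI::dbGetQuery(store$con, "SELECT tag FROM datatype ORDER BY tag")$tag
}

#' Insert or look up an attribute name
#'
#' The attribute relation is a shared dictionary: importing the same name
#' twice yields one row, and the id of the existing row is returned.
#'
#' @param store an `eav_store`.
#' @param name attribute name (nonempty).
#' @return the attribute id.
#' @export
upsert_attribute <- function(store, name) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("attribute name must be a nonempty string", call. = FALSE)
  }
  hit <- DBI::dbGetQuery(store$con,
    "SELECT attribute_id FROM attribute WHERE name = ?", params = list(name))
  if (nrow(hit)) return(hit$attribute_id[[1L]])
  DBI::dbExecute(store$con, "INSERT INTO attribute(name) VALUES (?)",
                 params = list(name))
  DBI::dbGetQuery(store$con, "SELECT last_insert_rowid() AS id")$id[[1L]]
}

#' Insert one entity occurrence
#'
#' Entities are per-occurrence rows: one row per element instance (or text
#' pseudo-node), carrying the parent link and the 1-based position among all
#' siblings in document order.
#'
#' @param store an `eav_store`.
#' @param name qualified element name.
#' @param parent_id parent entity id, or `NULL` for a document root.
#' @param sibling_pos integer >= 1; must not collide with an existing child of
#'   the same parent.
#' @return the new entity id.
#' @export
insert_entity <- function(store, name, parent_id = NULL, sibling_pos = 1L) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  sibling_pos <- as.integer(sibling_pos)
  if (is.na(sibling_pos) || sibling_pos < 1L) {
    stop("sibling_pos must be an integer >= 1", call. = FALSE)
  }
  if (!is.null(parent_id)) {
    ok <- DBI::dbGetQuery(store$con,
      "SELECT COUNT(*) AS n FROM entity WHERE entity_id = ?",
      params = list(parent_id))$n
    if (ok == 0L) stop("parent entity ", parent_id, " does not exist", call. = FALSE)
    clash <- DBI::dbGetQuery(store$con,
      "SELECT COUNT(*) AS n FROM entity WHERE parent_id = ? AND sibling_pos = ?",
      params = list(parent_id, sibling_pos))$n
    if (clash > 0L) {
      stop("sibling_pos ", sibling_pos, " already taken under parent ",
           parent_id, call. = FALSE)
    }
  }
  DBI::dbExecute(store$con,
    "INSERT INTO entity(name, parent_id, sibling_pos) VALUES (?, ?, ?)",
    params = list(name, if (is.null(parent_id)) NA else parent_id, sibling_pos))
  DBI::dbGetQuery(store$con, "SELECT last_insert_rowid() AS id")$id[[1L]]
}

#' Construct a value fact
#'
#' @param entity_id,attribute_id,source_doc_id references into the store.
#' @param lexical verbatim source string.
#' @param datatype datatype tag; inferred from the lexical when `NULL`.
#' @param typed_value parsed value; derived from the lexical when `NULL`.
#' @param is_metadata `TRUE` for facts from the document header.
#' @return a `value_fact` list.
#' @export
value_fact <- function(entity_id, attribute_id, source_doc_id, lexical,
                       datatype = NULL, typed_value = NULL,
                       is_metadata = FALSE) {
  stopifnot(is.character(lexical), length(lexical) == 1L)
  datatype <- datatype %||% infer_datatype(lexical)
  typed_value <- typed_value %||% parse_lexical(lexical, datatype)
  structure(
    list(entity_id = entity_id, attribute_id = attribute_id,
         source_doc_id = source_doc_id, lexical = lexical,
         datatype = datatype, typed_value = typed_value,
         is_metadata = isTRUE(is_metadata)),
    class = "value_fact")
}

#' Insert one value fact
#'
#' The fact is routed to the value table selected by its datatype tag. The
#' lexical is stored verbatim next to the typed value; the typed value must
#' reparse from the lexical.
#'
#' @param store an `eav_store`.
#' @param fact a [value_fact()].
#' @return the new value id.
#' @export
insert_value <- function(store, fact) {
  stopifnot(inherits(fact, "value_fact"))
  tags <- registered_datatypes(store)
  if (!fact$datatype %in% tags) {
    stop("datatype '", fact$datatype, "' is not registered", call. = FALSE)
  }
  reparsed <- datatype_def(fact$datatype)$parse(fact$lexical)
  if (is.null(reparsed) || !identical(as.character(reparsed), as.character(fact$typed_value))) {
    stop("typed_value is inconsistent with lexical under datatype '",
         fact$datatype, "'", call. = FALSE)
  }
  typed <- fact$typed_value
  if (is.logical(typed)) typed <- as.integer(typed)
  DBI::dbExecute(store$con, sprintf(
    "INSERT INTO %s (entity_id, attribute_id, source_doc_id, lexical, typed, metadata)
     VALUES (?, ?, ?, ?, ?, ?)", value_table(fact$datatype)),
    params = list(fact$entity_id, fact$attribute_id, fact$source_doc_id,
                  fact$lexical, typed, as.integer(fact$is_metadata)))
  DBI::dbGetQuery(store$con, "SELECT last_insert_rowid() AS id")$id[[1L]]
}

#' Register a source document
#'
#' Stores the provenance metadata and the raw text of an imported document.
#' The raw text is retained byte-identically; its MD5 digest enforces the
#' duplicate policy: `"reject"` (default) refuses a document whose digest is
#' already present, `"version"` stores it again with an incremented version.
#'
#' @param store an `eav_store`.
#' @param raw document text (character scalar) or raw vector.
#' @param author,doc_type,template,received_at provenance fields.
#' @param on_duplicate `"reject"` or `"version"`.
#' @return the new source document id.
#' @export
register_source_doc <- function(store, raw, author = NA_character_,
                                doc_type = NA_character_,
                                template = NA_character_,
                                received_at = NULL,
                                on_duplicate = c("reject", "version")) {
  on_duplicate <- match.arg(on_duplicate)
  if (is.raw(raw)) raw <- rawToChar(raw)
  stopifnot(is.character(raw), length(raw) == 1L)
  if (!nzchar(raw)) stop("raw document must be nonempty", call. = FALSE)
  digest <- content_digest(raw)
  prev <- DBI::dbGetQuery(store$con,
    "SELECT MAX(version) AS v FROM source_doc WHERE digest = ?",
    params = list(digest))$v
  version <- 1L
  if (!is.na(prev)) {
    if (on_duplicate == "reject") {
      stop("duplicate document (digest ", digest, ") rejected", call. = FALSE)
    }
    version <- prev + 1L
  }
  received_at <- received_at %||% now_timestamp()
  DBI::dbExecute(store$con,
    "INSERT INTO source_doc(author, doc_type, template, received_at, digest, version, raw)
     VALUES (?, ?, ?, ?, ?, ?, ?)",
    params = list(author, doc_type, template, received_at, digest, version, raw))
  DBI::dbGetQuery(store$con, "SELECT last_insert_rowid() AS id")$id[[1L]]
}

#' Retrieve the raw text of an imported document
#' @param store an `eav_store`.
#' @param source_doc_id a document id.
#' @return the stored document text, byte-identical to what was imported.
#' @export
get_raw <- function(store, source_doc_id) {
  r <- DBI::dbGetQuery(store$con,
    "SELECT raw FROM source_doc WHERE source_doc_id = ?",
    params = list(source_doc_id))
  if (!nrow(r)) stop("unknown source document: ", source_doc_id, call. = FALSE)
  r$raw[[1L]]
}

#' Provenance metadata of imported documents
#' @param store an `eav_store`.
#' @param source_doc_id optional id filter.
#' @return data.frame with one row per document.
#' @export
source_docs <- function(store, source_doc_id = NULL) {
  sql <- "SELECT source_doc_id, author, doc_type, template, received_at,
                 digest, version, root_entity_id
          FROM source_doc"
  if (is.null(source_doc_id)) {
    DBI::dbGetQuery(store$con, paste(sql, "ORDER BY source_doc_id"))
  } else {
    DBI::dbGetQuery(store$con, paste(sql, "WHERE source_doc_id = ?"),
                    params = list(source_doc_id))
  }
}

#' Row counts of the store's relations
#' @param store an `eav_store`.
#' @return named integer vector: entities, attributes, documents, values, and
#'   per-datatype value counts.
#' @export
store_counts <- function(store) {
  con <- store$con
  tags <- registered_datatypes(store)
  per <- vapply(tags, function(tg) {
    DBI::dbGetQuery(con, sprintf(
      "SELECT COUNT(*) AS n FROM %s WHERE current = 1", value_table(tg)))$n
  }, numeric(1L))
  c(entities = DBI::dbGetQuery(con, "SELECT COUNT(*) AS n FROM entity")$n,
    attributes = DBI::dbGetQuery(con, "SELECT COUNT(*) AS n FROM attribute")$n,
    documents = DBI::dbGetQuery(con, "SELECT COUNT(*) AS n FROM source_doc")$n,
    values = sum(per),
    per)
}

# SQL fragment selecting the union of all current value rows.
value_union_sql <- function(store) {
  tags <- registered_datatypes(store)
  paste(vapply(tags, function(tg) sprintf(
    "SELECT value_id, entity_id, attribute_id, source_doc_id, lexical,
            metadata, version, '%s' AS datatype FROM %s WHERE current = 1",
    tg, value_table(tg)), character(1L)),
    collapse = " UNION ALL ")
}

# Entities referenced by facts but absent from the path cache (possible via
# the low-level insert API) get their paths composed on demand, so the
# one-tuple-per-fact contract holds regardless of how facts were loaded.
ensure_orphan_paths <- function(store) {
  orphans <- DBI::dbGetQuery(store$con, sprintf(
    "SELECT DISTINCT entity_id, MIN(source_doc_id) AS source_doc_id
     FROM (%s) WHERE entity_id NOT IN (SELECT entity_id FROM entity_path)
     GROUP BY entity_id", value_union_sql(store)))
  for (i in seq_len(nrow(orphans))) {
    DBI::dbExecute(store$con,
      "INSERT INTO entity_path(entity_id, source_doc_id, path) VALUES (?, ?, ?)",
      params = list(orphans$entity_id[[i]], orphans$source_doc_id[[i]],
                    ancestor_path(store, orphans$entity_id[[i]])))
  }
  invisible(nrow(orphans))
}

# Full fact frame: one row per current value fact with path and provenance.
# The backbone of the query engine, the exporter and the access layer.
fact_frame <- function(store, doc_ids = NULL) {
  ensure_orphan_paths(store)
  sql <- sprintf(
    "SELECT v.value_id, v.datatype, v.entity_id, v.attribute_id,
            v.source_doc_id, p.path, a.name AS attribute, v.lexical,
            v.metadata, d.author, d.doc_type, d.received_at
     FROM (%s) v
     JOIN attribute a ON a.attribute_id = v.attribute_id
     JOIN entity_path p ON p.entity_id = v.entity_id
     JOIN source_doc d ON d.source_doc_id = v.source_doc_id",
    value_union_sql(store))
  if (!is.null(doc_ids)) {
    if (!length(doc_ids)) {
      df <- DBI::dbGetQuery(store$con, paste(sql, "WHERE 1 = 0"))
      return(df)
    }
    sql <- paste0(sql, " WHERE v.source_doc_id IN (",
                  paste(as.integer(doc_ids), collapse = ","), ")")
  }
  sql <- paste(sql, "ORDER BY v.source_doc_id, p.path, a.name, v.value_id")
  df <- DBI::dbGetQuery(store$con, sql)
  df$metadata <- as.logical(df$metadata)
  df
}
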