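# View-based access control: horizontal (row) and vertical (column) fragments
# of the fact space, with per-role read/add/delete/update rights, enforced in
# the engine's query layer at sub-document granularity. A role's visible set
# is the union of the fragments of all views granted to it with the relevant
# right.

RIGHTS <- c("read", "add", "delete", "update")

#' Define a view specification
#'
#' A view is a fragment of the fact space. The horizontal part is a predicate
#' over facts' provenance and header/body flag; the vertical part restricts
#' entity paths and/or attribute names. Omitted parts mean "all".
#'
#' @param name unique view name.
#' @param received_from,received_to inclusive bounds on the source document's
#'   receipt timestamp (horizontal).
#' @param doc_types restrict to documents of these types (horizontal).
#' @param metadata `TRUE` header-only, `FALSE` body-only (horizontal).
#' @param path_patterns prefix path patterns (vertical).
#' @param attributes attribute names (vertical).
#' @return an `eav_view_spec`.
#' @export
view_spec <- function(name, received_from = NULL, received_to = NULL,
                      doc_types = NULL, metadata = NULL,
                      path_patterns = NULL, attributes = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  for (pp in path_patterns) parse_pattern_segments(split_fact_pattern(pp)$path)
  structure(list(name = name, received_from = received_from,
                 received_to = received_to, doc_types = doc_types,
                 metadata = metadata, path_patterns = path_patterns,
                 attributes = attributes),
            class = "eav_view_spec")
}

#' Register a view in the store
#' @param store an `eav_store`.
#' @param spec an [view_spec()].
#' @return the view id.
#' @export
define_view <- function(store, spec) {
  stopifnot(inherits(spec, "eav_view_spec"))
  dup <- DBI::dbGetQuery(store$con, "SELECT COUNT(*) AS n FROM view_spec WHERE name = ?",
                         params = list(spec$name))$n
  if (dup > 0L) stop("view name already defined: ", spec$name, call. = FALSE)
  DBI::dbExecute(store$con, "INSERT INTO view_spec(name, spec_json) VALUES (?, ?)",
                 params = list(spec$name,
                               jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, null = "null")))
  DBI::dbGetQuery(store$con, "SELECT last_insert_rowid() AS id")$id[[1L]]
}

load_view <- function(store, view_id) {
  r <- DBI::dbGetQuery(store$con, "SELECT spec_json FROM view_spec WHERE view_id = ?",
                       params = list(view_id))
  if (!nrow(r)) stop("unknown view: ", view_id, call. = FALSE)
  s <- jsonlite::fromJSON(r$spec_json[[1L]], simplifyVector = TRUE)
  do.call(view_spec, s[!vapply(s, is.null, logical(1L))])
}

#' Grant rights on a view to a role
#'
#' @param store an `eav_store`.
#' @param role role (user group) name.
#' @param view view id, or view name.
#' @param rights nonempty subset of `read`, `add`, `delete`, `update`.
#' @return the grant id.
#' @export
grant_view <- function(store, role, view, rights = "read") {
  stopifnot(is.character(role), length(role) == 1L, nzchar(role))
  if (!length(rights) || !all(rights %in% RIGHTS)) {
    stop("rights must be a nonempty subset of: ", paste(RIGHTS, collapse = ", "),
         call. = FALSE)
  }
  if (is.character(view)) {
    r <- DBI::dbGetQuery(store$con, "SELECT view_id FROM view_spec WHERE name = ?",
                         params = list(view))
    if (!nrow(r)) stop("unknown view name: ", view, call. = FALSE)
    view <- r$view_id[[1L]]
  } else {
    ok <- DBI::dbGetQuery(store$con, "SELECT COUNT(*) AS n FROM view_spec WHERE view_id = ?",
                          params = list(view))$n
    if (ok == 0L) stop("unknown view: ", view, call. = FALSE)
  }
  DBI::dbExecute(store$con, "INSERT INTO grant_tbl(role, view_id, rights) VALUES (?, ?, ?)",
                 params = list(role, view, paste(sort(unique(rights)), collapse = ",")))
  DBI::dbGetQuery(store$con, "SELECT last_insert_rowid() AS id")$id[[1L]]
}

#' Revoke a grant
#' @param store an `eav_store`.
#' @param grant_id a grant id.
#' @export
revoke_grant <- function(store, grant_id) {
  n <- DBI::dbExecute(store$con, "DELETE FROM grant_tbl WHERE grant_id = ?",
                      params = list(grant_id))
  if (n == 0L) stop("unknown grant: ", grant_id, call. = FALSE)
  invisible(NULL)
}

#' List grants, optionally per role
#' @param store an `eav_store`.
#' @param role optional role filter.
#' @return data.frame of grants with view names.
#' @export
grants <- function(store, role = NULL) {
  sql <- "SELECT g.grant_id, g.role, g.view_id, v.name AS view_name, g.rights
          FROM grant_tbl g JOIN view_spec v ON v.view_id = g.view_id"
  if (is.null(role)) DBI::dbGetQuery(store$con, paste(sql, "ORDER BY g.grant_id"))
  else DBI::dbGetQuery(store$con, paste(sql, "WHERE g.role = ? ORDER BY g.grant_id"),
                       params = list(role))
}

# Logical filter: which rows of a fact frame fall inside a view's fragment.
view_filter <- function(spec, df) {
  keep <- rep(TRUE, nrow(df))
  if (!is.null(spec$received_from)) keep <- keep & df$received_at >= spec$received_from
  if (!is.null(spec$received_to)) keep <- keep & df$received_at <= spec$received_to
  if (!is.null(spec$doc_types)) keep <- keep & df$doc_type %in% spec$doc_types
  if (!is.null(spec$metadata)) keep <- keep & (df$metadata == spec$metadata)
  vert <- NULL
  if (!is.null(spec$path_patterns)) {
    pats <- lapply(spec$path_patterns, split_fact_pattern)
    vert <- rep(FALSE, nrow(df))
    for (p in pats) {
      idx <- which(!vert)
      if (!length(idx)) break
      ok <- vapply(idx, function(i) {
        (p$attr == "*" || p$attr == df$attribute[[i]]) &&
          isTRUE(path_pattern_match(p$path, df$path[[i]], mode = "prefix"))
      }, logical(1L))
      vert[idx] <- ok
    }
  }
  if (!is.null(spec$attributes)) {
    byattr <- df$attribute %in% spec$attributes
    vert <- if (is.null(vert)) byattr else (vert | byattr)
  }
  if (!is.null(vert)) keep <- keep & vert
  keep
}

#' Evaluate a view to its fragment of facts
#' @param store an `eav_store`.
#' @param view view id or name.
#' @return an `eav_selection` data.frame of the fragment's facts.
#' @export
view_fragment <- function(store, view) {
  if (is.character(view)) {
    r <- DBI::dbGetQuery(store$con, "SELECT view_id FROM view_spec WHERE name = ?",
                         params = list(view))
    if (!nrow(r)) stop("unknown view name: ", view, call. = FALSE)
    view <- r$view_id[[1L]]
  }
  spec <- load_view(store, view)
  df <- fact_frame(store)
  out <- df[view_filter(spec, df), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("eav_selection", "data.frame")
  out
}

# Logical filter over a fact frame: facts on which `role` holds `right`.
role_filter <- function(store, role, right, df) {
  g <- grants(store, role)
  g <- g[vapply(strsplit(g$rights, ",", fixed = TRUE),
                function(r) right %in% r, logical(1L)), , drop = FALSE]
  if (!nrow(g)) return(NULL)  # no grant at all, distinct from empty fragment
  keep <- rep(FALSE, nrow(df))
  for (vid in unique(g$view_id)) {
    keep <- keep | view_filter(load_view(store, vid), df)
  }
  keep
}

auth_error <- function(role, right) {
  stop(errorCondition(
    paste0("role '", role, "' has no '", right, "' grant covering the request"),
    class = c("eav_auth_error", "error")))
}

#' Run a query as a role
#'
#' Enforces the role's readable fragment at query time: the result is the
#' unrestricted query result intersected with the union of the fragments of
#' all views the role holds a read grant on. Granularity is per fact: single
#' values can be hidden while sibling values show. A role without any read
#' grant gets an authorization error.
#'
#' @param store an `eav_store`.
#' @param role role name.
#' @param spec an [query_spec()].
#' @return data.frame as in [all_tuples()].
#' @export
query_as <- function(store, role, spec = query_spec("all")) {
  stopifnot(inherits(spec, "eav_query_spec"))
  df <- fact_frame(store)
  keep <- role_filter(store, role, "read", df)
  if (is.null(keep)) auth_error(role, "read")
  visible <- df[keep, , drop = FALSE]
  if (spec$type == "term") {
    hit_docs <- find_documents(store, spec$term)
    visible <- visible[visible$source_doc_id %in% hit_docs, , drop = FALSE]
  }
  as_tuples(visible)
}

# Locate one stored fact by (datatype, value_id); used by the write paths.
fetch_fact <- function(store, datatype, value_id) {
  if (!datatype %in% registered_datatypes(store)) {
    stop("datatype '", datatype, "' is not registered", call. = FALSE)
  }
  df <- fact_frame(store)
  row <- df[df$datatype == datatype & df$value_id == value_id, , drop = FALSE]
  if (!nrow(row)) stop("unknown fact: ", datatype, "/", value_id, call. = FALSE)
  row
}

require_right <- function(store, role, right, fact_row) {
  keep <- role_filter(store, role, right, fact_row)
  if (is.null(keep) || !any(keep)) auth_error(role, right)
  invisible(TRUE)
}

#' Delete a fact as a role
#'
#' Requires a `delete` grant whose fragment covers the fact. Imported facts
#' are immutable: deletion retires the row (it leaves current query results
#' but stays on record).
#'
#' @param store an `eav_store`.
#' @param role role name.
#' @param datatype,value_id fact reference.
#' @export
delete_value_as <- function(store, role, datatype, value_id) {
  row <- fetch_fact(store, datatype, value_id)
  require_right(store, role, "delete", row)
  DBI::dbExecute(store$con, sprintf(
    "UPDATE %s SET current = 0 WHERE value_id = ?", value_table(datatype)),
    params = list(value_id))
  invisible(NULL)
}

#' Update a fact as a role
#'
#' Requires an `update` grant covering the fact. The stored row is never
#' overwritten: a new version row replaces it in current results.
#'
#' @param store an `eav_store`.
#' @param role role name.
#' @param datatype,value_id fact reference.
#' @param new_lexical replacement lexical value (must be valid for the
#'   fact's datatype).
#' @return the new value id.
#' @export
update_value_as <- function(store, role, datatype, value_id, new_lexical) {
  row <- fetch_fact(store, datatype, value_id)
  require_right(store, role, "update", row)
  typed <- parse_lexical(new_lexical, datatype)
  if (is.logical(typed)) typed <- as.integer(typed)
  old <- DBI::dbGetQuery(store$con, sprintf(
    "SELECT entity_id, attribute_id, source_doc_id, metadata, version
     FROM %s WHERE value_id = ?", value_table(datatype)), params = list(value_id))
  DBI::dbExecute(store$con, sprintf(
    "UPDATE %s SET current = 0 WHERE value_id = ?", value_table(datatype)),
    params = list(value_id))
  DBI::dbExecute(store$con, sprintf(
    "INSERT INTO %s (entity_id, attribute_id, source_doc_id, lexical, typed,
                     metadata, version, current)
     VALUES (?, ?, ?, ?, ?, ?, ?, 1)", value_table(datatype)),
    params = list(old$entity_id, old$attribute_id, old$source_doc_id,
                  new_lexical, typed, old$metadata, old$version + 1L))
  DBI::dbGetQuery(store$con, "SELECT last_insert_rowid() AS id")$id[[1L]]
}

#' Add a fact as a role
#'
#' Requires an `add` grant whose fragment would contain the new fact.
#'
#' @param store an `eav_store`.
#' @param role role name.
#' @param fact a [value_fact()].
#' @return the new value id.
#' @export
add_value_as <- function(store, role, fact) {
  stopifnot(inherits(fact, "value_fact"))
  ep <- DBI::dbGetQuery(store$con,
    "SELECT path FROM entity_path WHERE entity_id = ?", params = list(fact$entity_id))
  if (!nrow(ep)) stop("unknown entity: ", fact$entity_id, call. = FALSE)
  doc <- source_docs(store, fact$source_doc_id)
  attr_name <- DBI::dbGetQuery(store$con,
    "SELECT name FROM attribute WHERE attribute_id = ?",
    params = list(fact$attribute_id))$name
  hypo <- data.frame(value_id = NA, datatype = fact$datatype,
                     entity_id = fact$entity_id, attribute_id = fact$attribute_id,
                     source_doc_id = fact$source_doc_id, path = ep$path[[1L]],
                     attribute = attr_name %||% NA_character_,
                     lexical = fact$lexical, metadata = fact$is_metadata,
                     author = doc$author[[1L]], doc_type = doc$doc_type[[1L]],
                     received_at = doc$received_at[[1L]])
  require_right(store, role, "add", hypo)
  insert_value(store, fact)
}
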