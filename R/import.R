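# Import pipeline: extract the XML report, transform it to EAV records,
# load them atomically. The mapping rules:
#   * every element occurrence -> one entity row;
#   * every non-whitespace text node -> one "#text" pseudo-entity plus one
#     fact under the reserved attribute "#text";
#   * every XML attribute (namespace declarations included) -> one fact whose
#     attribute name is the (qualified) XML attribute name;
#   * sibling positions count ALL sibling nodes, elements and text alike,
#     1-based in document order;
#   * facts are flagged header (metadata) or body by position relative to
#     the configured body root (default: a component/structuredBody chain).
# Whitespace-only text nodes, comments and processing instructions carry no
# information in this dialect and are dropped (the canonical comparison used
# for round-trip checks applies the same rule).

#' Import configuration
#'
#' @param body_path character vector naming the descendant chain whose last
#'   element is the body root; facts strictly below it are body facts, all
#'   others are header (metadata) facts.
#' @return an `eav_import_config` list.
#' @export
eav_import_config <- function(body_path = c("component", "structuredBody")) {
  structure(list(body_path = body_path), class = "eav_import_config")
}

#' Parse raw bytes into a document tree
#'
#' @param raw document text (character scalar) or raw vector.
#' @return an `eav_doctree` wrapping the parsed tree and the source text.
#' @export
parse_document <- function(raw) {
  if (is.raw(raw)) raw <- rawToChar(raw)
  stopifnot(is.character(raw), length(raw) == 1L)
  doc <- tryCatch(
    xml2::read_xml(raw, options = c("NOBLANKS" = 0L)),
    error = function(e) {
      stop(errorCondition(paste0("malformed XML: ", conditionMessage(e)),
                          class = c("eav_parse_error", "error")))
    })
  structure(list(xml = doc, raw = raw), class = "eav_doctree")
}

# Qualified name of a node: xml2 reports real prefixes verbatim and invents
# d1, d2, ... for default namespaces; those synthetic prefixes are stripped so
# names keep their source form.
qualified_name <- function(node, ns, default_uris) {
  nm <- if (length(ns)) xml2::xml_name(node, ns) else xml2::xml_name(node)
  if (grepl("^d[0-9]+:", nm)) {
    pfx <- sub(":.*$", "", nm)
    uri <- unname(ns[pfx])
    if (!is.na(uri) && uri %in% default_uris) nm <- sub("^d[0-9]+:", "", nm)
  }
  nm
}

# Walk the parsed tree once, emitting entity and fact protorecords in
# document order (parent before child).
walk_doctree <- function(tree) {
  doc <- tree$xml
  ns <- tryCatch(xml2::xml_ns(doc), error = function(e) character(0))
  # URIs declared as a *default* namespace anywhere in the document.
  all_attr_sets <- lapply(xml2::xml_find_all(doc, "//*"), xml2::xml_attrs)
  default_uris <- unique(unlist(lapply(all_attr_sets, function(a) {
    unname(a[names(a) == "xmlns"])
  })))

  entities <- list()  # list of list(name, parent_idx, sibling_pos, path)
  facts <- list()     # list of list(entity_idx, attribute, lexical)

  add_entity <- function(name, parent_idx, sibling_pos, parent_path) {
    idx <- length(entities) + 1L
    path <- paste0(parent_path, "/", name, "[", sibling_pos, "]")
    entities[[idx]] <<- list(name = name, parent_idx = parent_idx,
                             sibling_pos = sibling_pos, path = path)
    idx
  }
  add_fact <- function(entity_idx, attribute, lexical) {
    facts[[length(facts) + 1L]] <<- list(entity_idx = entity_idx,
                                         attribute = attribute,
                                         lexical = lexical)
  }

  visit <- function(node, parent_idx, sibling_pos, parent_path) {
    name <- qualified_name(node, ns, default_uris)
    idx <- add_entity(name, parent_idx, sibling_pos, parent_path)
    attrs <- xml2::xml_attrs(node, ns)
    # xml2 lists namespace declarations among the attributes; their names
    # ("xmlns", "xmlns:p") are kept as ordinary attribute facts.
    for (i in seq_along(attrs)) {
      add_fact(idx, names(attrs)[[i]], unname(attrs[[i]]))
    }
    pos <- 0L
    for (child in xml2::xml_contents(node)) {
      type <- xml2::xml_type(child)
      if (type == "element") {
        pos <- pos + 1L
        visit(child, idx, pos, entities[[idx]]$path)
      } else if (type %in% c("text", "cdata")) {
        txt <- xml2::xml_text(child)
        if (grepl("[^[:space:]]", txt)) {
          pos <- pos + 1L
          tidx <- add_entity("#text", idx, pos, entities[[idx]]$path)
          add_fact(tidx, "#text", txt)
        }
      }
      # comments and processing instructions: dropped
    }
    idx
  }
  visit(xml2::xml_root(doc), NA_integer_, 1L, "")

  list(
    entities = data.frame(
      name = vapply(entities, `[[`, "", "name"),
      parent_idx = vapply(entities, `[[`, 1L, "parent_idx"),
      sibling_pos = vapply(entities, `[[`, 1L, "sibling_pos"),
      path = vapply(entities, `[[`, "", "path"),
      stringsAsFactors = FALSE),
    facts = if (length(facts)) data.frame(
      entity_idx = vapply(facts, `[[`, 1L, "entity_idx"),
      attribute = vapply(facts, `[[`, "", "attribute"),
      lexical = vapply(facts, `[[`, "", "lexical"),
      stringsAsFactors = FALSE)
    else data.frame(entity_idx = integer(0), attribute = character(0),
                    lexical = character(0), stringsAsFactors = FALSE)
  )
}

#' Classify a node path as header or body
#'
#' A fact is a body fact when its entity lies strictly below the body root,
#' the first element reached through the configured descendant chain
#' (default `component/structuredBody`, the structured-body region of a
#' CDA-style report). Everything else - including documents that have no body
#' root at all - is header metadata.
#'
#' @param node_path an entity path string.
#' @param config an [eav_import_config()].
#' @return `TRUE` if the fact is header metadata.
#' @export
classify_header_body <- function(node_path, config = eav_import_config()) {
  chain <- config$body_path
  if (!length(chain)) return(rep(TRUE, length(node_path)))
  re <- paste0(paste0("/", chain, "\\[[0-9]+\\]", collapse = ""), "/")
  !grepl(re, node_path)
}

#' Shred a parsed document into EAV protorecords
#'
#' @param tree an `eav_doctree` from [parse_document()].
#' @param config an [eav_import_config()].
#' @return an `eav_shred_batch`: `entities` (parent-before-child, with paths),
#'   `attribute_names`, and `facts` with inferred datatypes and header/body
#'   flags.
#' @export
shred_document <- function(tree, config = eav_import_config()) {
  stopifnot(inherits(tree, "eav_doctree"))
  w <- walk_doctree(tree)
  f <- w$facts
  if (nrow(f)) {
    f$datatype <- infer_datatype(f$lexical)
    f$is_metadata <- classify_header_body(w$entities$path[f$entity_idx], config)
  } else {
    f$datatype <- character(0)
    f$is_metadata <- logical(0)
  }
  structure(
    list(entities = w$entities,
         attribute_names = unique(f$attribute),
         facts = f),
    class = "eav_shred_batch")
}

#' Import one document into the store
#'
#' Runs extract (parse), transform (shred) and load in a single transaction:
#' a failed import leaves the store untouched. The raw text is retained for
#' restorability, and ancestor paths for the new entities are materialized.
#'
#' @param store an `eav_store`.
#' @param raw document text or raw vector.
#' @param author,doc_type,template,received_at provenance; `doc_type` defaults
#'   to the root element name and `template` to the root's `templateId`-like
#'   content when present.
#' @param on_duplicate `"reject"` (default) or `"version"`.
#' @param config an [eav_import_config()].
#' @return an `eav_import_report` with the load counts.
#' @export
import_document <- function(store, raw, author = NA_character_,
                            doc_type = NULL, template = NULL,
                            received_at = NULL,
                            on_duplicate = c("reject", "version"),
                            config = eav_import_config()) {
  on_duplicate <- match.arg(on_duplicate)
  if (is.raw(raw)) raw <- rawToChar(raw)
  tree <- parse_document(raw)          # fails before any state change
  batch <- shred_document(tree, config)
  ents <- batch$entities
  facts <- batch$facts

  if (is.null(doc_type)) doc_type <- ents$name[[1L]]
  if (is.null(template)) {
    tmpl_fact <- facts[grepl("/templateId\\[[0-9]+\\]$", ents$path[facts$entity_idx]) &
                         facts$attribute == "root", , drop = FALSE]
    template <- if (nrow(tmpl_fact)) tmpl_fact$lexical[[1L]] else "unknown"
  }

  con <- store$con
  n_attr_before <- DBI::dbGetQuery(con, "SELECT COUNT(*) AS n FROM attribute")$n
  report <- NULL
  DBI::dbWithTransaction(con, {
    doc_id <- register_source_doc(store, raw, author = author,
                                  doc_type = doc_type, template = template,
                                  received_at = received_at,
                                  on_duplicate = on_duplicate)
    base <- DBI::dbGetQuery(con,
      "SELECT COALESCE(MAX(entity_id), 0) AS m FROM entity")$m
    ids <- base + seq_len(nrow(ents))
    DBI::dbAppendTable(con, "entity", data.frame(
      entity_id = ids,
      name = ents$name,
      parent_id = ifelse(is.na(ents$parent_idx), NA, ids[ents$parent_idx]),
      sibling_pos = ents$sibling_pos))
    DBI::dbExecute(con,
      "UPDATE source_doc SET root_entity_id = ? WHERE source_doc_id = ?",
      params = list(ids[[1L]], doc_id))

    attr_ids <- integer(0)
    if (length(batch$attribute_names)) {
      attr_ids <- vapply(batch$attribute_names, function(a) upsert_attribute(store, a),
                         numeric(1L))
      names(attr_ids) <- batch$attribute_names
    }

    if (nrow(facts)) {
      facts$entity_id <- ids[facts$entity_idx]
      for (tg in unique(facts$datatype)) {
        sub <- facts[facts$datatype == tg, , drop = FALSE]
        typed <- lapply(sub$lexical, parse_lexical, tag = tg)
        typed <- vapply(typed, function(v) {
          if (is.logical(v)) as.numeric(v) else if (is.character(v)) NA_real_ else as.numeric(v)
        }, numeric(1L))
        df <- data.frame(
          entity_id = sub$entity_id,
          attribute_id = unname(attr_ids[sub$attribute]),
          source_doc_id = doc_id,
          lexical = sub$lexical,
          metadata = as.integer(sub$is_metadata))
        if (datatype_def(tg)$sql_type == "TEXT") {
          df$typed <- vapply(sub$lexical, function(x) as.character(parse_lexical(x, tg)), "")
        } else {
          df$typed <- typed
        }
        DBI::dbAppendTable(con, value_table(tg), df)
      }
    }

    materialize_paths(store, doc_id, ids[[1L]])

    n_attr_after <- DBI::dbGetQuery(con, "SELECT COUNT(*) AS n FROM attribute")$n
    report <- structure(list(
      source_doc_id = doc_id,
      n_entities = nrow(ents),
      n_new_attributes = n_attr_after - n_attr_before,
      n_values = nrow(facts),
      n_header_values = sum(facts$is_metadata),
      n_body_values = sum(!facts$is_metadata)
    ), class = "eav_import_report")
  })
  report
}

#' @export
print.eav_import_report <- function(x, ...) {
  cat("<import> doc ", x$source_doc_id, ": ", x$n_entities, " entities, ",
      x$n_values, " values (", x$n_header_values, " header / ",
      x$n_body_values, " body), ", x$n_new_attributes, " new attributes\n",
      sep = "")
  invisible(x)
}

# Materialize ancestor paths for one document via a recursive CTE from its
# root downward (the stored-path cache behind path-returning queries).
materialize_paths <- function(store, doc_id, root_entity_id) {
  DBI::dbExecute(store$con,
    "DELETE FROM entity_path WHERE source_doc_id = ?", params = list(doc_id))
  DBI::dbExecute(store$con, sprintf(
    "WITH RECURSIVE p(entity_id, path) AS (
       SELECT entity_id, '/' || name || '[' || sibling_pos || ']'
       FROM entity WHERE entity_id = %d
       UNION ALL
       SELECT e.entity_id, p.path || '/' || e.name || '[' || e.sibling_pos || ']'
       FROM entity e JOIN p ON e.parent_id = p.entity_id)
     INSERT INTO entity_path(entity_id, source_doc_id, path)
     SELECT entity_id, %d, path FROM p", root_entity_id, doc_id))
}
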