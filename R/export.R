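# Export side of the engine:
#   * reconstruct_document - rebuild an imported report purely from EAV rows
#     (restorability);
#   * canonical_xml - the operational meaning of "no data is lost": a
#     deterministic serialization that ignores attribute order,
#     whitespace-only text, comments and processing instructions;
#   * the five-subtask export loop: preselect -> select -> transform via
#     rules -> completeness check -> generate, repeated until the target
#     document is complete.

# ---------------------------------------------------------------- reconstruct

serialize_entity_tree <- function(nodes, facts_by_entity, id) {
  node <- nodes[[as.character(id)]]
  facts <- facts_by_entity[[as.character(id)]]
  if (node$name == "#text") {
    return(xml_escape_text(facts$lexical[facts$attribute == "#text"][[1L]]))
  }
  attrs <- ""
  if (!is.null(facts) && nrow(facts)) {
    af <- facts[facts$attribute != "#text", , drop = FALSE]
    af <- af[order(af$value_id), , drop = FALSE]  # original attribute order
    if (nrow(af)) {
      attrs <- paste0(" ", af$attribute, "=\"", xml_escape_attr(af$lexical), "\"",
                      collapse = "")
    }
  }
  kids <- node$children
  if (!length(kids)) {
    return(paste0("<", node$name, attrs, "/>"))
  }
  inner <- vapply(kids, function(k) serialize_entity_tree(nodes, facts_by_entity, k),
                  character(1L))
  paste0("<", node$name, attrs, ">", paste0(inner, collapse = ""),
         "</", node$name, ">")
}

#' Reconstruct an imported document from its EAV rows
#'
#' Rebuilds the XML purely from the entity, attribute and value relations:
#' children ordered by sibling position, attribute facts re-attached, text
#' pseudo-entities emitted in place, and every value emitted in its verbatim
#' lexical form (an attribute imported as `"042"` comes back as `"042"`).
#' The canonical form of the result equals the canonical form of the
#' original input.
#'
#' @param store an `eav_store`.
#' @param source_doc_id an imported document id.
#' @return the reconstructed XML as a character scalar.
#' @export
reconstruct_document <- function(store, source_doc_id) {
  meta <- source_docs(store, source_doc_id)
  if (!nrow(meta)) stop("unknown source document: ", source_doc_id, call. = FALSE)
  root <- meta$root_entity_id[[1L]]
  ents <- DBI::dbGetQuery(store$con,
    "SELECT e.entity_id, e.name, e.parent_id, e.sibling_pos
     FROM entity e JOIN entity_path p ON p.entity_id = e.entity_id
     WHERE p.source_doc_id = ?
     ORDER BY e.parent_id, e.sibling_pos", params = list(source_doc_id))
  nodes <- lapply(seq_len(nrow(ents)), function(i) {
    list(name = ents$name[[i]], children = integer(0))
  })
  names(nodes) <- as.character(ents$entity_id)
  for (i in seq_len(nrow(ents))) {
    p <- ents$parent_id[[i]]
    if (!is.na(p)) {
      k <- as.character(p)
      nodes[[k]]$children <- c(nodes[[k]]$children, ents$entity_id[[i]])
    }
  }
  vals <- DBI::dbGetQuery(store$con, sprintf(
    "SELECT v.value_id, v.entity_id, a.name AS attribute, v.lexical
     FROM (%s) v JOIN attribute a ON a.attribute_id = v.attribute_id
     WHERE v.source_doc_id = %d ORDER BY v.entity_id, v.value_id",
    value_union_sql(store), as.integer(source_doc_id)))
  facts_by_entity <- split(vals, as.character(vals$entity_id))
  paste0("<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
         serialize_entity_tree(nodes, facts_by_entity, root))
}

# ------------------------------------------------------------- canonical form

canon_node <- function(node, ns, default_uris) {
  name <- qualified_name(node, ns, default_uris)
  attrs <- xml2::xml_attrs(node, ns)
  attrs <- attrs[order(names(attrs))]
  astr <- if (length(attrs)) {
    paste0(" ", names(attrs), "=\"", xml_escape_attr(unname(attrs)), "\"",
           collapse = "")
  } else ""
  parts <- character(0)
  for (child in xml2::xml_contents(node)) {
    type <- xml2::xml_type(child)
    if (type == "element") {
      parts <- c(parts, canon_node(child, ns, default_uris))
    } else if (type %in% c("text", "cdata")) {
      txt <- xml2::xml_text(child)
      if (grepl("[^[:space:]]", txt)) parts <- c(parts, xml_escape_text(txt))
    }
  }
  if (!length(parts)) paste0("<", name, astr, "/>")
  else paste0("<", name, astr, ">", paste0(parts, collapse = ""), "</", name, ">")
}

#' Canonical serialization of an XML document
#'
#' The equality notion used for round-trip checks: attribute order, an XML
#' declaration, whitespace-only text nodes, comments and processing
#' instructions are all ignored; text is compared decoded; namespace
#' declarations and qualified names are kept.
#'
#' @param x XML text (character), raw vector, or an `eav_doctree`.
#' @return canonical serialization as a character scalar.
#' @export
canonical_xml <- function(x) {
  tree <- if (inherits(x, "eav_doctree")) x else parse_document(x)
  doc <- tree$xml
  ns <- tryCatch(xml2::xml_ns(doc), error = function(e) character(0))
  all_attr_sets <- lapply(xml2::xml_find_all(doc, "//*"), xml2::xml_attrs)
  default_uris <- unique(unlist(lapply(all_attr_sets, function(a) {
    unname(a[names(a) == "xmlns"])
  })))
  canon_node(xml2::xml_root(doc), ns, default_uris)
}

# ----------------------------------------------------------------- preselect

#' Preselect facts for export
#'
#' First subtask of the export loop: gather every stored fact matching the
#' criteria. The final (manual) selection is a subset of this preselection.
#'
#' @param store an `eav_store`.
#' @param criteria a list with any of: `doc_ids` (document ids),
#'   `received_from`/`received_to` (inclusive bounds on the receipt
#'   timestamp), `metadata` (`TRUE` header-only, `FALSE` body-only),
#'   `path_patterns` (prefix path patterns), `attributes` (attribute names).
#' @return an `eav_selection` data.frame of fact references (possibly empty).
#' @export
preselect <- function(store, criteria = list()) {
  df <- fact_frame(store, doc_ids = criteria$doc_ids)
  keep <- rep(TRUE, nrow(df))
  if (!is.null(criteria$received_from)) keep <- keep & df$received_at >= criteria$received_from
  if (!is.null(criteria$received_to)) keep <- keep & df$received_at <= criteria$received_to
  if (!is.null(criteria$metadata)) keep <- keep & (df$metadata == criteria$metadata)
  if (!is.null(criteria$path_patterns)) {
    keep <- keep & paths_match_any(criteria$path_patterns, df$path, mode = "prefix")
  }
  if (!is.null(criteria$attributes)) keep <- keep & df$attribute %in% criteria$attributes
  sel <- df[keep, , drop = FALSE]
  rownames(sel) <- NULL
  class(sel) <- c("eav_selection", "data.frame")
  sel
}

# ------------------------------------------------------------- rule language

.eav_runtime$transforms <- list(
  identity = function(x) x,
  uppercase = function(x) toupper(x),
  # ISO 8601 date -> German day.month.year
  date_de = function(x) {
    d <- as.Date(x, format = "%Y-%m-%d")
    ifelse(is.na(d), x, format(d, "%d.%m.%Y"))
  }
)

#' Register a named value transform
#'
#' Transforms are total functions on lexical strings, referenced by name from
#' transformation rules. Built-ins: `identity`, `uppercase`, `date_de`
#' (ISO date to day.month.year). `make_code_lookup()` builds a code-table
#' transform.
#'
#' @param name transform name.
#' @param fn function taking and returning a character vector.
#' @export
register_transform <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  .eav_runtime$transforms[[name]] <- fn
  invisible(name)
}

#' Build a code-table lookup transform
#' @param table named character vector mapping source codes to target codes.
#' @param default value for unmapped codes (default: keep the source code).
#' @return a transform function suitable for [register_transform()].
#' @export
make_code_lookup <- function(table, default = NULL) {
  force(table); force(default)
  function(x) {
    hit <- table[x]
    miss <- is.na(hit)
    hit[miss] <- if (is.null(default)) x[miss] else default
    unname(hit)
  }
}

#' Define a transformation rule
#'
#' Maps facts whose entity path (and attribute) match `source_pattern` to a
#' slot in the target document. Patterns use `*` for a name segment and `[*]`
#' for any position; an attribute part is written `/@name` (text content is
#' the reserved attribute `#text`). The target path is a template: each `*`
#' or `[*]` in it is instantiated with the corresponding wildcard match from
#' the source, in order.
#'
#' @param source_pattern fact pattern over stored entity paths.
#' @param target_path slot template in the target document, ending in
#'   `/@name` for an attribute slot or `/#text` for text content.
#' @param transform name of a registered value transform (default
#'   `"identity"`).
#' @param required marks the rule as one whose target must be populated.
#' @return an `eav_transform_rule`.
#' @export
transform_rule <- function(source_pattern, target_path,
                           transform = "identity", required = FALSE) {
  if (is.null(.eav_runtime$transforms[[transform]])) {
    stop("unregistered value transform: ", transform, call. = FALSE)
  }
  sp <- split_fact_pattern(source_pattern)
  parse_pattern_segments(sp$path)  # validate syntax
  tgt <- parse_target_path(target_path)
  structure(list(source_pattern = source_pattern, target_path = target_path,
                 transform = transform, required = isTRUE(required),
                 .source = sp, .target = tgt),
            class = "eav_transform_rule")
}

# A target template splits into an element path part and a slot kind:
# ".../@name" (attribute) or ".../#text" (text content).
parse_target_path <- function(target_path) {
  if (grepl("/@", target_path, fixed = TRUE)) {
    sp <- split_fact_pattern(target_path)
    list(path = sp$path, kind = "attr", attr = sp$attr)
  } else if (grepl("/#text$", target_path)) {
    list(path = sub("/#text$", "", target_path), kind = "text", attr = "#text")
  } else {
    stop("target path must end in /@name or /#text: ", target_path, call. = FALSE)
  }
}

# Instantiate a target template with wildcard captures from the source match.
instantiate_target <- function(tgt, wild_names, wild_pos) {
  segs <- parse_pattern_segments(tgt$path)
  ni <- 0L; pi <- 0L
  out <- vapply(segs, function(s) {
    nm <- s$name
    if (nm == "*") {
      ni <<- ni + 1L
      if (ni > length(wild_names)) stop("target has more name wildcards than source", call. = FALSE)
      nm <- wild_names[[ni]]
    }
    pos <- s$pos
    if (pos == "*") {
      pi <<- pi + 1L
      pos <- if (pi <= length(wild_pos)) wild_pos[[pi]] else 1L
    }
    paste0(nm, "[", pos, "]")
  }, character(1L))
  paste0("/", paste(out, collapse = "/"))
}

#' Apply transformation rules to a selection
#'
#' Third subtask of the export loop. Every selected fact matching a rule's
#' source pattern has its (transformed) value placed at the instantiated
#' target slot; selected facts matched by no rule are skipped with a notice
#' (message). Two rules writing different values to one slot is an error
#' naming both rules.
#'
#' @param selection an `eav_selection` from [preselect()].
#' @param rules list of [transform_rule()]s.
#' @param store an `eav_store` (reserved for transforms needing store
#'   context; unused by the built-ins).
#' @param quiet suppress the unmatched-fact notice.
#' @return an `eav_target_tree` holding the populated slots.
#' @export
apply_rules <- function(selection, rules, store = NULL, quiet = FALSE) {
  stopifnot(inherits(selection, "eav_selection"))
  for (r in rules) stopifnot(inherits(r, "eav_transform_rule"))
  slots <- list()
  unmatched <- 0L
  if (nrow(selection)) {
    for (i in seq_len(nrow(selection))) {
      path <- selection$path[[i]]
      attribute <- selection$attribute[[i]]
      hit <- FALSE
      for (ri in seq_along(rules)) {
        r <- rules[[ri]]
        if (r$.source$attr != "*" && r$.source$attr != attribute) next
        m <- path_pattern_match(r$.source$path, path, mode = "exact")
        if (!isTRUE(m)) next
        hit <- TRUE
        tpath <- instantiate_target(r$.target, attr(m, "wild_names"), attr(m, "wild_pos"))
        key <- paste0(tpath, if (r$.target$kind == "attr") paste0("/@", r$.target$attr) else "/#text")
        val <- .eav_runtime$transforms[[r$transform]](selection$lexical[[i]])
        if (!is.null(slots[[key]])) {
          if (!identical(slots[[key]]$value, val)) {
            stop("rule conflict at target slot ", key, ": rule #",
                 slots[[key]]$rule, " (", rules[[slots[[key]]$rule]]$source_pattern,
                 ") vs rule #", ri, " (", r$source_pattern, ")", call. = FALSE)
          }
        } else {
          slots[[key]] <- list(value = val, rule = ri, path = tpath,
                               kind = r$.target$kind, attr = r$.target$attr)
        }
      }
      if (!hit) unmatched <- unmatched + 1L
    }
  }
  if (unmatched > 0L && !quiet) {
    message("apply_rules: ", unmatched, " selected fact(s) matched no rule and were skipped")
  }
  structure(list(slots = slots), class = "eav_target_tree")
}

#' Completeness specification for a target format
#'
#' @param required_paths character vector of slot patterns that must be
#'   populated before the target document may be generated.
#' @param root expected root element name, or `NULL` to skip the check.
#' @return an `eav_completeness_spec`.
#' @export
completeness_spec <- function(required_paths = character(0), root = NULL) {
  structure(list(required_paths = required_paths, root = root),
            class = "eav_completeness_spec")
}

#' Check a target tree for completeness
#'
#' Returns exactly the required slot patterns not yet populated (an empty
#' vector means the document is complete and structurally valid). A root-name
#' mismatch or an empty tree with requirements is reported via the
#' `"problems"` attribute.
#'
#' @param tree an `eav_target_tree`.
#' @param spec an [completeness_spec()].
#' @return character vector of missing patterns (with a `problems`
#'   attribute).
#' @export
check_completeness <- function(tree, spec) {
  stopifnot(inherits(tree, "eav_target_tree"), inherits(spec, "eav_completeness_spec"))
  keys <- names(tree$slots)
  missing <- character(0)
  for (pat in spec$required_paths) {
    pp <- if (grepl("/@", pat, fixed = TRUE) || grepl("/#text$", pat)) pat else paste0(pat, "/#text")
    tgt <- parse_target_path(pp)
    found <- any(vapply(keys, function(k) {
      kt <- parse_target_path(k)
      kt$kind == tgt$kind &&
        (tgt$attr == "*" || kt$attr == tgt$attr) &&
        isTRUE(path_pattern_match(tgt$path, kt$path, mode = "exact"))
    }, logical(1L)))
    if (!found) missing <- c(missing, pat)
  }
  problems <- character(0)
  if (!is.null(spec$root) && length(keys)) {
    roots <- unique(vapply(keys, function(k) {
      path_segments(parse_target_path(k)$path)$name[[1L]]
    }, character(1L)))
    if (length(roots) > 1L) {
      problems <- c(problems, paste0("multiple root elements: ", paste(roots, collapse = ", ")))
    } else if (!identical(roots, spec$root)) {
      problems <- c(problems, paste0("root element is '", roots, "', expected '", spec$root, "'"))
    }
  }
  structure(missing, problems = problems)
}

# --------------------------------------------------------------- generation

#' Serialize a target tree to XML
#'
#' @param tree an `eav_target_tree` with at least one populated slot.
#' @return XML text.
#' @export
generate_target <- function(tree) {
  stopifnot(inherits(tree, "eav_target_tree"))
  if (!length(tree$slots)) stop("target tree is empty", call. = FALSE)
  # Build a nested node map keyed by element path.
  nodes <- new.env(parent = emptyenv())
  ensure_node <- function(path) {
    if (is.null(nodes[[path]])) {
      seg <- path_segments(path)
      nodes[[path]] <- list(name = seg$name[[nrow(seg)]], pos = seg$pos[[nrow(seg)]],
                            attrs = character(0), text = NULL, children = character(0))
      if (nrow(seg) > 1L) {
        parent <- make_path(seg$name[-nrow(seg)], seg$pos[-nrow(seg)])
        ensure_node(parent)
        nodes[[parent]]$children <- union(nodes[[parent]]$children, path)
      }
    }
    path
  }
  for (slot in tree$slots) {
    p <- ensure_node(slot$path)
    if (slot$kind == "attr") {
      a <- nodes[[p]]$attrs
      a[slot$attr] <- slot$value
      nodes[[p]]$attrs <- a
    } else {
      nodes[[p]]$text <- slot$value
    }
  }
  roots <- Filter(function(p) nrow(path_segments(p)) == 1L, ls(nodes))
  if (length(roots) != 1L) {
    stop("target tree must have exactly one root, found: ",
         paste(roots, collapse = ", "), call. = FALSE)
  }
  emit <- function(path) {
    nd <- nodes[[path]]
    attrs <- nd$attrs
    if (length(attrs)) attrs <- attrs[order(names(attrs))]
    astr <- if (length(attrs)) {
      paste0(" ", names(attrs), "=\"", xml_escape_attr(unname(attrs)), "\"", collapse = "")
    } else ""
    kids <- nd$children
    if (length(kids)) {
      pos <- vapply(kids, function(k) nodes[[k]]$pos, numeric(1L))
      kids <- kids[order(pos)]
    }
    inner <- paste0(
      if (!is.null(nd$text)) xml_escape_text(nd$text) else "",
      paste0(vapply(kids, emit, character(1L)), collapse = ""))
    if (!nzchar(inner)) paste0("<", nd$name, astr, "/>")
    else paste0("<", nd$name, astr, ">", inner, "</", nd$name, ">")
  }
  paste0("<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n", emit(roots))
}

# ---------------------------------------------------------------- export loop

#' Run the full export loop
#'
#' Iterates preselect, (scripted) selection, rule transformation and the
#' completeness check until the check reports nothing missing, then generates
#' the target document. The manual selection step is modeled as the
#' `selector` callback: `selector(selection, missing)` returns the refined
#' selection for the next pass (it is clamped to the preselection). The
#' default selector keeps the whole preselection.
#'
#' @param store an `eav_store`.
#' @param criteria preselection criteria (see [preselect()]).
#' @param rules list of [transform_rule()]s.
#' @param spec an [completeness_spec()].
#' @param selector callback `function(selection, missing)`; `missing` is
#'   `NULL` on the first pass.
#' @param max_iterations bound on loop passes.
#' @param quiet passed to [apply_rules()].
#' @return an `eav_export`: list with `document` (XML text), `iterations`,
#'   and the final `tree`.
#' @export
export_document <- function(store, criteria, rules, spec,
                            selector = NULL, max_iterations = 20L,
                            quiet = TRUE) {
  pre <- preselect(store, criteria)
  selector <- selector %||% function(selection, missing) selection
  missing <- NULL
  sel <- pre
  fact_key <- function(df) paste(df$datatype, df$value_id)
  for (it in seq_len(max_iterations)) {
    sel <- selector(sel, missing)
    stopifnot(is.data.frame(sel))
    # the selection is always a subset of the preselection
    sel <- pre[fact_key(pre) %in% fact_key(sel), , drop = FALSE]
    class(sel) <- c("eav_selection", "data.frame")
    tree <- apply_rules(sel, rules, store, quiet = quiet)
    missing <- check_completeness(tree, spec)
    if (!length(missing) && !length(attr(missing, "problems"))) {
      return(structure(list(document = generate_target(tree),
                            iterations = it, tree = tree),
                       class = "eav_export"))
    }
  }
  stop(errorCondition(
    paste0("export incomplete after ", max_iterations, " iteration(s); missing: ",
           paste(missing, collapse = ", ")),
    class = c("eav_export_incomplete", "error"),
    missing = as.character(missing)))
}

#' @export
print.eav_export <- function(x, ...) {
  cat("<eav_export> complete after ", x$iterations, " iteration(s), ",
      length(x$tree$slots), " slot(s)\n", sep = "")
  invisible(x)
}

# ------------------------------------------------------------- config files

#' Read transformation rules from a JSON file
#'
#' The file holds an array of objects with fields `source`, `target`,
#' optional `transform` and `required`.
#'
#' @param path file path.
#' @return list of [transform_rule()]s.
#' @export
read_rules_file <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(spec, function(r) {
    transform_rule(r$source, r$target,
                   transform = r$transform %||% "identity",
                   required = isTRUE(r$required))
  })
}

#' Read a completeness specification from a JSON file
#'
#' The file holds an object with fields `required_paths` (array) and
#' optional `root`.
#'
#' @param path file path.
#' @return an [completeness_spec()].
#' @export
read_completeness_file <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  completeness_spec(required_paths = unlist(spec$required_paths) %||% character(0),
                    root = spec$root)
}
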