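# Independent single-pass XML walk used as the oracle for conservation and
# query-equivalence checks. It never touches the store: it re-derives, from
# the raw document text alone, the set of (path, attribute, lexical) facts
# and the node counts that a lossless shredding must produce.

oracle_walk <- function(xml_text) {
  doc <- xml2::read_xml(xml_text)
  n_elements <- 0L
  n_texts <- 0L
  n_attrs <- 0L
  entity_paths <- character(0)
  facts <- list()

  descend <- function(node, path) {
    n_elements <<- n_elements + 1L
    entity_paths <<- c(entity_paths, path)
    ats <- xml2::xml_attrs(node)
    n_attrs <<- n_attrs + length(ats)
    for (k in seq_along(ats)) {
      facts[[length(facts) + 1L]] <<-
        c(path = path, attribute = names(ats)[[k]], lexical = unname(ats[[k]]))
    }
    pos <- 0L
    for (ch in xml2::xml_contents(node)) {
      ty <- xml2::xml_type(ch)
      if (ty == "element") {
        pos <- pos + 1L
        descend(ch, paste0(path, "/", xml2::xml_name(ch), "[", pos, "]"))
      } else if (ty %in% c("text", "cdata")) {
        tx <- xml2::xml_text(ch)
        if (grepl("[^[:space:]]", tx)) {
          pos <- pos + 1L
          n_texts <<- n_texts + 1L
          tpath <- paste0(path, "/#text[", pos, "]")
          entity_paths <<- c(entity_paths, tpath)
          facts[[length(facts) + 1L]] <<-
            c(path = tpath, attribute = "#text", lexical = tx)
        }
      }
    }
  }
  root <- xml2::xml_root(doc)
  descend(root, paste0("/", xml2::xml_name(root), "[1]"))

  facts_df <- if (length(facts)) {
    as.data.frame(do.call(rbind, facts), stringsAsFactors = FALSE)
  } else {
    data.frame(path = character(0), attribute = character(0),
               lexical = character(0))
  }
  list(n_elements = n_elements, n_texts = n_texts, n_attrs = n_attrs,
       entity_paths = entity_paths, facts = facts_df)
}

# Import every document of a generated corpus into a fresh in-memory store.
import_corpus <- function(corpus, received_at = "2013-02-04 10:00:00") {
  store <- eav_open(":memory:")
  ids <- integer(0)
  for (i in seq_along(corpus$docs)) {
    rep <- import_document(store, corpus$docs[[i]], author = "Nurse A",
                           received_at = received_at)
    ids <- c(ids, rep$source_doc_id)
  }
  attr(store, "doc_ids") <- ids
  store
}

# Canonical multiset key for tuple comparisons.
tuple_keys <- function(df, doc = df$source_doc_id, path = df$entity_path,
                       attribute = df$attribute, value = df$value) {
  sort(paste(doc, path, attribute, value, sep = "\r"))
}
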