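# Synthetic corpus generator: seeded CDA-like nursing transition reports
# (header with document/patient/author metadata; body with five main care
# sections, subsections nested to a configurable depth, sparse optional
# fields, and optionally planted search terms), together with a ground-truth
# manifest recording every fact the document carries. The manifest is built
# during construction, independently of the import machinery, and serves as
# the oracle for conservation, query and fragment checks.

.gen_sections <- c("Nursing Process", "Social Information", "Home Care Status",
                   "Reference to Legal Documents", "Medical Information")

.gen_vocab <- c(
  "mobilisation", "dekubitusprophylaxe", "wundversorgung", "vitalzeichen",
  "blutdruckkontrolle", "koerperpflege", "ernaehrungsplan", "fluessigkeitsbilanz",
  "sturzrisiko", "schmerzskala", "betreuungsbedarf", "hausnotruf",
  "angehoerigengespraech", "verbandwechsel", "injektionsschema", "salbenauftrag",
  "lagerungswechsel", "inkontinenzversorgung", "thromboseprophylaxe", "pflegeplanung")

.gen_given <- c("Anna", "Karl", "Maria", "Peter", "Ilse", "Hans", "Greta", "Otto")
.gen_family <- c("Schmidt", "Meyer", "Fischer", "Weber", "Wagner", "Becker",
                 "Hoffmann", "Schulz")
.gen_orgs <- c("Pflegedienst Nord", "Sozialstation Mitte", "Hauskrankenpflege Sued")

#' Parameters for the synthetic corpus generator
#'
#' @param seed integer seed; the corpus is a deterministic function of the
#'   parameters.
#' @param n_docs number of documents.
#' @param sections names of the main body sections (default: the five main
#'   sections of a nursing transition report).
#' @param max_depth nesting depth of subsections within each main section
#'   (default 4).
#' @param fields_per_section number of optional fields per main section,
#'   distributed over the nesting levels.
#' @param fill_rate probability in (0, 1] that an optional field is present.
#' @param planted_terms named integer vector: each term is planted into
#'   exactly that many documents (e.g. `c(hemoglobin = 9)`).
#' @param plant_in_header plant terms into a header field instead of a body
#'   text node.
#' @return a `gen_params` list.
#' @export
gen_params <- function(seed = 1L, n_docs = 10L, sections = .gen_sections,
                       max_depth = 4L, fields_per_section = 8L,
                       fill_rate = 0.7, planted_terms = integer(0),
                       plant_in_header = FALSE) {
  stopifnot(n_docs >= 0L, max_depth >= 1L, fields_per_section >= 0L,
            fill_rate > 0, fill_rate <= 1)
  planted_terms <- unlist(planted_terms)
  if (length(planted_terms)) {
    stopifnot(!is.null(names(planted_terms)), all(nzchar(names(planted_terms))))
    if (any(planted_terms > n_docs)) {
      stop("cannot plant a term in more documents than the corpus holds", call. = FALSE)
    }
    if (!all(grepl("^[A-Za-z]+$", names(planted_terms)))) {
      stop("planted terms must be purely alphabetic", call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), n_docs = as.integer(n_docs),
                 sections = sections, max_depth = as.integer(max_depth),
                 fields_per_section = as.integer(fields_per_section),
                 fill_rate = fill_rate, planted_terms = planted_terms,
                 plant_in_header = isTRUE(plant_in_header)),
            class = "gen_params")
}

# Wordlists with any entry containing a planted term removed, so planted
# counts stay exact.
safe_pool <- function(pool, terms) {
  if (!length(terms)) return(pool)
  keep <- !vapply(pool, function(w) {
    any(vapply(terms, function(t) grepl(t, w, ignore.case = TRUE), logical(1L)))
  }, logical(1L))
  out <- pool[keep]
  if (!length(out)) stop("planted terms eliminate an entire wordlist", call. = FALSE)
  out
}

# --- tiny document model used only by the generator ------------------------
g_el <- function(name, attrs = character(0), children = list()) {
  list(kind = "el", name = name, attrs = attrs, children = children)
}
g_tx <- function(text) list(kind = "tx", text = text)

# Serialize the model and record the manifest in one pass. Elements whose
# children include a text node are emitted compactly; all others are
# pretty-printed, which creates whitespace-only text nodes the importer must
# ignore.
gen_serialize <- function(node, rec, parent_path = "", sibling_pos = 1L,
                          depth = 0L, region = "header", section = NA_character_) {
  ind <- strrep("  ", depth)
  if (node$kind == "tx") {
    rec$texts <- rec$texts + 1L
    path <- paste0(parent_path, "/#text[", sibling_pos, "]")
    rec$facts[[length(rec$facts) + 1L]] <- list(
      path = path, attribute = "#text", lexical = node$text,
      metadata = region == "header", section = section)
    return(xml_escape_text(node$text))
  }
  rec$elements <- rec$elements + 1L
  path <- paste0(parent_path, "/", node$name, "[", sibling_pos, "]")
  astr <- ""
  if (length(node$attrs)) {
    rec$attrs <- rec$attrs + length(node$attrs)
    for (i in seq_along(node$attrs)) {
      rec$facts[[length(rec$facts) + 1L]] <- list(
        path = path, attribute = names(node$attrs)[[i]],
        lexical = unname(node$attrs[[i]]),
        metadata = region == "header", section = section)
    }
    astr <- paste0(" ", names(node$attrs), "=\"",
                   xml_escape_attr(unname(node$attrs)), "\"", collapse = "")
  }
  if (!length(node$children)) return(paste0("<", node$name, astr, "/>"))
  has_text <- any(vapply(node$children, function(c) c$kind == "tx", logical(1L)))
  parts <- character(length(node$children))
  for (i in seq_along(node$children)) {
    parts[[i]] <- gen_serialize(node$children[[i]], rec, path, i, depth + 1L,
                                region, section)
  }
  if (has_text) {
    paste0("<", node$name, astr, ">", paste0(parts, collapse = ""),
           "</", node$name, ">")
  } else {
    paste0("<", node$name, astr, ">\n",
           paste0(ind, "  ", parts, collapse = "\n"),
           "\n", ind, "</", node$name, ">")
  }
}

gen_field_value <- function(j, vocab) {
  switch((j %% 6L) + 1L,
    as.character(sample(0:200, 1L)),                          # integer
    sprintf("%.1f", stats::runif(1L, 30, 40)),                # real
    sample(c("true", "false"), 1L),                           # boolean
    format(as.Date("2012-01-01") + sample(0:365, 1L)),        # date
    paste0(format(as.Date("2012-01-01") + sample(0:365, 1L)), # timestamp
           "T", sprintf("%02d:%02d:00", sample(6:20, 1L), sample(0:59, 1L))),
    paste(sample(vocab, 2L), collapse = " "))                 # string
}

# One main section: a chain of nested <section> elements, fields distributed
# round-robin over the levels, each present with probability fill_rate.
gen_section <- function(params, vocab, extra_children = list()) {
  levels <- vector("list", params$max_depth)
  for (j in seq_len(params$fields_per_section)) {
    if (stats::runif(1L) > params$fill_rate) next
    lvl <- ((j - 1L) %% params$max_depth) + 1L
    lex <- gen_field_value(j, vocab)
    field <- if (j %% 2L == 0L) {
      g_el("observation", attrs = c(value = lex))
    } else {
      g_el("content", children = list(g_tx(lex)))
    }
    levels[[lvl]] <- c(levels[[lvl]], list(field))
  }
  node <- NULL
  for (lvl in rev(seq_len(params$max_depth))) {
    kids <- levels[[lvl]] %||% list()
    if (!is.null(node)) kids <- c(kids, list(node))
    if (lvl > 1L) {
      node <- g_el("section", children = kids)
    } else {
      node <- g_el("section", children = c(extra_children, kids))
    }
  }
  node
}

#' Generate one synthetic document
#'
#' @param params a [gen_params()].
#' @param doc_index 1-based index of the document in the corpus.
#' @param planted character vector of terms to plant into this document.
#' @return list with `xml` (document text) and `manifest` (per-document
#'   ground truth: counts and the full fact table).
#' @export
generate_document <- function(params, doc_index, planted = character(0)) {
  stopifnot(inherits(params, "gen_params"))
  terms <- names(params$planted_terms)
  vocab <- safe_pool(.gen_vocab, terms)
  givens <- safe_pool(.gen_given, terms)
  familys <- safe_pool(.gen_family, terms)
  orgs <- safe_pool(.gen_orgs, terms)
  statics <- c("Pflegebericht zur Ueberleitung", "care note:", "DE",
               "urn:hl7-org:v3")
  for (t in terms) {
    if (any(grepl(t, statics, ignore.case = TRUE))) {
      stop("planted term '", t, "' collides with fixed document text", call. = FALSE)
    }
  }

  with_local_seed((params$seed %% 100000L) * 20011 + doc_index, {
    eff_date <- as.Date("2012-01-01") + sample(0:365, 1L)
    eff <- paste0(format(eff_date), "T",
                  sprintf("%02d:%02d:00", sample(6:20, 1L), sample(0:59, 1L)))
    header <- list(
      g_el("realmCode", c(code = "DE")),
      g_el("typeId", c(root = "2.16.840.1.113883.1.3", extension = "POCD_HD000040")),
      g_el("templateId", c(root = "1.2.276.0.76.10.1019")),
      g_el("id", c(root = "1.2.276.0.76.4711",
                   extension = sprintf("doc-%04d", doc_index))),
      g_el("code", c(code = "34133-9", codeSystem = "2.16.840.1.113883.6.1")),
      g_el("title", children = list(g_tx("Pflegebericht zur Ueberleitung"))),
      g_el("effectiveTime", c(value = eff)),
      g_el("recordTarget", children = list(
        g_el("patientRole", children = list(
          g_el("id", c(extension = sprintf("pid-%03d", sample(1:999, 1L)))),
          g_el("patient", children = list(
            g_el("name", children = list(
              g_el("given", children = list(g_tx(sample(givens, 1L)))),
              g_el("family", children = list(g_tx(sample(familys, 1L)))))),
            g_el("administrativeGenderCode", c(code = sample(c("M", "F"), 1L))),
            g_el("birthTime", c(value = format(as.Date("1930-01-01") +
                                                 sample(0:10000, 1L)))))))))),
      g_el("author", children = list(
        g_el("time", c(value = eff)),
        g_el("assignedAuthor", children = list(
          g_el("id", c(extension = sprintf("aut-%03d", sample(1:999, 1L)))),
          g_el("assignedPerson", children = list(
            g_el("name", children = list(
              g_el("given", children = list(g_tx(sample(givens, 1L)))),
              g_el("family", children = list(g_tx(sample(familys, 1L)))))))))))),
      g_el("custodian", children = list(
        g_el("assignedCustodian", children = list(
          g_el("representedOrganization", children = list(
            g_el("name", children = list(g_tx(sample(orgs, 1L))))))))))
    )
    if (length(planted) && params$plant_in_header) {
      header <- c(header, lapply(planted, function(t) {
        g_el("title", children = list(g_tx(paste("care note:", t))))
      }))
    }

    rec <- new.env(parent = emptyenv())
    rec$elements <- 0L; rec$texts <- 0L; rec$attrs <- 0L; rec$facts <- list()

    # Header subtree serialized first so its facts carry metadata = TRUE;
    # the body region is serialized with region = "body" per section.
    header_xml <- vapply(seq_along(header), function(i) {
      gen_serialize(header[[i]], rec, "/ClinicalDocument[1]", i, 1L, "header")
    }, character(1L))
    n_header_children <- length(header)

    body_sections <- lapply(seq_along(params$sections), function(si) {
      extra <- list()
      if (length(planted) && !params$plant_in_header && si == 1L) {
        extra <- lapply(planted, function(t) {
          g_el("text", children = list(g_tx(paste("care note:", t))))
        })
      }
      gen_section(params, vocab, extra_children = extra)
    })

    comp_pos <- n_header_children + 1L
    comp_path <- paste0("/ClinicalDocument[1]/component[", comp_pos, "]")
    sb_path <- paste0(comp_path, "/structuredBody[1]")
    rec$elements <- rec$elements + 2L  # component + structuredBody
    section_xml <- vapply(seq_along(body_sections), function(si) {
      wrapper_path <- paste0(sb_path, "/component[", si, "]")
      rec$elements <- rec$elements + 1L  # section wrapper component
      gen_serialize(body_sections[[si]], rec, wrapper_path, 1L, 4L, "body",
                    section = params$sections[[si]])
    }, character(1L))

    # record the root's xmlns fact
    rec$attrs <- rec$attrs + 1L
    rec$facts <- c(list(list(path = "/ClinicalDocument[1]", attribute = "xmlns",
                             lexical = "urn:hl7-org:v3", metadata = TRUE,
                             section = NA_character_)), rec$facts)
    rec$elements <- rec$elements + 1L  # root

    body_inner <- paste0(
      vapply(seq_along(section_xml), function(si) {
        paste0("      <component>\n        ", section_xml[[si]], "\n      </component>")
      }, character(1L)),
      collapse = "\n")
    xml <- paste0(
      "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
      "<ClinicalDocument xmlns=\"urn:hl7-org:v3\">\n",
      paste0("  ", header_xml, collapse = "\n"), "\n",
      "  <component>\n    <structuredBody>\n",
      body_inner, "\n",
      "    </structuredBody>\n  </component>\n",
      "</ClinicalDocument>\n")

    facts <- do.call(rbind, lapply(rec$facts, function(f) {
      data.frame(path = f$path, attribute = f$attribute, lexical = f$lexical,
                 metadata = f$metadata, section = f$section,
                 stringsAsFactors = FALSE)
    }))
    list(xml = xml,
         manifest = list(doc_index = doc_index,
                         n_elements = rec$elements,
                         n_text_nodes = rec$texts,
                         n_attributes = rec$attrs,
                         planted = planted,
                         facts = facts))
  })
}

#' Generate a synthetic corpus with its manifest
#'
#' @param params a [gen_params()].
#' @param dir optional directory; when given, each document is written to
#'   `doc_NNNN.xml` and a `manifest.json` is written alongside.
#' @return list with `docs` (named character vector of document texts),
#'   `manifest` (per-document ground truth plus the term placement map), and
#'   `files` (paths, when `dir` was given).
#' @export
generate_corpus <- function(params, dir = NULL) {
  stopifnot(inherits(params, "gen_params"))
  terms <- params$planted_terms
  placements <- list()
  if (length(terms)) {
    placements <- with_local_seed((params$seed %% 100000L) * 7919 + 17, {
      out <- list()
      for (i in seq_along(terms)) {
        out[[names(terms)[[i]]]] <- sort(sample.int(params$n_docs, terms[[i]]))
      }
      out
    })
  }
  docs <- character(params$n_docs)
  per_doc <- vector("list", params$n_docs)
  for (d in seq_len(params$n_docs)) {
    planted_here <- names(placements)[vapply(placements, function(p) d %in% p,
                                             logical(1L))]
    g <- generate_document(params, d, planted = planted_here)
    docs[[d]] <- g$xml
    per_doc[[d]] <- g$manifest
  }
  names(docs) <- sprintf("doc_%04d.xml", seq_len(params$n_docs))
  manifest <- list(params = unclass(params), docs = per_doc, terms = placements)
  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- file.path(dir, names(docs))
    for (i in seq_along(docs)) writeLines(docs[[i]], files[[i]], useBytes = TRUE)
    jsonlite::write_json(manifest_to_json(manifest),
                         file.path(dir, "manifest.json"), auto_unbox = TRUE)
  }
  list(docs = docs, manifest = manifest, files = files)
}

manifest_to_json <- function(manifest) {
  list(params = manifest$params,
       terms = manifest$terms,
       docs = lapply(manifest$docs, function(d) {
         list(doc_index = d$doc_index, n_elements = d$n_elements,
              n_text_nodes = d$n_text_nodes, n_attributes = d$n_attributes,
              planted = d$planted, facts = d$facts)
       }))
}

#' Collect a manifest's fact table across documents
#' @param manifest a corpus manifest from [generate_corpus()].
#' @return data.frame of all facts with a `doc_index` column.
#' @export
manifest_facts <- function(manifest) {
  do.call(rbind, lapply(manifest$docs, function(d) {
    if (is.null(d$facts)) return(NULL)
    cbind(doc_index = d$doc_index, d$facts)
  }))
}
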