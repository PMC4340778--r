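# Internal helpers shared across the engine: path algebra, XML escaping,
# content digests and seeded evaluation.

#' Split an entity path into its segments
#'
#' Paths have the form `/name[pos]/name[pos]/...` where `pos` is the 1-based
#' position of the node among *all* of its siblings (elements and text
#' pseudo-nodes alike).
#'
#' @param path a single path string.
#' @return a data.frame with columns `name` and `pos` (integer), one row per
#'   segment from the root down.
#' @keywords internal
path_segments <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!nzchar(path) || !startsWith(path, "/")) {
    stop("invalid entity path: ", path, call. = FALSE)
  }
  segs <- strsplit(substring(path, 2L), "/", fixed = TRUE)[[1L]]
  m <- regmatches(segs, regexec("^(.*)\\[([0-9]+)\\]$", segs))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("malformed path segment(s): ", paste(segs[bad], collapse = ", "), call. = FALSE)
  data.frame(
    name = vapply(m, `[`, "", 2L),
    pos  = as.integer(vapply(m, `[`, "", 3L)),
    stringsAsFactors = FALSE
  )
}

#' @keywords internal
make_path <- function(names, pos) {
  paste0("/", paste0(names, "[", pos, "]", collapse = "/"))
}

# Parse one pattern segment: "name[3]", "name[*]", "*", "*[2]", "name".
# A missing position means "any position".
parse_pattern_segments <- function(pattern_path) {
  if (!nzchar(pattern_path) || !startsWith(pattern_path, "/")) {
    stop("invalid path pattern: ", pattern_path, call. = FALSE)
  }
  segs <- strsplit(substring(pattern_path, 2L), "/", fixed = TRUE)[[1L]]
  lapply(segs, function(s) {
    m <- regmatches(s, regexec("^(.*)\\[([0-9*]+)\\]$", s))[[1L]]
    if (length(m) == 3L) {
      list(name = m[2L], pos = m[3L])
    } else {
      list(name = s, pos = "*")
    }
  })
}

# Split a fact pattern into an entity-path part and an attribute part.
# "/a[1]/b[*]/@code" -> path "/a[1]/b[*]", attr "code"; no "@" -> attr "*".
split_fact_pattern <- function(pattern) {
  at <- regexpr("/@", pattern, fixed = TRUE)
  if (at > 0L) {
    list(path = substring(pattern, 1L, at - 1L), attr = substring(pattern, at + 2L))
  } else {
    list(path = pattern, attr = "*")
  }
}

#' Match an entity path against a path pattern
#'
#' Patterns use `*` as a name wildcard and `[*]` (or an omitted position) as a
#' position wildcard. In `"exact"` mode the pattern must cover the whole path;
#' in `"prefix"` mode it must match an initial run of segments, so a section
#' pattern selects everything below that section.
#'
#' @param pattern a path pattern string.
#' @param path an entity path string.
#' @param mode `"exact"` or `"prefix"`.
#' @return `TRUE`/`FALSE`; in exact mode, a `TRUE` result carries the
#'   attributes `wild_names` and `wild_pos` with the segments captured by
#'   wildcards (used to instantiate rule targets).
#' @keywords internal
path_pattern_match <- function(pattern, path, mode = c("exact", "prefix")) {
  mode <- match.arg(mode)
  pat <- parse_pattern_segments(pattern)
  seg <- path_segments(path)
  np <- length(pat)
  if (mode == "exact" && np != nrow(seg)) return(FALSE)
  if (np > nrow(seg)) return(FALSE)
  wild_names <- character(0)
  wild_pos <- integer(0)
  for (i in seq_len(np)) {
    p <- pat[[i]]
    if (p$name == "*") {
      wild_names <- c(wild_names, seg$name[i])
    } else if (p$name != seg$name[i]) {
      return(FALSE)
    }
    if (p$pos == "*") {
      wild_pos <- c(wild_pos, seg$pos[i])
    } else if (as.integer(p$pos) != seg$pos[i]) {
      return(FALSE)
    }
  }
  structure(TRUE, wild_names = wild_names, wild_pos = wild_pos)
}

# Vectorised prefix matching of many paths against many patterns: TRUE where
# a path matches at least one pattern.
paths_match_any <- function(patterns, paths, mode = "prefix") {
  if (length(patterns) == 0L) return(rep(TRUE, length(paths)))
  out <- logical(length(paths))
  for (pp in patterns) {
    idx <- which(!out)
    if (!length(idx)) break
    out[idx] <- vapply(
      paths[idx],
      function(p) isTRUE(path_pattern_match(pp, p, mode = mode)),
      logical(1L), USE.NAMES = FALSE
    )
  }
  out
}

xml_escape_text <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

xml_escape_attr <- function(x) {
  x <- xml_escape_text(x)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

#' MD5 digest of a document's text
#'
#' @param txt a character scalar (the raw document text).
#' @return lowercase hex digest string.
#' @keywords internal
content_digest <- function(txt) {
  stopifnot(is.character(txt), length(txt) == 1L)
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, open = "wb")
  writeBin(charToRaw(enc2utf8(txt)), con)
  close(con)
  unname(tools::md5sum(f))
}

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

now_timestamp <- function() format(Sys.time(), "%Y-%m-%d %H:%M:%S")
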