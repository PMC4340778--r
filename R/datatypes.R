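# Typed value tables: the registry of datatype tags and the lexical
# inference rule that routes each incoming value to its table.

# Built-in parsers. Each returns the typed value, or NULL if the lexical is
# not a member of the datatype's lexical space.
.builtin_datatypes <- list(
  string = list(
    sql_type = "TEXT",
    parse = function(x) x
  ),
  integer = list(
    sql_type = "INTEGER",
    parse = function(x) {
      if (grepl("^[+-]?[0-9]+$", x) && nchar(gsub("[+-]", "", x)) <= 15L) {
        as.numeric(x)
      } else NULL
    }
  ),
  real = list(
    sql_type = "REAL",
    parse = function(x) {
      ok <- grepl("^[+-]?([0-9]+\\.[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", x) ||
        grepl("^[+-]?[0-9]+[eE][+-]?[0-9]+$", x)
      if (ok) as.numeric(x) else NULL
    }
  ),
  boolean = list(
    sql_type = "INTEGER",
    parse = function(x) {
      lx <- tolower(x)
      if (lx == "true") TRUE else if (lx == "false") FALSE else NULL
    }
  ),
  date = list(
    sql_type = "TEXT",
    parse = function(x) {
      if (!grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", x)) return(NULL)
      d <- as.Date(x, format = "%Y-%m-%d")
      if (is.na(d) || format(d, "%Y-%m-%d") != x) NULL else format(d, "%Y-%m-%d")
    }
  ),
  timestamp = list(
    sql_type = "TEXT",
    parse = function(x) {
      re <- paste0(
        "^[0-9]{4}-[0-9]{2}-[0-9]{2}[T ]",
        "[0-9]{2}:[0-9]{2}(:[0-9]{2})?(\\.[0-9]+)?",
        "(Z|[+-][0-9]{2}:?[0-9]{2})?$"
      )
      if (!grepl(re, x)) return(NULL)
      date_part <- substr(x, 1L, 10L)
      if (is.null(.builtin_datatypes$date$parse(date_part))) return(NULL)
      hh <- as.integer(substr(x, 12L, 13L))
      mm <- as.integer(substr(x, 15L, 16L))
      if (hh > 23L || mm > 59L) return(NULL)
      x
    }
  )
)

# Inference precedence for untyped lexicals. "string" is the catch-all and
# must stay last.
.infer_order <- c("boolean", "integer", "real", "date", "timestamp", "string")

# Session-level registry of extension datatypes (tag -> list(sql_type, parse)).
.eav_runtime <- new.env(parent = emptyenv())
.eav_runtime$extra_datatypes <- list()

datatype_def <- function(tag) {
  def <- .builtin_datatypes[[tag]] %||% .eav_runtime$extra_datatypes[[tag]]
  if (is.null(def)) {
    # Tag registered in a store by an earlier session whose parser is gone:
    # fall back to string semantics so stored rows stay readable.
    def <- list(sql_type = "TEXT", parse = function(x) x)
  }
  def
}

#' Infer the datatype tag of a lexical value
#'
#' Routing rule for untyped incoming values, applied per value (no schema is
#' consulted). Precedence: boolean, integer, real, date (ISO 8601), timestamp
#' (ISO 8601 date-time), string. The empty string is a string. The function is
#' total and deterministic.
#'
#' @param lexical a character vector of verbatim source strings.
#' @return a character vector of datatype tags, one per input.
#' @examples
#' infer_datatype(c("true", "42", "042", "3.14", "2013-02-04", "4.2.1"))
#' @export
infer_datatype <- function(lexical) {
  stopifnot(is.character(lexical))
  vapply(lexical, function(x) {
    if (is.na(x) || !nzchar(x)) return("string")
    for (tag in .infer_order) {
      if (tag == "string") return("string")
      if (!is.null(.builtin_datatypes[[tag]]$parse(x))) return(tag)
    }
    "string"
  }, character(1L), USE.NAMES = FALSE)
}

#' Parse a lexical under a datatype tag
#'
#' @param lexical a single verbatim string.
#' @param tag a registered datatype tag.
#' @return the typed value, or an error if the lexical is not valid for the
#'   tag.
#' @keywords internal
parse_lexical <- function(lexical, tag) {
  v <- datatype_def(tag)$parse(lexical)
  if (is.null(v)) {
    stop("lexical ", deparse(lexical), " is not valid for datatype '", tag, "'",
         call. = FALSE)
  }
  v
}
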