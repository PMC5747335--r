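VALUE_TYPES <- c("string", "integer", "float", "boolean", "file", "choice")
LINK_KINDS <- c("homepage", "documentation", "repository")
VERSION_SENTINEL <- "unknown"

coerce_default <- function(default, value_type) {
  if (is.null(default)) return(NULL)
  switch(value_type,
    integer = {
      v <- suppressWarnings(as.integer(default))
      if (is.na(v)) ts_abort("type_mismatch",
        sprintf("default '%s' is not an integer", chr1(default)))
      v
    },
    float = {
      v <- suppressWarnings(as.numeric(default))
      if (is.na(v)) ts_abort("type_mismatch",
        sprintf("default '%s' is not a number", chr1(default)))
      v
    },
    boolean = {
      v <- if (is.logical(default)) default[1] else
        c("true" = TRUE, "false" = FALSE)[tolower(chr1(default))]
      if (is.na(v)) ts_abort("type_mismatch",
        sprintf("default '%s' is not a boolean", chr1(default)))
      unname(v)
    },
    chr1(default)
  )
}

#' Create a tool parameter
#'
#' One input of a command-line tool: a typed value with an optional
#' command-line binding (flag string for options, position index for
#' positionals) and optional EDAM annotation of its semantic type
#' (`data` branch) and accepted serializations (`format` branch).
#'
#' @param name Identifier-safe token, unique within a description.
#' @param value_type One of `string`, `integer`, `float`, `boolean`,
#'   `file`, `choice`.
#' @param choices Allowed literal values; required exactly when
#'   `value_type = "choice"`.
#' @param default Optional default literal, coerced to the declared type.
#' @param required Is the parameter mandatory?
#' @param multiple May the argument repeat?
#' @param help One-line usage text.
#' @param edam_data Optional `data`-branch [edam_term()].
#' @param edam_formats List of `format`-branch terms.
#' @param cli_binding Optional list with `flag` (e.g. `"--threads"`) and/or
#'   `position` (1-based index for positionals).
#' @return An object of class `tool_parameter`.
#' @export
tool_parameter <- function(name, value_type = "string", choices = NULL,
                           default = NULL, required = TRUE,
                           multiple = FALSE, help = "",
                           edam_data = NULL, edam_formats = NULL,
                           cli_binding = NULL) {
  if (!is_string(name) || is_blank(name) || grepl("[[:space:]]", name)) {
    ts_abort("bad_parameter", "parameter name must be a whitespace-free token")
  }
  if (!value_type %in% VALUE_TYPES) {
    ts_abort("bad_parameter",
             sprintf("unknown value_type '%s'", chr1(value_type)))
  }
  choices <- as.character(choices %||% character(0))
  if ((value_type == "choice") != (length(choices) > 0L)) {
    ts_abort("bad_parameter",
             "choices must be nonempty exactly when value_type is 'choice'")
  }
  if (!is.null(edam_data)) {
    if (!is_edam_term(edam_data)) edam_data <- edam_term(edam_data)
    if (edam_branch(edam_data) != "data") {
      ts_abort("bad_edam_branch", "edam_data must be a data-branch term")
    }
  }
  if (!is.null(cli_binding)) {
    cli_binding <- list(flag = if (!is.null(cli_binding$flag))
                          chr1(cli_binding$flag) else NULL,
                        position = if (!is.null(cli_binding$position))
                          as.integer(cli_binding$position) else NULL)
  }
  structure(
    list(name = name,
         value_type = value_type,
         choices = choices,
         default = coerce_default(default, value_type),
         required = isTRUE(required),
         multiple = isTRUE(multiple),
         help = trim_ws(help),
         edam_data = edam_data,
         edam_formats = edam_term_list(edam_formats, "format",
                                       "parameter edam_formats"),
         cli_binding = cli_binding),
    class = "tool_parameter"
  )
}

#' Create an output specification
#'
#' @param name Identifier-safe token, unique among a description's outputs.
#' @param edam_data Optional `data`-branch [edam_term()].
#' @param edam_formats List of `format`-branch terms.
#' @param from_pattern Optional filename or glob the output is collected
#'   from. Registry metadata cannot supply this mapping, so generated
#'   skeletons leave it empty for the author to fill in.
#' @return An object of class `output_spec`.
#' @export
output_spec <- function(name, edam_data = NULL, edam_formats = NULL,
                        from_pattern = NULL) {
  if (!is_string(name) || is_blank(name) || grepl("[[:space:]]", name)) {
    ts_abort("bad_output", "output name must be a whitespace-free token")
  }
  if (!is.null(edam_data)) {
    if (!is_edam_term(edam_data)) edam_data <- edam_term(edam_data)
    if (edam_branch(edam_data) != "data") {
      ts_abort("bad_edam_branch", "edam_data must be a data-branch term")
    }
  }
  structure(
    list(name = name,
         edam_data = edam_data,
         edam_formats = edam_term_list(edam_formats, "format",
                                       "output edam_formats"),
         from_pattern = if (is.null(from_pattern)) NULL
                        else chr1(from_pattern)),
    class = "output_spec"
  )
}

normalize_doc_links <- function(doc_links) {
  if (is.null(doc_links) || length(doc_links) == 0L) return(list())
  out <- lapply(doc_links, function(l) {
    kind <- chr1(l$kind %||% l[[1]])
    if (!kind %in% LINK_KINDS) {
      ts_abort("bad_link", sprintf("unknown link kind '%s'", kind))
    }
    list(kind = kind, url = chr1(l$url %||% l[[2]]))
  })
  keys <- vapply(out, function(l) paste0(l$kind, "\t", l$url), "")
  out[!duplicated(keys)]
}

#' Create a format-neutral tool description
#'
#' The object model shared by every reader and writer in the package:
#' registry entries, Galaxy XML and CWL CommandLineTool documents all map
#' onto it, and enrichment operates on it. Scalar metadata, EDAM topic and
#' operation annotations, citations and links live beside the structural
#' core (inputs, outputs, command template), which metadata enrichment
#' never modifies.
#'
#' @param id Stable identifier token (no whitespace).
#' @param name Display name.
#' @param version Version string; `"unknown"` when not stated.
#' @param description One-line summary.
#' @param help_text Long usage text.
#' @param command_template Command skeleton; `$dest` placeholders refer to
#'   parameter names.
#' @param inputs List of [tool_parameter()] (names unique).
#' @param outputs List of [output_spec()] (names unique).
#' @param topics,operations Lists of [edam_term()] in the matching branch.
#' @param citations List of [citation_ref()].
#' @param doc_links List of `list(kind, url)` with kind in `homepage`,
#'   `documentation`, `repository`.
#' @param license Optional SPDX-style license string.
#' @param passthrough Opaque store of unrecognized document content kept
#'   across parse/write cycles; not user-constructed.
#' @return An object of class `tool_description`.
#' @examples
#' tool_description("integron_finder", name = "IntegronFinder",
#'                  topics = list(edam_term("topic_0085")))
#' @export
tool_description <- function(id, name = id, version = VERSION_SENTINEL,
                             description = "", help_text = "",
                             command_template = "",
                             inputs = list(), outputs = list(),
                             topics = list(), operations = list(),
                             citations = list(), doc_links = list(),
                             license = "", passthrough = list()) {
  if (!is_string(id) || is_blank(id) || grepl("[[:space:]]", id)) {
    ts_abort("bad_description", "id must be a nonempty whitespace-free token")
  }
  inputs <- lapply(inputs, function(p) {
    if (!inherits(p, "tool_parameter")) {
      ts_abort("bad_description", "inputs must be tool_parameter objects")
    }
    p
  })
  in_names <- vapply(inputs, `[[`, "", "name")
  if (anyDuplicated(in_names)) {
    ts_abort("bad_description", "duplicate parameter names")
  }
  outputs <- lapply(outputs, function(o) {
    if (!inherits(o, "output_spec")) {
      ts_abort("bad_description", "outputs must be output_spec objects")
    }
    o
  })
  out_names <- vapply(outputs, `[[`, "", "name")
  if (anyDuplicated(out_names)) {
    ts_abort("bad_description", "duplicate output names")
  }
  citations <- lapply(citations, function(x) {
    if (!is_citation(x)) ts_abort("bad_description",
                                  "citations must be citation_ref objects")
    x
  })
  structure(
    list(id = id,
         name = chr1(name, id),
         version = if (is_blank(version)) VERSION_SENTINEL
                   else trim_ws(version),
         description = trim_ws(description),
         help_text = trim_ws(help_text),
         command_template = trim_ws(command_template),
         inputs = inputs,
         outputs = outputs,
         topics = edam_term_list(topics, "topic", "topics"),
         operations = edam_term_list(operations, "operation", "operations"),
         citations = dedupe_citations(citations),
         doc_links = normalize_doc_links(doc_links),
         license = trim_ws(license),
         passthrough = passthrough),
    class = "tool_description"
  )
}

is_tool_description <- function(x) inherits(x, "tool_description")

#' @export
print.tool_description <- function(x, ...) {
  cat("<tool_description> ", x$id, " (", x$name, " ", x$version, ")\n",
      sep = "")
  cat("  inputs: ", length(x$inputs),
      "  outputs: ", length(x$outputs),
      "  topics: ", length(x$topics),
      "  operations: ", length(x$operations),
      "  citations: ", length(x$citations), "\n", sep = "")
  flags <- completeness(x)
  cat("  complete: ",
      paste(names(flags)[unlist(flags)], collapse = " "), "\n", sep = "")
  invisible(x)
}

scalar_empty <- function(field, value) {
  if (field == "version") return(is_blank(value) || value == VERSION_SENTINEL)
  is_blank(value)
}

MERGE_SCALARS <- c("name", "version", "description", "help_text", "license")

#' Merge registry metadata into a tool description
#'
#' Fills missing metadata in `base` from `extra`. Under the default
#' `additive` policy no nonempty scalar of `base` is ever changed: empty
#' scalars take `extra`'s value and the list-valued metadata fields
#' (topics, operations, citations, doc links) become the deduplicated
#' union with `base`'s elements first. The structural core of `base` --
#' inputs, outputs and the command template -- is never modified by a
#' merge: parameter structure comes from generation, not enrichment.
#'
#' The non-default `overwrite` policy lets `extra`'s nonempty scalars win;
#' it exists for deliberate correction runs and is never implied.
#'
#' @param base,extra Valid [tool_description()] objects.
#' @param policy `"additive"` (default) or `"overwrite"`.
#' @return A merged `tool_description`.
#' @export
merge_metadata <- function(base, extra, policy = c("additive", "overwrite")) {
  policy <- match.arg(policy)
  if (!is_tool_description(base) || !is_tool_description(extra)) {
    ts_abort("bad_description", "merge_metadata expects tool_description")
  }
  out <- base
  for (f in MERGE_SCALARS) {
    if (policy == "overwrite") {
      if (!scalar_empty(f, extra[[f]])) out[[f]] <- extra[[f]]
    } else if (scalar_empty(f, base[[f]]) && !scalar_empty(f, extra[[f]])) {
      out[[f]] <- extra[[f]]
    }
  }
  out$topics <- dedupe_terms(c(base$topics, extra$topics))
  out$operations <- dedupe_terms(c(base$operations, extra$operations))
  out$citations <- dedupe_citations(c(base$citations, extra$citations))
  links <- c(base$doc_links, extra$doc_links)
  keys <- vapply(links, function(l) paste0(l$kind, "\t", l$url), "")
  out$doc_links <- links[!duplicated(keys)]
  out
}

#' Metadata completeness flags of a description
#'
#' The six per-tool metadata indicators used in corpus coverage audits:
#' presence of help text, of a description line, of citations, of all
#' three at once (`has_hdc`), and of EDAM operation and topic annotations.
#' Presence means nonempty after whitespace trimming.
#'
#' @param desc A [tool_description()].
#' @return Named list of six logicals: `has_help`, `has_description`,
#'   `has_citations`, `has_hdc`, `has_operations`, `has_topics`.
#' @export
completeness <- function(desc) {
  if (!is_tool_description(desc)) {
    ts_abort("bad_description", "completeness expects a tool_description")
  }
  h <- !is_blank(desc$help_text)
  d <- !is_blank(desc$description)
  c_ <- length(desc$citations) > 0L
  list(has_help = h,
       has_description = d,
       has_citations = c_,
       has_hdc = h && d && c_,
       has_operations = length(desc$operations) > 0L,
       has_topics = length(desc$topics) > 0L)
}

#' Canonical normal form of a description
#'
#' Deterministic normal form used to define equality across parse/write
#' round trips: EDAM term lists sorted by accession, citations sorted by
#' value, doc links sorted by kind then URL, scalar fields trimmed. DOIs
#' are already normalized at construction. Idempotent; input and output
#' order of parameters is meaningful and is left untouched.
#'
#' @param desc A [tool_description()].
#' @return The canonicalized `tool_description`.
#' @export
canonicalize <- function(desc) {
  if (!is_tool_description(desc)) {
    ts_abort("bad_description", "canonicalize expects a tool_description")
  }
  desc$topics <- sort_terms(desc$topics)
  desc$operations <- sort_terms(desc$operations)
  desc$citations <- sort_citations(desc$citations)
  if (length(desc$doc_links)) {
    kinds <- vapply(desc$doc_links, `[[`, "", "kind")
    urls <- vapply(desc$doc_links, `[[`, "", "url")
    desc$doc_links <- desc$doc_links[order(kinds, urls, method = "radix")]
  }
  desc
}

#' Test two descriptions for canonical equality
#'
#' @param a,b [tool_description()] objects.
#' @param ignore_passthrough Drop the opaque passthrough stores before
#'   comparing (default `TRUE`).
#' @return `TRUE` if the canonical forms are identical.
#' @export
desc_identical <- function(a, b, ignore_passthrough = TRUE) {
  a <- canonicalize(a); b <- canonicalize(b)
  if (ignore_passthrough) {
    a$passthrough <- list(); b$passthrough <- list()
  }
  identical(unclass(a), unclass(b))
}
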