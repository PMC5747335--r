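# Registry entries follow a BiotoolsSchema subset. Recognized keys:
# name, biotoolsID, description, homepage, toolType, topic, function,
# publication, documentation, license. Anything else is ignored with a
# notice -- the registry schema is wider than what a workbench
# description can carry.

REGISTRY_KEYS <- c("name", "biotoolsID", "description", "homepage",
                   "toolType", "topic", "function", "publication",
                   "documentation", "license")

parse_term_list <- function(x, branch, what) {
  if (is.null(x)) return(list())
  if (is.data.frame(x)) x <- split(x, seq_len(nrow(x)))
  terms <- lapply(x, function(t) {
    if (is.character(t)) return(edam_term(t))
    if (is.data.frame(t)) t <- as.list(t)
    uri <- chr1(t$uri %||% t$accession %||% "")
    if (is_blank(uri)) {
      ts_abort("schema", sprintf("%s term lacks a uri", what))
    }
    edam_term(uri, label = chr1(t$term %||% ""))
  })
  dedupe_terms(unname(terms))
}

parse_io_list <- function(x, what) {
  if (is.null(x)) return(list())
  if (is.data.frame(x)) x <- split(x, seq_len(nrow(x)))
  unname(lapply(x, function(io) {
    if (is.data.frame(io)) io <- as.list(io)
    dat <- io$data
    if (is.data.frame(dat)) dat <- as.list(dat)
    ed <- if (!is.null(dat) && !is_blank(chr1(dat$uri %||% ""))) {
      t <- edam_term(chr1(dat$uri), label = chr1(dat$term %||% ""))
      if (edam_branch(t) != "data") {
        ts_abort("schema", sprintf("%s data term is not data-branch", what))
      }
      t
    } else NULL
    list(edam_data = ed,
         edam_formats = parse_term_list(io$format, "format", what))
  }))
}

#' Parse one registry entry
#'
#' Maps a bio.tools-style JSON document (the BiotoolsSchema subset) onto a
#' `registry_entry`: EDAM topics, functions (operations plus typed
#' inputs/outputs), publications and documentation links. EDAM terms are
#' accepted as full URIs or bare accessions; DOIs are stored normalized.
#' Unrecognized keys are ignored with a logged notice.
#'
#' @param doc A JSON string, a file path, or an already-parsed list.
#' @return An object of class `registry_entry`.
#' @export
parse_registry_entry <- function(doc) {
  if (is.character(doc)) {
    doc <- if (length(doc) == 1L && file.exists(doc)) {
      jsonlite::fromJSON(doc, simplifyVector = FALSE)
    } else {
      jsonlite::fromJSON(paste(doc, collapse = "\n"),
                         simplifyVector = FALSE)
    }
  }
  if (!is.list(doc)) ts_abort("schema", "registry entry must be a JSON object")

  unknown <- setdiff(names(doc), REGISTRY_KEYS)
  if (length(unknown)) {
    ts_log("ignoring unrecognized registry keys: ",
           paste(unknown, collapse = ", "))
  }
  name <- chr1(doc$name %||% "")
  if (is_blank(name)) {
    ts_abort("missing_field", "registry entry has no 'name'")
  }
  biotools_id <- chr1(doc$biotoolsID %||% "")
  if (is_blank(biotools_id)) {
    # bio.tools derives IDs from names; do the same for partial entries
    biotools_id <- tolower(gsub("[^A-Za-z0-9_.-]+", "_", trim_ws(name)))
  }

  funs <- doc[["function"]]
  if (!is.null(funs) && !is.list(funs)) {
    ts_abort("schema", "'function' must be an array")
  }
  functions <- unname(lapply(funs %||% list(), function(f) {
    structure(
      list(operations = parse_term_list(f$operation, "operation", "function"),
           inputs = parse_io_list(f$input, "function input"),
           outputs = parse_io_list(f$output, "function output")),
      class = "registry_function"
    )
  }))

  pubs <- unname(lapply(doc$publication %||% list(), function(p) {
    if (is.data.frame(p)) p <- as.list(p)
    role <- if (identical(tolower(chr1(p$type %||% "")), "primary"))
      "primary" else "other"
    out <- list()
    if (!is_blank(chr1(p$doi %||% ""))) {
      out <- c(out, list(list(kind = "doi",
                              value = normalize_doi(chr1(p$doi)),
                              role = role)))
    }
    if (!is_blank(chr1(p$pmid %||% ""))) {
      out <- c(out, list(list(kind = "pmid", value = chr1(p$pmid),
                              role = role)))
    }
    if (!is_blank(chr1(p$pmcid %||% ""))) {
      out <- c(out, list(list(kind = "pmcid", value = chr1(p$pmcid),
                              role = role)))
    }
    out
  }))
  publications <- do.call(c, c(list(list()), pubs))

  docs <- unname(lapply(doc$documentation %||% list(), function(d) {
    if (is.data.frame(d)) d <- as.list(d)
    list(kind = chr1(d$type %||% "documentation", "documentation"),
         url = chr1(d$url %||% ""))
  }))
  docs <- Filter(function(d) !is_blank(d$url), docs)

  tool_types <- as.character(unlist(doc$toolType %||% character(0)))

  structure(
    list(biotools_id = biotools_id,
         name = trim_ws(name),
         description = trim_ws(chr1(doc$description %||% "")),
         homepage = trim_ws(chr1(doc$homepage %||% "")),
         tool_types = tool_types,
         topics = parse_term_list(doc$topic, "topic", "topic"),
         functions = functions,
         publications = publications,
         documentation = docs,
         license = trim_ws(chr1(doc$license %||% ""))),
    class = "registry_entry"
  )
}

is_registry_entry <- function(x) inherits(x, "registry_entry")

#' @export
print.registry_entry <- function(x, ...) {
  cat("<registry_entry> ", x$biotools_id, " (", x$name, ")\n", sep = "")
  cat("  functions: ", length(x$functions),
      "  topics: ", length(x$topics),
      "  publications: ", length(x$publications), "\n", sep = "")
  invisible(x)
}

#' Load a registry dump
#'
#' Reads a JSON array of entries or newline-delimited JSON. Per-entry
#' parse failures are collected on the `"failures"` attribute rather than
#' aborting the load, so one malformed record does not invalidate a dump.
#'
#' @param file Path to the dump.
#' @return List of `registry_entry` in file order, with attribute
#'   `failures`: a list of `list(index, message)`. Warns when the dump is
#'   empty.
#' @export
load_registry_dump <- function(file) {
  if (!file.exists(file)) ts_abort("io", sprintf("no such file: %s", file))
  txt <- paste(readLines(file, warn = FALSE), collapse = "\n")
  docs <- tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = FALSE),
    error = function(e) {
      # newline-delimited JSON fallback
      lines <- Filter(nzchar, strsplit(txt, "\n", fixed = TRUE)[[1]])
      lapply(lines, jsonlite::fromJSON, simplifyVector = FALSE)
    })
  if (!is.list(docs)) ts_abort("schema", "registry dump must be a JSON array")
  entries <- list()
  failures <- list()
  for (i in seq_along(docs)) {
    res <- tryCatch(parse_registry_entry(docs[[i]]), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        list(index = i, message = conditionMessage(res))
    } else {
      entries[[length(entries) + 1L]] <- res
    }
  }
  if (length(docs) == 0L) {
    ts_warn("empty_dump", sprintf("registry dump '%s' is empty", file))
  }
  attr(entries, "failures") <- failures
  entries
}

#' Map a registry entry onto the tool-description model
#'
#' Builds the metadata side of a description from registry information:
#' topics are copied, operations are the union over all registry
#' functions, and DOI publications become citations (primary publications
#' first). Help text is composed from the description, homepage and
#' documentation links, one per line and labeled. Structurally, only the
#' FIRST registry function contributes inputs and outputs -- a workbench
#' description wraps a single command, and multi-function entries do not
#' say which function that command is -- each input named `input_<k>` with
#' `value_type = "file"` (registry functions describe data, not scalar
#' flags). The command template is left empty: the registry does not state
#' how inputs map onto the command line.
#'
#' PMID/PMCID publications stay on the registry entry; workbench citation
#' blocks anchor on DOI or BibTeX, so only DOIs cross over.
#'
#' @param entry A [parse_registry_entry()] result.
#' @return A [tool_description()].
#' @export
entry_to_model <- function(entry) {
  if (!is_registry_entry(entry)) {
    ts_abort("schema", "entry_to_model expects a registry_entry")
  }
  ops <- dedupe_terms(do.call(c, c(list(list()),
    lapply(entry$functions, `[[`, "operations"))))

  pubs <- entry$publications
  roles <- vapply(pubs, `[[`, "", "role")
  pubs <- c(pubs[roles == "primary"], pubs[roles != "primary"])
  dois <- Filter(function(p) p$kind == "doi", pubs)
  citations <- dedupe_citations(
    lapply(dois, function(p) citation_ref("doi", p$value)))

  help_lines <- character(0)
  if (!is_blank(entry$description)) help_lines <- entry$description
  if (!is_blank(entry$homepage)) {
    help_lines <- c(help_lines, paste0("Homepage: ", entry$homepage))
  }
  for (d in entry$documentation) {
    help_lines <- c(help_lines, paste0("Documentation: ", d$url))
  }

  doc_links <- list()
  if (!is_blank(entry$homepage)) {
    doc_links <- list(list(kind = "homepage", url = entry$homepage))
  }
  for (d in entry$documentation) {
    kind <- if (chr1(d$kind) %in% LINK_KINDS) chr1(d$kind) else "documentation"
    doc_links <- c(doc_links, list(list(kind = kind, url = d$url)))
  }

  inputs <- list()
  outputs <- list()
  if (length(entry$functions)) {
    f1 <- entry$functions[[1]]
    inputs <- lapply(seq_along(f1$inputs), function(k) {
      io <- f1$inputs[[k]]
      tool_parameter(sprintf("input_%d", k), value_type = "file",
                     edam_data = io$edam_data,
                     edam_formats = io$edam_formats)
    })
    outputs <- lapply(seq_along(f1$outputs), function(k) {
      io <- f1$outputs[[k]]
      output_spec(sprintf("output_%d", k),
                  edam_data = io$edam_data,
                  edam_formats = io$edam_formats)
    })
  }

  tool_description(
    id = entry$biotools_id,
    name = entry$name,
    description = entry$description,
    help_text = paste(help_lines, collapse = "\n"),
    inputs = inputs,
    outputs = outputs,
    topics = entry$topics,
    operations = ops,
    citations = citations,
    doc_links = doc_links,
    license = entry$license
  )
}

# ---- serialization (used by the corpus generator and round-trip tests) ----

term_to_json <- function(t) {
  out <- list(uri = t$uri)
  if (nzchar(t$label)) out$term <- t$label
  out
}

#' Serialize a registry entry back to its JSON shape
#'
#' Inverse of [parse_registry_entry()] on the supported schema subset.
#'
#' @param entry A `registry_entry`.
#' @return A list ready for [jsonlite::toJSON()].
#' @export
entry_to_json <- function(entry) {
  out <- list(name = entry$name, biotoolsID = entry$biotools_id)
  if (nzchar(entry$description)) out$description <- entry$description
  if (nzchar(entry$homepage)) out$homepage <- entry$homepage
  if (length(entry$tool_types)) out$toolType <- as.list(entry$tool_types)
  if (length(entry$topics)) out$topic <- lapply(entry$topics, term_to_json)
  if (length(entry$functions)) {
    out[["function"]] <- lapply(entry$functions, function(f) {
      fx <- list()
      if (length(f$operations)) {
        fx$operation <- lapply(f$operations, term_to_json)
      }
      io_json <- function(io) {
        x <- list()
        if (!is.null(io$edam_data)) x$data <- term_to_json(io$edam_data)
        if (length(io$edam_formats)) {
          x$format <- lapply(io$edam_formats, term_to_json)
        }
        x
      }
      if (length(f$inputs)) fx$input <- lapply(f$inputs, io_json)
      if (length(f$outputs)) fx$output <- lapply(f$outputs, io_json)
      fx
    })
  }
  if (length(entry$publications)) {
    out$publication <- lapply(entry$publications, function(p) {
      px <- list()
      px[[p$kind]] <- p$value
      px$type <- if (p$role == "primary") "Primary" else "Other"
      px
    })
  }
  if (length(entry$documentation)) {
    out$documentation <- lapply(entry$documentation, function(d) {
      list(url = d$url, type = d$kind)
    })
  }
  if (nzchar(entry$license)) out$license <- entry$license
  out
}

#' Write registry entries as a JSON dump
#'
#' @param entries List of `registry_entry`.
#' @param file Output path.
#' @export
write_registry_dump <- function(entries, file) {
  docs <- lapply(entries, entry_to_json)
  jsonlite::write_json(docs, file, auto_unbox = TRUE, pretty = TRUE)
  invisible(file)
}
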