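# CWL CommandLineTool YAML dialect.
#
# Semantic annotations use one namespaced metadata convention, declared
# in $namespaces: EDAM topic/operation URIs under "edam:has_topic" /
# "edam:has_operation", citations as DOI URLs (raw strings = BibTeX)
# under "s:citation", and "s:softwareVersion" for the version string,
# which CWL has no native field for. This is the package's documented
# dialect; the writer pins cwlVersion to v1.0 and the parser accepts any
# v1.x.

CWL_TYPE <- c(string = "string", integer = "int", float = "float",
              boolean = "boolean", file = "File")
CWL_KNOWN <- c("cwlVersion", "class", "id", "label", "doc", "baseCommand",
               "inputs", "outputs", "$namespaces",
               "edam:has_topic", "edam:has_operation",
               "s:citation", "s:softwareVersion")
SCHEMA_ORG_NS <- "https://schema.org/"
DOI_URL <- "https://doi.org/"

empty_map <- function() stats::setNames(list(), character(0))

cwl_encode_type <- function(p) {
  if (p$value_type == "choice") {
    base <- list(type = "enum", symbols = as.list(p$choices))
    if (p$multiple) base <- list(type = "array", items = base)
    if (!p$required) base <- list("null", base)
    return(base)
  }
  base <- CWL_TYPE[[p$value_type]]
  if (p$multiple) base <- paste0(base, "[]")
  if (!p$required) base <- paste0(base, "?")
  base
}

cwl_decode_type <- function(ty) {
  required <- TRUE; multiple <- FALSE
  choices <- NULL
  if (is.list(ty) && is.null(names(ty)) && length(ty) == 2L &&
      identical(ty[[1]], "null")) {
    required <- FALSE
    ty <- ty[[2]]
  }
  if (is.list(ty) && identical(ty$type, "array")) {
    multiple <- TRUE
    ty <- ty$items
  }
  if (is.list(ty) && identical(ty$type, "enum")) {
    return(list(value_type = "choice",
                choices = as.character(unlist(ty$symbols)),
                required = required, multiple = multiple))
  }
  if (!is.character(ty) || length(ty) != 1L) {
    ts_abort("schema", "unsupported CWL input type")
  }
  if (endsWith(ty, "?")) { required <- FALSE; ty <- sub("\\?$", "", ty) }
  if (endsWith(ty, "[]")) { multiple <- TRUE; ty <- sub("\\[\\]$", "", ty) }
  vt <- names(CWL_TYPE)[match(ty, CWL_TYPE)]
  if (is.na(vt)) {
    ts_abort("schema", sprintf("unsupported CWL type '%s'", ty))
  }
  list(value_type = vt, choices = choices,
       required = required, multiple = multiple)
}

format_uris <- function(terms) {
  uris <- vapply(terms, `[[`, "", "uri")
  if (length(uris) == 1L) uris[[1]] else as.list(uris)
}

#' Write a tool description as CWL CommandLineTool YAML
#'
#' Deterministic serialization of the canonicalized description:
#' `cwlVersion` (pinned to v1.0), `class`, `id`, `label`, `doc`
#' (description and help text separated by a blank line), `baseCommand`
#' (first token of the command template, or the id), typed `inputs` with
#' command-line bindings and EDAM `format` URIs, `outputs`, and the
#' namespaced metadata block carrying EDAM topic/operation URIs and
#' citations as DOI URLs. Optional inputs use the `?` type suffix,
#' repeatable inputs array types. Passthrough keys from a previous parse
#' are re-emitted last.
#'
#' @param desc A [tool_description()].
#' @return A single YAML string.
#' @export
write_cwl <- function(desc) {
  if (!is_tool_description(desc)) {
    ts_abort("bad_description", "write_cwl expects a tool_description")
  }
  desc <- canonicalize(desc)
  out <- list(cwlVersion = "v1.0", class = "CommandLineTool", id = desc$id,
              label = desc$name)
  doc_parts <- c(if (nzchar(desc$description)) desc$description,
                 if (nzchar(desc$help_text)) desc$help_text)
  if (length(doc_parts)) out$doc <- paste(doc_parts, collapse = "\n\n")
  base_cmd <- if (nzchar(desc$command_template)) {
    strsplit(desc$command_template, "[[:space:]]+")[[1]][1]
  } else desc$id
  out$baseCommand <- base_cmd

  inputs <- empty_map()
  for (p in desc$inputs) {
    rec <- list(type = cwl_encode_type(p))
    bind <- list()
    if (!is.null(p$cli_binding$flag)) bind$prefix <- p$cli_binding$flag
    if (!is.null(p$cli_binding$position)) {
      bind$position <- p$cli_binding$position
    }
    if (length(bind)) rec$inputBinding <- bind
    if (!is.null(p$default) && p$value_type != "choice") {
      rec$default <- p$default
    } else if (!is.null(p$default)) {
      rec$default <- as.character(p$default)
    }
    if (length(p$edam_formats)) rec$format <- format_uris(p$edam_formats)
    if (nzchar(p$help)) rec$doc <- p$help
    inputs[[p$name]] <- rec
  }
  out$inputs <- inputs

  outputs <- empty_map()
  for (o in desc$outputs) {
    rec <- list(type = "File")
    if (!is.null(o$from_pattern)) {
      rec$outputBinding <- list(glob = o$from_pattern)
    }
    if (length(o$edam_formats)) rec$format <- format_uris(o$edam_formats)
    outputs[[o$name]] <- rec
  }
  out$outputs <- outputs

  out$`$namespaces` <- list(edam = EDAM_NS, s = SCHEMA_ORG_NS)
  if (length(desc$topics)) {
    out$`edam:has_topic` <- lapply(desc$topics, `[[`, "uri")
  }
  if (length(desc$operations)) {
    out$`edam:has_operation` <- lapply(desc$operations, `[[`, "uri")
  }
  if (length(desc$citations)) {
    out$`s:citation` <- lapply(desc$citations, function(ct) {
      if (ct$kind == "doi") paste0(DOI_URL, ct$value) else ct$value
    })
  }
  if (desc$version != VERSION_SENTINEL) {
    out$`s:softwareVersion` <- desc$version
  }
  for (k in names(desc$passthrough$cwl %||% list())) {
    out[[k]] <- desc$passthrough$cwl[[k]]
  }
  yaml::as.yaml(out, indent = 2, line.sep = "\n")
}

cwl_parse_input <- function(name, rec) {
  if (is.character(rec)) rec <- list(type = rec)
  tinfo <- cwl_decode_type(rec$type)
  binding <- NULL
  if (!is.null(rec$inputBinding)) {
    binding <- list(flag = rec$inputBinding$prefix,
                    position = rec$inputBinding$position)
  }
  formats <- NULL
  if (!is.null(rec$format)) {
    formats <- lapply(as.character(unlist(rec$format)), edam_term)
  }
  tool_parameter(
    name = name,
    value_type = tinfo$value_type,
    choices = tinfo$choices,
    default = rec$default,
    required = tinfo$required,
    multiple = tinfo$multiple,
    help = chr1(rec$doc %||% ""),
    edam_formats = formats,
    cli_binding = binding
  )
}

as_named_records <- function(x, what) {
  if (is.null(x) || length(x) == 0L) return(empty_map())
  if (!is.null(names(x))) return(x)
  # array-of-records form with id fields
  ids <- vapply(x, function(r) chr1(r$id %||% ""), "")
  if (any(!nzchar(ids))) {
    ts_abort("schema", sprintf("CWL %s records need names or ids", what))
  }
  stats::setNames(lapply(x, function(r) r[setdiff(names(r), "id")]), ids)
}

#' Parse CWL CommandLineTool YAML into the object model
#'
#' Inverse of [write_cwl()] on the supported key subset. Top-level keys
#' outside that subset are preserved in the passthrough store and
#' re-emitted on the next write. EDAM URIs in `format` fields become
#' format-branch terms; `s:citation` entries that are DOI URLs become DOI
#' citations and anything else is kept as BibTeX. Any `cwlVersion` of the
#' v1 series is accepted and recorded.
#'
#' @param yaml_text YAML text, a file path, or a parsed list.
#' @return A [tool_description()].
#' @export
parse_cwl <- function(yaml_text) {
  doc <- read_yaml_input(yaml_text)
  if (!is.list(doc) || is.null(names(doc))) {
    ts_abort("not_cwl", "not a YAML mapping")
  }
  if (!identical(doc$class, "CommandLineTool")) {
    ts_abort("not_cwl", sprintf("class is '%s', not CommandLineTool",
                                chr1(doc$class, "<missing>")))
  }
  ver <- chr1(doc$cwlVersion %||% "v1.0")
  if (!grepl("^v1\\.", ver)) {
    ts_abort("schema", sprintf("unsupported cwlVersion '%s'", ver))
  }
  id <- chr1(doc$id %||% "")
  if (is_blank(id)) ts_abort("schema", "CWL document lacks an id")

  doc_field <- chr1(doc$doc %||% "")
  if (grepl("\n\n", doc_field, fixed = TRUE)) {
    split_at <- regexpr("\n\n", doc_field, fixed = TRUE)
    description <- substr(doc_field, 1L, split_at - 1L)
    help_text <- substr(doc_field, split_at + 2L, nchar(doc_field))
  } else {
    description <- doc_field
    help_text <- ""
  }

  in_recs <- as_named_records(doc$inputs, "input")
  inputs <- lapply(names(in_recs), function(nm) {
    cwl_parse_input(nm, in_recs[[nm]])
  })
  out_recs <- as_named_records(doc$outputs, "output")
  outputs <- lapply(names(out_recs), function(nm) {
    rec <- out_recs[[nm]]
    if (is.character(rec)) rec <- list(type = rec)
    formats <- if (!is.null(rec$format)) {
      lapply(as.character(unlist(rec$format)), edam_term)
    } else NULL
    output_spec(nm, edam_formats = formats,
                from_pattern = rec$outputBinding$glob)
  })

  parse_uri_terms <- function(x) {
    lapply(as.character(unlist(x %||% list())), edam_term)
  }
  citations <- lapply(as.character(unlist(doc$`s:citation` %||% list())),
                      function(v) {
    if (startsWith(tolower(v), DOI_URL) ||
        startsWith(tolower(v), "http://doi.org/")) {
      citation_ref("doi", v)
    } else if (grepl("^10\\.[^/]+/", v)) {
      citation_ref("doi", v)
    } else {
      citation_ref("bibtex", v)
    }
  })

  base_cmd <- paste(as.character(unlist(doc$baseCommand %||% character(0))),
                    collapse = " ")
  passthrough_keys <- setdiff(names(doc), CWL_KNOWN)
  passthrough <- list(cwl_version = ver)
  if (length(passthrough_keys)) passthrough$cwl <- doc[passthrough_keys]

  tool_description(
    id = id,
    name = chr1(doc$label %||% id, id),
    version = chr1(doc$`s:softwareVersion` %||% VERSION_SENTINEL),
    description = description,
    help_text = help_text,
    command_template = base_cmd,
    inputs = inputs,
    outputs = outputs,
    topics = parse_uri_terms(doc$`edam:has_topic`),
    operations = parse_uri_terms(doc$`edam:has_operation`),
    citations = citations,
    passthrough = passthrough
  )
}

read_yaml_input <- function(x) {
  if (is.list(x)) return(x)
  if (!is_string(x)) ts_abort("schema", "expected YAML text or a path")
  txt <- if (!grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    paste(readLines(x, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  } else x
  tryCatch(yaml::yaml.load(txt),
           error = function(e) ts_abort("malformed_yaml",
                                        conditionMessage(e)))
}
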