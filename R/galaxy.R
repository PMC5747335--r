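# Galaxy tool XML dialect.
#
# Supported subset: tool/@id,@name,@version; description; edam_topics/
# edam_topic; edam_operations/edam_operation; command; inputs/param;
# outputs/data; help; citations/citation. EDAM tags carry bare accessions
# as element text. The param @format attribute carries comma-separated
# EDAM format accessions. Unrecognized child elements of <tool> survive
# parse/write cycles through the passthrough store, so enrichment never
# destroys author-supplied sections (tests, requirements, macros, ...).

GALAXY_PARAM_TYPE <- c(string = "text", integer = "integer",
                       float = "float", boolean = "boolean",
                       file = "data", choice = "select")
GALAXY_KNOWN <- c("description", "edam_topics", "edam_operations",
                  "command", "inputs", "outputs", "help", "citations")

needs_cdata <- function(x) grepl("[<>&]", x)

format_default_chr <- function(p) {
  if (is.null(p$default)) return(NULL)
  switch(p$value_type,
    boolean = if (isTRUE(p$default)) "true" else "false",
    integer = as.character(p$default),
    float   = as.character(p$default),
    as.character(p$default))
}

add_text_or_cdata <- function(node, text) {
  if (needs_cdata(text)) {
    xml2::xml_add_child(node, xml2::xml_cdata(text))
  } else {
    xml2::xml_text(node) <- text
  }
}

#' Write a tool description as Galaxy tool XML
#'
#' Serialization is deterministic: the description is canonicalized
#' first, elements appear in a fixed order (description, EDAM topic and
#' operation tags, command, inputs, outputs, help, citations, then any
#' passthrough content), attributes in the order id, name, version, and
#' the document is 2-space indented. Blocks for empty lists are omitted.
#' Help and command text containing XML-significant characters is wrapped
#' in CDATA; `$` placeholders are emitted verbatim because Galaxy's
#' templating uses them. The requirements section is never generated:
#' registry metadata does not say what software a tool needs installed.
#'
#' @param desc A [tool_description()].
#' @return A single string of well-formed UTF-8 XML.
#' @export
write_galaxy <- function(desc) {
  if (!is_tool_description(desc)) {
    ts_abort("bad_description", "write_galaxy expects a tool_description")
  }
  desc <- canonicalize(desc)
  root <- xml2::xml_new_root("tool", id = desc$id, name = desc$name,
                             version = desc$version)
  if (nzchar(desc$description)) {
    xml2::xml_add_child(root, "description", desc$description)
  }
  if (length(desc$topics)) {
    blk <- xml2::xml_add_child(root, "edam_topics")
    for (t in desc$topics) {
      xml2::xml_add_child(blk, "edam_topic", t$accession)
    }
  }
  if (length(desc$operations)) {
    blk <- xml2::xml_add_child(root, "edam_operations")
    for (t in desc$operations) {
      xml2::xml_add_child(blk, "edam_operation", t$accession)
    }
  }
  cmd <- xml2::xml_add_child(root, "command")
  if (nzchar(desc$command_template)) {
    add_text_or_cdata(cmd, desc$command_template)
  } else {
    xml2::xml_add_child(cmd, xml2::xml_comment(
      " TODO: map inputs and outputs onto the command line "))
  }
  if (length(desc$inputs)) {
    blk <- xml2::xml_add_child(root, "inputs")
    for (p in desc$inputs) write_galaxy_param(blk, p)
  }
  if (length(desc$outputs)) {
    blk <- xml2::xml_add_child(root, "outputs")
    for (o in desc$outputs) {
      attrs <- list(name = o$name)
      if (length(o$edam_formats)) {
        attrs$format <- paste(term_accessions(o$edam_formats),
                              collapse = ",")
      }
      if (!is.null(o$from_pattern)) attrs$from_work_dir <- o$from_pattern
      do.call(xml2::xml_add_child, c(list(blk, "data"), attrs))
    }
  }
  if (nzchar(desc$help_text)) {
    h <- xml2::xml_add_child(root, "help")
    add_text_or_cdata(h, desc$help_text)
  }
  if (length(desc$citations)) {
    blk <- xml2::xml_add_child(root, "citations")
    for (ct in desc$citations) {
      c_node <- xml2::xml_add_child(blk, "citation", type = ct$kind)
      add_text_or_cdata(c_node, ct$value)
    }
  }
  for (frag in desc$passthrough$galaxy %||% character(0)) {
    xml2::xml_add_child(root, xml2::xml_root(xml2::read_xml(frag)))
  }
  serialize_xml(root)
}

write_galaxy_param <- function(parent, p) {
  attrs <- list(name = p$name, type = GALAXY_PARAM_TYPE[[p$value_type]])
  def <- format_default_chr(p)
  if (p$value_type != "choice" && !is.null(def)) attrs$value <- def
  if (!p$required && is.null(p$default)) attrs$optional <- "true"
  if (p$multiple) attrs$multiple <- "true"
  if (nzchar(p$help)) attrs$label <- p$help
  if (length(p$edam_formats)) {
    attrs$format <- paste(term_accessions(p$edam_formats), collapse = ",")
  }
  node <- do.call(xml2::xml_add_child, c(list(parent, "param"), attrs))
  if (p$value_type == "choice") {
    for (ch in p$choices) {
      o_attrs <- list(value = ch)
      if (!is.null(p$default) && identical(as.character(p$default), ch)) {
        o_attrs$selected <- "true"
      }
      o <- do.call(xml2::xml_add_child, c(list(node, "option"), o_attrs))
      xml2::xml_text(o) <- ch
    }
  }
  node
}

serialize_xml <- function(root) {
  tf <- tempfile(fileext = ".xml")
  on.exit(unlink(tf))
  xml2::write_xml(root, tf, options = "format")
  paste0(paste(readLines(tf, warn = FALSE, encoding = "UTF-8"),
               collapse = "\n"), "\n")
}

attr1 <- function(node, name, default = "") {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) default else v
}

parse_galaxy_param <- function(node) {
  gtype <- attr1(node, "type")
  value_type <- names(GALAXY_PARAM_TYPE)[match(gtype, GALAXY_PARAM_TYPE)]
  if (is.na(value_type)) {
    ts_abort("schema", sprintf("unsupported Galaxy param type '%s'", gtype))
  }
  choices <- character(0)
  default <- NULL
  if (value_type == "choice") {
    opts <- xml2::xml_find_all(node, "./option")
    choices <- vapply(opts, function(o) attr1(o, "value"), "")
    sel <- vapply(opts, function(o) identical(attr1(o, "selected"), "true"),
                  TRUE)
    if (any(sel)) default <- choices[which(sel)[1]]
  } else {
    v <- xml2::xml_attr(node, "value")
    if (!is.na(v)) default <- v
  }
  has_default <- !is.null(default)
  optional <- identical(attr1(node, "optional"), "true")
  fmt <- xml2::xml_attr(node, "format")
  formats <- if (is.na(fmt) || is_blank(fmt)) NULL else
    lapply(strsplit(fmt, ",", fixed = TRUE)[[1]], edam_term)
  tool_parameter(
    name = attr1(node, "name"),
    value_type = value_type,
    choices = if (length(choices)) choices else NULL,
    default = default,
    required = !(optional || has_default),
    multiple = identical(attr1(node, "multiple"), "true"),
    help = attr1(node, "label"),
    edam_formats = formats
  )
}

#' Parse Galaxy tool XML into the object model
#'
#' Inverse of [write_galaxy()] on the supported element subset. Child
#' elements of `<tool>` outside that subset are preserved verbatim in the
#' description's passthrough store and re-emitted on the next write, so a
#' parse/enrich/write cycle never loses author content. A missing
#' `version` attribute becomes the `"unknown"` sentinel.
#'
#' @param xml XML text, a file path, or an `xml_document`.
#' @return A [tool_description()].
#' @export
parse_galaxy <- function(xml) {
  doc <- read_xml_input(xml)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "tool") {
    ts_abort("not_galaxy", sprintf(
      "root element is <%s>, not <tool>", xml2::xml_name(root)))
  }
  id <- attr1(root, "id")
  if (is_blank(id)) ts_abort("schema", "Galaxy tool lacks an id attribute")

  topics <- list(); operations <- list(); citations <- list()
  description <- ""; help_text <- ""; command_template <- ""
  inputs <- list(); outputs <- list()
  passthrough <- character(0)

  for (child in xml2::xml_find_all(root, "./*")) {
    nm <- xml2::xml_name(child)
    if (!nm %in% GALAXY_KNOWN) {
      passthrough <- c(passthrough, as.character(child))
      next
    }
    switch(nm,
      description = { description <- xml2::xml_text(child) },
      edam_topics = {
        topics <- lapply(xml2::xml_find_all(child, "./edam_topic"),
                         function(t) edam_term(xml2::xml_text(t)))
      },
      edam_operations = {
        operations <- lapply(xml2::xml_find_all(child, "./edam_operation"),
                             function(t) edam_term(xml2::xml_text(t)))
      },
      command = { command_template <- trim_ws(xml2::xml_text(child)) },
      inputs = {
        inputs <- lapply(xml2::xml_find_all(child, "./param"),
                         parse_galaxy_param)
      },
      outputs = {
        outputs <- lapply(xml2::xml_find_all(child, "./data"), function(d) {
          fmt <- xml2::xml_attr(d, "format")
          formats <- if (is.na(fmt) || is_blank(fmt)) NULL else
            lapply(strsplit(fmt, ",", fixed = TRUE)[[1]], edam_term)
          fw <- xml2::xml_attr(d, "from_work_dir")
          output_spec(attr1(d, "name"), edam_formats = formats,
                      from_pattern = if (is.na(fw)) NULL else fw)
        })
      },
      help = { help_text <- xml2::xml_text(child) },
      citations = {
        citations <- lapply(xml2::xml_find_all(child, "./citation"),
                            function(cn) {
          kind <- attr1(cn, "type", "doi")
          if (!kind %in% c("doi", "bibtex")) {
            ts_abort("schema",
                     sprintf("unsupported citation type '%s'", kind))
          }
          citation_ref(kind, xml2::xml_text(cn))
        })
      }
    )
  }

  tool_description(
    id = id,
    name = attr1(root, "name", id),
    version = attr1(root, "version", VERSION_SENTINEL),
    description = description,
    help_text = help_text,
    command_template = command_template,
    inputs = inputs,
    outputs = outputs,
    topics = topics,
    operations = operations,
    citations = citations,
    passthrough = if (length(passthrough)) list(galaxy = passthrough)
                  else list()
  )
}

read_xml_input <- function(xml) {
  if (inherits(xml, "xml_document")) return(xml)
  if (!is_string(xml)) ts_abort("schema", "expected XML text or a path")
  src <- if (!grepl("<", xml, fixed = TRUE) && file.exists(xml)) {
    paste(readLines(xml, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  } else xml
  tryCatch(xml2::read_xml(src),
           error = function(e) ts_abort("malformed_xml",
                                        conditionMessage(e)))
}

#' Check the structural rules of a Galaxy tool document
#'
#' Verifies the rules encoded from the Galaxy schema subset: a `<tool>`
#' root with id, name and version attributes; recognized child elements in
#' their fixed relative order; `param` elements with name and a supported
#' type; `data` outputs with a name; citations with a supported type.
#' Unrecognized elements are allowed anywhere (they are passthrough
#' content).
#'
#' @param xml XML text or path.
#' @return Character vector of violations; empty when the document
#'   conforms.
#' @export
check_galaxy_structure <- function(xml) {
  problems <- character(0)
  doc <- tryCatch(read_xml_input(xml), error = function(e) e)
  if (inherits(doc, "error")) {
    return(paste("not well-formed XML:", conditionMessage(doc)))
  }
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "tool") {
    return(sprintf("root is <%s>, expected <tool>", xml2::xml_name(root)))
  }
  for (a in c("id", "name", "version")) {
    if (is.na(xml2::xml_attr(root, a))) {
      problems <- c(problems, sprintf("missing tool attribute '%s'", a))
    }
  }
  kids <- xml2::xml_name(xml2::xml_find_all(root, "./*"))
  known <- kids[kids %in% GALAXY_KNOWN]
  if (anyDuplicated(known)) {
    problems <- c(problems, sprintf("duplicated block: %s",
      paste(unique(known[duplicated(known)]), collapse = ", ")))
  }
  pos <- match(unique(known), GALAXY_KNOWN)
  if (is.unsorted(pos)) {
    problems <- c(problems, "recognized blocks out of canonical order")
  }
  for (p in xml2::xml_find_all(root, "./inputs/param")) {
    if (is.na(xml2::xml_attr(p, "name"))) {
      problems <- c(problems, "param without name")
    }
    ty <- xml2::xml_attr(p, "type")
    if (is.na(ty) || !ty %in% GALAXY_PARAM_TYPE) {
      problems <- c(problems, sprintf("param with unsupported type '%s'",
                                      chr1(ty, "<missing>")))
    }
  }
  for (d in xml2::xml_find_all(root, "./outputs/data")) {
    if (is.na(xml2::xml_attr(d, "name"))) {
      problems <- c(problems, "output data without name")
    }
  }
  for (cn in xml2::xml_find_all(root, "./citations/citation")) {
    ty <- xml2::xml_attr(cn, "type")
    if (is.na(ty) || !ty %in% c("doi", "bibtex")) {
      problems <- c(problems, "citation with unsupported type")
    }
  }
  problems
}
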