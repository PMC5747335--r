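#' Detect the format of a tool-description document
#'
#' `galaxy_xml` when the text parses as XML with a `<tool>` root,
#' `cwl_yaml` when it parses as a YAML mapping with
#' `class: CommandLineTool`. Deterministic; anything else raises an
#' `unknown_format` error.
#'
#' @param text Document text or a file path.
#' @return `"galaxy_xml"` or `"cwl_yaml"`.
#' @export
detect_format <- function(text) {
  if (!is_string(text) || is_blank(text)) {
    ts_abort("unknown_format", "empty document")
  }
  xml_try <- tryCatch(read_xml_input(text), error = function(e) NULL)
  if (!is.null(xml_try) &&
      xml2::xml_name(xml2::xml_root(xml_try)) == "tool") {
    return("galaxy_xml")
  }
  yml_try <- tryCatch(read_yaml_input(text), error = function(e) NULL)
  if (is.list(yml_try) && identical(yml_try$class, "CommandLineTool")) {
    return("cwl_yaml")
  }
  ts_abort("unknown_format",
           "document is neither Galaxy tool XML nor CWL CommandLineTool")
}

#' Enrich an existing description with registry metadata
#'
#' The second half of the pipeline, usable on its own: the document is
#' parsed into the object model, the registry entry's metadata is merged
#' in additively (missing description, help, citations and EDAM topic/
#' operation annotations are filled; nothing already present is changed;
#' inputs, outputs and the command are untouched), and the document is
#' fully re-serialized in its original format. Unrecognized document
#' content survives through the passthrough store. Running the same
#' enrichment twice returns byte-identical text.
#'
#' @param text Document text or a file path (Galaxy XML or CWL YAML).
#' @param entry A `registry_entry`.
#' @return The enriched document text.
#' @export
enrich_description <- function(text, entry) {
  if (!is_registry_entry(entry)) {
    ts_abort("schema", "enrich_description expects a registry_entry")
  }
  fmt <- detect_format(text)
  extra <- entry_to_model(entry)
  if (fmt == "galaxy_xml") {
    model <- parse_galaxy(text)
    write_galaxy(merge_metadata(model, extra))
  } else {
    model <- parse_cwl(text)
    write_cwl(merge_metadata(model, extra))
  }
}
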