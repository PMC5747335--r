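# Declarative command-line-interface specifications: the introspection
# payload a language-specific analysis plugin (e.g. an argparse
# inspector) would emit. The pipeline contract starts at this document --
# third-party source code is never executed.

CLI_KINDS <- c("positional", "option", "flag")
CLI_VALUE_TYPES <- c("string", "integer", "float", "file", "choice")

cli_argument <- function(kind, dest, flags = character(0),
                         value_type = "string", choices = NULL,
                         default = NULL, required = NULL,
                         repeat_ = FALSE, help = "") {
  if (!kind %in% CLI_KINDS) {
    ts_abort("schema", sprintf("unknown argument kind '%s'", chr1(kind)))
  }
  if (!is_string(dest) || is_blank(dest) || grepl("[[:space:]]", dest)) {
    ts_abort("schema", "argument dest must be a whitespace-free token")
  }
  flags <- as.character(flags %||% character(0))
  if (kind == "positional" && length(flags)) {
    ts_abort("schema", sprintf("positional '%s' must not have flags", dest))
  }
  if (kind != "positional" && !length(flags)) {
    ts_abort("schema", sprintf("'%s' (%s) needs at least one flag",
                               dest, kind))
  }
  if (kind == "flag") {
    value_type <- "boolean"          # implied; flags carry no value
    choices <- NULL
    if (is.null(default)) default <- FALSE
    required <- FALSE
  } else {
    if (!value_type %in% CLI_VALUE_TYPES) {
      ts_abort("schema",
               sprintf("unknown value type '%s' for '%s'",
                       chr1(value_type), dest))
    }
    choices <- as.character(choices %||% character(0))
    if ((value_type == "choice") != (length(choices) > 0L)) {
      ts_abort("schema", sprintf(
        "'%s': choices must be given exactly when type is 'choice'", dest))
    }
    if (!is.null(default) && value_type == "choice" &&
        !chr1(default) %in% choices) {
      ts_abort("type_mismatch", sprintf(
        "'%s': default '%s' is not one of the choices", dest, chr1(default)))
    }
    default <- coerce_default(default, value_type)  # TypeMismatch on error
    if (is.null(required)) required <- is.null(default)
  }
  structure(
    list(kind = kind, flags = flags, dest = dest, value_type = value_type,
         choices = choices %||% character(0), default = default,
         required = isTRUE(required), repeat_ = isTRUE(repeat_),
         help = trim_ws(help)),
    class = "cli_argument"
  )
}

#' Parse a command-line-interface specification
#'
#' Reads the declarative JSON/YAML payload describing a program's
#' interface: `{program, description, arguments: [{kind, flags, dest,
#' type, choices, default, required, repeat, help}]}`. Arguments keep
#' document order; positionals take their position from that order.
#' Defaults are type-checked against the declared value type.
#'
#' @param doc Path to a `.json`/`.yml`/`.yaml` file, a JSON/YAML string,
#'   or an already-parsed list.
#' @return An object of class `cli_spec`.
#' @export
parse_clispec <- function(doc) {
  if (is.character(doc)) {
    txt <- if (length(doc) == 1L && !grepl("[\n{]", doc) &&
               file.exists(doc)) {
      paste(readLines(doc, warn = FALSE, encoding = "UTF-8"),
            collapse = "\n")
    } else paste(doc, collapse = "\n")
    doc <- tryCatch(
      if (grepl("^[[:space:]]*\\{", txt)) {
        jsonlite::fromJSON(txt, simplifyVector = FALSE)
      } else {
        yaml::yaml.load(txt)
      },
      error = function(e) ts_abort("malformed_clispec",
                                   conditionMessage(e)))
  }
  if (!is.list(doc)) ts_abort("schema", "CLI spec must be a mapping")
  program <- chr1(doc$program %||% "")
  if (is_blank(program)) {
    ts_abort("missing_field", "CLI spec has no 'program'")
  }
  args <- lapply(doc$arguments %||% list(), function(a) {
    cli_argument(kind = chr1(a$kind %||% "option"),
                 dest = chr1(a$dest %||% ""),
                 flags = as.character(unlist(a$flags %||% character(0))),
                 value_type = chr1(a$type %||% a$value_type %||% "string"),
                 choices = unlist(a$choices %||% NULL),
                 default = a$default,
                 required = a$required,
                 repeat_ = isTRUE(a[["repeat"]]) || isTRUE(a$repeat_),
                 help = chr1(a$help %||% ""))
  })
  dests <- vapply(args, `[[`, "", "dest")
  if (anyDuplicated(dests)) {
    ts_abort("duplicate_dest", sprintf(
      "duplicate dest token(s): %s",
      paste(unique(dests[duplicated(dests)]), collapse = ", ")))
  }
  structure(
    list(program = trim_ws(program),
         description = trim_ws(chr1(doc$description %||% "")),
         arguments = args),
    class = "cli_spec"
  )
}

#' @export
print.cli_spec <- function(x, ...) {
  cat("<cli_spec> ", x$program, " (", length(x$arguments),
      " arguments)\n", sep = "")
  invisible(x)
}

longest_flag <- function(flags) flags[which.max(nchar(flags))]

#' Render the command template for a CLI spec
#'
#' Deterministic construction of the command skeleton that generated
#' descriptions carry: the program name, then non-positional arguments in
#' declaration order (options as `FLAG $dest`, boolean flags as
#' conditionally guarded tokens so the flag is only emitted when the
#' parameter is set), then positionals in order as bare `$dest`
#' placeholders. Every dest token appears exactly once.
#'
#' @param spec A [parse_clispec()] result.
#' @return The command template string.
#' @examples
#' spec <- parse_clispec(list(program = "p", arguments = list(
#'   list(kind = "option", dest = "k", flags = list("--k"),
#'        type = "integer"),
#'   list(kind = "positional", dest = "f", type = "file"))))
#' render_command(spec)  # "p --k $k $f"
#' @export
render_command <- function(spec) {
  if (!inherits(spec, "cli_spec")) {
    ts_abort("schema", "render_command expects a cli_spec")
  }
  tokens <- spec$program
  for (a in spec$arguments) {
    if (a$kind == "option") {
      tokens <- c(tokens,
                  paste(longest_flag(a$flags), paste0("$", a$dest)))
    } else if (a$kind == "flag") {
      tokens <- c(tokens, sprintf("#if $%s#%s#end if#",
                                  a$dest, longest_flag(a$flags)))
    }
  }
  for (a in spec$arguments) {
    if (a$kind == "positional") tokens <- c(tokens, paste0("$", a$dest))
  }
  paste(tokens, collapse = " ")
}

#' Generate a tool-description skeleton from a CLI spec
#'
#' The first half of the two-module pipeline: interface introspection
#' yields the structural core of a description (one parameter per
#' argument, boolean parameters for flags, a rendered command template
#' and a single placeholder output -- the registry cannot say which file
#' a tool writes), and registry metadata, when supplied, is merged in
#' additively for the metadata half.
#'
#' For every argument the command-line binding keeps the longest flag
#' (`--threads` preferred over `-t`); positionals are bound by position.
#' File-typed positionals become data inputs.
#'
#' @param spec A [parse_clispec()] result.
#' @param merge_with Optional `registry_entry` whose metadata is merged
#'   into the skeleton via [merge_metadata()].
#' @return A [tool_description()].
#' @export
skeleton_from_clispec <- function(spec, merge_with = NULL) {
  if (!inherits(spec, "cli_spec")) {
    ts_abort("schema", "skeleton_from_clispec expects a cli_spec")
  }
  pos_index <- 0L
  inputs <- lapply(spec$arguments, function(a) {
    if (a$kind == "positional") {
      pos_index <<- pos_index + 1L
      tool_parameter(a$dest, value_type = a$value_type,
                     choices = if (length(a$choices)) a$choices else NULL,
                     default = a$default, required = a$required,
                     multiple = a$repeat_, help = a$help,
                     cli_binding = list(position = pos_index))
    } else if (a$kind == "flag") {
      tool_parameter(a$dest, value_type = "boolean", default = FALSE,
                     required = FALSE, help = a$help,
                     cli_binding = list(flag = longest_flag(a$flags)))
    } else {
      tool_parameter(a$dest, value_type = a$value_type,
                     choices = if (length(a$choices)) a$choices else NULL,
                     default = a$default, required = a$required,
                     multiple = a$repeat_, help = a$help,
                     cli_binding = list(flag = longest_flag(a$flags)))
    }
  })
  skeleton <- tool_description(
    id = spec$program,
    name = spec$program,
    description = spec$description,
    command_template = render_command(spec),
    inputs = inputs,
    outputs = list(output_spec("output1"))
  )
  if (!is.null(merge_with)) {
    extra <- if (is_registry_entry(merge_with)) entry_to_model(merge_with)
             else merge_with
    skeleton <- merge_metadata(skeleton, extra)
  }
  skeleton
}
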