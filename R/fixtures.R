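# Seeded synthetic corpora: Galaxy tool documents with independently
# planted metadata (help, description, DOI citations, EDAM annotations),
# a registry dump whose entries share planted DOIs with a configurable
# fraction of the corpus, planted ambiguities (one DOI duplicated across
# two registry entries), and a ground-truth table recording every
# decision. Everything downstream -- generation, enrichment, matching,
# auditing, the command-line layer -- is testable offline against this.

TOPIC_POOL <- c("topic_0622", "topic_0080", "topic_0091", "topic_3168",
                "topic_0085", "topic_3301")
OPERATION_POOL <- c("operation_0004", "operation_2403", "operation_0292",
                    "operation_3192", "operation_0525", "operation_3644")
FORMAT_POOL <- c("format_1929", "format_2330", "format_1930", "format_2572",
                 "format_3016")
DATA_POOL <- c("data_0006", "data_2044", "data_1383")

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

rtoken <- function(n = 6L) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

rwords <- function(n) {
  paste(replicate(n, rtoken(sample(3:8, 1))), collapse = " ")
}

#' Seeded random tool descriptions
#'
#' Samples descriptions from the subset of the object model that both the
#' Galaxy XML and the CWL YAML dialects can represent losslessly: typed
#' parameters (all six value types, optional and repeatable variants,
#' typed defaults on non-required parameters, EDAM format annotations),
#' outputs with collection globs, EDAM topics and operations, DOI and
#' BibTeX citations, single-token command templates. Used by the
#' round-trip and cross-format property harnesses.
#'
#' @param n Number of descriptions.
#' @param seed Integer seed; the same seed yields identical objects.
#' @return List of [tool_description()].
#' @export
random_descriptions <- function(n, seed = 1L) {
  with_seed(seed, lapply(seq_len(n), function(i) {
    id <- sprintf("tool_%04d_%s", i, rtoken(4))
    description <- if (stats::runif(1) < 0.8) rwords(5) else ""
    help_text <- if (nzchar(description) && stats::runif(1) < 0.6) {
      paste(rwords(6), rwords(6), sep = "\n")
    } else ""
    n_in <- sample(0:4, 1)
    inputs <- lapply(seq_len(n_in), function(k) {
      vt <- sample(VALUE_TYPES, 1)
      choices <- if (vt == "choice") {
        replicate(sample(2:4, 1), rtoken(4))
      } else NULL
      required <- stats::runif(1) < 0.6
      default <- NULL
      if (!required && stats::runif(1) < 0.5) {
        default <- switch(vt,
          string = rtoken(5),
          integer = sample.int(100L, 1),
          float = round(stats::runif(1, 0, 50), 2),
          boolean = stats::runif(1) < 0.5,
          choice = sample(choices, 1),
          file = NULL)
      }
      fmts <- if (stats::runif(1) < 0.4) {
        sample(FORMAT_POOL, sample(1:2, 1))
      } else NULL
      tool_parameter(sprintf("param_%d", k), value_type = vt,
                     choices = choices, default = default,
                     required = required,
                     multiple = stats::runif(1) < 0.2,
                     help = if (stats::runif(1) < 0.7) rwords(3) else "",
                     edam_formats = fmts)
    })
    n_out <- sample(0:2, 1)
    outputs <- lapply(seq_len(n_out), function(k) {
      output_spec(sprintf("out_%d", k),
                  edam_formats = if (stats::runif(1) < 0.5)
                    sample(FORMAT_POOL, 1) else NULL,
                  from_pattern = if (stats::runif(1) < 0.5)
                    paste0(rtoken(4), ".txt") else NULL)
    })
    n_cit <- sample(0:3, 1)
    citations <- lapply(seq_len(n_cit), function(k) {
      if (stats::runif(1) < 0.8) {
        citation_ref("doi", sprintf("10.5555/rand.%d.%d", i, k))
      } else {
        citation_ref("bibtex", sprintf(
          "@article{key%d_%d, title={%s}}", i, k, rwords(2)))
      }
    })
    tool_description(
      id = id,
      name = paste("Tool", rtoken(5)),
      version = sample(c(VERSION_SENTINEL, "1.0", "0.3.1", "2.4.1"), 1),
      description = description,
      help_text = help_text,
      command_template = paste0("run_", rtoken(5)),
      inputs = inputs,
      outputs = outputs,
      topics = as.list(sample(TOPIC_POOL, sample(0:3, 1))),
      operations = as.list(sample(OPERATION_POOL, sample(0:3, 1))),
      citations = citations
    )
  }))
}

#' Configuration for a synthetic corpus
#'
#' Defaults emulate a realistic workbench corpus: most tools document
#' themselves (help, description), roughly three in five carry a DOI
#' citation, just over half of those DOIs also appear in the registry,
#' EDAM annotations are rare (the situation enrichment exists to fix),
#' and a small fraction of planted DOIs is duplicated across two registry
#' entries to exercise the ambiguity handling of the strict matcher.
#'
#' @param n_tools Number of tool descriptions.
#' @param p_help,p_description,p_citations,p_edam Independent presence
#'   probabilities of the per-tool metadata fields (EDAM topic and
#'   operation blocks are planted independently, each with `p_edam`).
#' @param p_doi_link Probability that a tool's DOI also appears in the
#'   registry dump.
#' @param n_registry_extra Registry entries with no corpus counterpart.
#' @param ambiguity_rate Probability that a linked DOI is duplicated
#'   across two registry entries (making the strict match ambiguous).
#' @param seed Integer seed.
#' @return An object of class `corpus_config`.
#' @export
corpus_config <- function(n_tools = 665L, p_help = 0.85,
                          p_description = 0.90, p_citations = 0.60,
                          p_edam = 0.10, p_doi_link = 0.56,
                          n_registry_extra = 100L, ambiguity_rate = 0.03,
                          seed = 1L) {
  probs <- c(p_help = p_help, p_description = p_description,
             p_citations = p_citations, p_edam = p_edam,
             p_doi_link = p_doi_link, ambiguity_rate = ambiguity_rate)
  if (any(probs < 0 | probs > 1)) {
    ts_abort("schema", "probabilities must lie in [0, 1]")
  }
  if (n_tools < 0L) ts_abort("schema", "n_tools must be >= 0")
  structure(
    list(n_tools = as.integer(n_tools), p_help = p_help,
         p_description = p_description, p_citations = p_citations,
         p_edam = p_edam, p_doi_link = p_doi_link,
         n_registry_extra = as.integer(n_registry_extra),
         ambiguity_rate = ambiguity_rate, seed = as.integer(seed)),
    class = "corpus_config"
  )
}

#' Generate a seeded synthetic corpus
#'
#' Emits Galaxy tool XML documents with metadata planted independently at
#' the configured rates, a registry dump sharing planted DOIs, and a
#' ground-truth table. Planted DOIs use the reserved example prefix
#' `10.5555/` so they can never collide with real DOIs. The same
#' configuration yields byte-identical output.
#'
#' @param config A [corpus_config()].
#' @return An object of class `synthetic_corpus` with fields
#'   `galaxy_docs` (named list of XML strings), `registry` (list of
#'   `registry_entry`), `truth` (data.frame: desc_id, entry_id, ambiguous
#'   and the planted per-metric flags), and `config`.
#' @export
generate_corpus <- function(config = corpus_config()) {
  if (!inherits(config, "corpus_config")) {
    ts_abort("schema", "generate_corpus expects a corpus_config")
  }
  with_seed(config$seed, {
    n <- config$n_tools
    docs <- list()
    registry <- list()
    truth <- vector("list", n)
    for (k in seq_len(n)) {
      desc_id <- sprintf("synthtool_%04d", k)
      has_help <- stats::runif(1) < config$p_help
      has_desc <- stats::runif(1) < config$p_description
      has_cit <- stats::runif(1) < config$p_citations
      has_topics <- stats::runif(1) < config$p_edam
      has_ops <- stats::runif(1) < config$p_edam
      doi <- sprintf("10.5555/synth.%d", k)
      desc <- tool_description(
        id = desc_id,
        name = paste("Synthetic tool", k),
        version = "1.0",
        description = if (has_desc) rwords(5) else "",
        help_text = if (has_help) paste(rwords(8), rwords(8), sep = "\n")
                    else "",
        command_template = paste0("synthtool_", k),
        inputs = list(tool_parameter("input_1", value_type = "file")),
        outputs = list(output_spec("output_1")),
        topics = if (has_topics) as.list(sample(TOPIC_POOL,
                                                sample(1:2, 1))) else list(),
        operations = if (has_ops) as.list(sample(OPERATION_POOL,
                                                 sample(1:2, 1)))
                     else list(),
        citations = if (has_cit) list(citation_ref("doi", doi)) else list()
      )
      docs[[desc_id]] <- write_galaxy(desc)

      entry_id <- NA_character_
      ambiguous <- FALSE
      if (has_cit && stats::runif(1) < config$p_doi_link) {
        entry_id <- sprintf("bt_%04d", k)
        entry <- parse_registry_entry(list(
          name = paste("RegistryTool", k),
          biotoolsID = entry_id,
          description = rwords(6),
          homepage = sprintf("https://example.org/%s", entry_id),
          topic = lapply(sample(TOPIC_POOL, sample(1:2, 1)),
                         function(a) list(uri = paste0(EDAM_NS, a))),
          `function` = list(list(
            operation = lapply(sample(OPERATION_POOL, 1),
                               function(a) list(uri = paste0(EDAM_NS, a)))
          )),
          publication = list(list(doi = doi, type = "Primary"))
        ))
        registry[[length(registry) + 1L]] <- entry
        if (stats::runif(1) < config$ambiguity_rate) {
          ambiguous <- TRUE
          dup <- entry
          dup$biotools_id <- paste0(entry_id, "_dup")
          dup$name <- paste(dup$name, "(duplicate)")
          registry[[length(registry) + 1L]] <- dup
        }
      }
      truth[[k]] <- data.frame(
        desc_id = desc_id, entry_id = entry_id, ambiguous = ambiguous,
        has_help = has_help, has_description = has_desc,
        has_citations = has_cit, has_topics = has_topics,
        has_operations = has_ops, stringsAsFactors = FALSE)
    }
    for (j in seq_len(config$n_registry_extra)) {
      registry[[length(registry) + 1L]] <- parse_registry_entry(list(
        name = paste("ExtraTool", j),
        biotoolsID = sprintf("bt_extra_%04d", j),
        publication = list(list(doi = sprintf("10.5555/extra.%d", j),
                                type = "Primary"))
      ))
    }
    truth_df <- if (n) do.call(rbind, truth) else
      data.frame(desc_id = character(0), entry_id = character(0),
                 ambiguous = logical(0), has_help = logical(0),
                 has_description = logical(0), has_citations = logical(0),
                 has_topics = logical(0), has_operations = logical(0))
    structure(
      list(galaxy_docs = docs, registry = registry, truth = truth_df,
           config = config),
      class = "synthetic_corpus"
    )
  })
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat("<synthetic_corpus> ", length(x$galaxy_docs), " tools, ",
      length(x$registry), " registry entries (seed ",
      x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Write a synthetic corpus to disk
#'
#' Lays out the on-disk form the command-line audit consumes:
#' `tools/<desc_id>.xml`, `registry.json` and `truth.tsv` under `dir`.
#'
#' @param corpus A [generate_corpus()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  if (!inherits(corpus, "synthetic_corpus")) {
    ts_abort("schema", "write_corpus expects a synthetic_corpus")
  }
  tools_dir <- file.path(dir, "tools")
  dir.create(tools_dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(corpus$galaxy_docs)) {
    writeLines(sub("\n$", "", corpus$galaxy_docs[[id]]),
               file.path(tools_dir, paste0(id, ".xml")))
  }
  write_registry_dump(corpus$registry, file.path(dir, "registry.json"))
  utils::write.table(corpus$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(dir)
}
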