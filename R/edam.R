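EDAM_NS <- "http://edamontology.org/"
EDAM_BRANCHES <- c("topic", "operation", "data", "format")

#' Create an EDAM ontology term
#'
#' EDAM concepts are identified by accessions of the form
#' `<branch>_<4 digits>`, where the branch is one of `topic`, `operation`,
#' `data` or `format` (e.g. `topic_0622` for "Genomics"). Terms compare
#' equal by accession alone; the label is informative.
#'
#' @param accession Bare accession (e.g. `"topic_0622"`) or a full EDAM URI
#'   (`"http://edamontology.org/topic_0622"`).
#' @param label Optional human-readable term text.
#' @return An object of class `edam_term` with fields `accession`, `uri`
#'   and `label`.
#' @examples
#' edam_term("topic_0622", "Genomics")
#' edam_term("http://edamontology.org/format_1929")
#' @export
edam_term <- function(accession, label = "") {
  if (!is_string(accession)) {
    ts_abort("bad_edam", "EDAM accession must be a single string")
  }
  acc <- trim_ws(accession)
  if (startsWith(acc, EDAM_NS)) acc <- substring(acc, nchar(EDAM_NS) + 1L)
  acc <- sub("^https://edamontology\\.org/", "", acc)
  if (!grepl("^(topic|operation|data|format)_[0-9]{4}$", acc)) {
    ts_abort("bad_edam",
             sprintf("not a valid EDAM accession: '%s'", accession))
  }
  structure(
    list(accession = acc,
         uri = paste0(EDAM_NS, acc),
         label = trim_ws(chr1(label))),
    class = "edam_term"
  )
}

#' Branch of an EDAM term
#'
#' @param term An `edam_term` or a bare accession string.
#' @return One of `"topic"`, `"operation"`, `"data"`, `"format"`.
#' @export
edam_branch <- function(term) {
  acc <- if (inherits(term, "edam_term")) term$accession else chr1(term)
  sub("_[0-9]{4}$", "", acc)
}

is_edam_term <- function(x) inherits(x, "edam_term")

#' @export
print.edam_term <- function(x, ...) {
  lab <- if (nzchar(x$label)) paste0(" (", x$label, ")") else ""
  cat("<edam_term> ", x$accession, lab, "\n", sep = "")
  invisible(x)
}

#' @export
format.edam_term <- function(x, ...) x$accession

# validated list of terms restricted to one branch
edam_term_list <- function(terms, branch, what) {
  if (is.null(terms)) return(list())
  if (is_edam_term(terms)) terms <- list(terms)
  terms <- lapply(terms, function(t) {
    if (!is_edam_term(t)) t <- edam_term(t)
    t
  })
  bad <- vapply(terms, function(t) edam_branch(t) != branch, TRUE)
  if (any(bad)) {
    ts_abort("bad_edam_branch",
             sprintf("%s must hold %s-branch EDAM terms; got: %s",
                     what, branch,
                     paste(vapply(terms[bad], `[[`, "", "accession"),
                           collapse = ", ")))
  }
  dedupe_terms(terms)
}

dedupe_terms <- function(terms) {
  accs <- vapply(terms, `[[`, "", "accession")
  terms[!duplicated(accs)]
}

sort_terms <- function(terms) {
  accs <- vapply(terms, `[[`, "", "accession")
  terms[order(accs, method = "radix")]
}

term_accessions <- function(terms) vapply(terms, `[[`, "", "accession")
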