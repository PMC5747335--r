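#' Normalize a DOI string
#'
#' Strips resolver prefixes (`https://doi.org/`, `http://dx.doi.org/`,
#' `doi:`, ...), lowercases, trims whitespace and trailing punctuation
#' (`.`, `,`, `;`). DOI-based record linkage between tool-description
#' corpora and the registry relies on every DOI being in this canonical
#' form; the function is idempotent.
#'
#' @param text Raw citation identifier string.
#' @return Canonical DOI of the form `10.<prefix>/<suffix>`, lowercased.
#'   Raises an `invalid_doi` error if the residue does not look like a DOI.
#' @examples
#' normalize_doi("https://doi.org/10.1093/NAR/GKV1116")
#' normalize_doi("doi:10.1000/abc;")
#' @export
normalize_doi <- function(text) {
  if (!is_string(text) || is_blank(text)) {
    ts_abort("invalid_doi", "DOI must be a nonempty string")
  }
  x <- trim_ws(text)
  x <- sub("^(?i)(https?://)?(dx\\.)?doi\\.org/", "", x, perl = TRUE)
  x <- sub("^(?i)doi:\\s*", "", x, perl = TRUE)
  x <- tolower(trim_ws(x))
  x <- sub("[.,;]+$", "", x)
  if (!grepl("^10\\.[^/[:space:]]+/.+", x)) {
    ts_abort("invalid_doi", sprintf("not a DOI: '%s'", text))
  }
  x
}

#' Create a tool citation
#'
#' A citation is either a DOI (stored normalized, see [normalize_doi()])
#' or a raw BibTeX block. DOI citations compare equal on the normalized
#' value.
#'
#' @param kind `"doi"` or `"bibtex"`.
#' @param value DOI string or BibTeX text.
#' @return An object of class `citation_ref`.
#' @export
citation_ref <- function(kind = c("doi", "bibtex"), value) {
  kind <- match.arg(kind)
  if (!is_string(value) || is_blank(value)) {
    ts_abort("bad_citation", "citation value must be a nonempty string")
  }
  value <- if (kind == "doi") normalize_doi(value) else trim_ws(value)
  structure(list(kind = kind, value = value), class = "citation_ref")
}

is_citation <- function(x) inherits(x, "citation_ref")

#' @export
print.citation_ref <- function(x, ...) {
  cat("<citation> [", x$kind, "] ", x$value, "\n", sep = "")
  invisible(x)
}

citation_keys <- function(cits) {
  vapply(cits, function(x) paste0(x$kind, ":", x$value), "")
}

dedupe_citations <- function(cits) cits[!duplicated(citation_keys(cits))]

sort_citations <- function(cits) {
  vals <- vapply(cits, `[[`, "", "value")
  kinds <- vapply(cits, `[[`, "", "kind")
  cits[order(vals, kinds, method = "radix")]
}

# DOIs of the doi-kind citations of a description (bibtex excluded)
doi_set <- function(desc) {
  cits <- desc$citations
  vals <- vapply(cits, `[[`, "", "value")
  kinds <- vapply(cits, `[[`, "", "kind")
  sort(unique(vals[kinds == "doi"]))
}
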