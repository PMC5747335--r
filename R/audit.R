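# Corpus-level metadata coverage: how many descriptions carry help text,
# a description line, citations, all three at once, and EDAM operation/
# topic annotations -- plus, when a registry dump is available, the DOI
# mapping funnel: total >= has-DOI >= mapped >= annotated.

#' Audit metadata coverage of a description corpus
#'
#' Computes per-metric counts via [completeness()] and, when registry
#' entries are supplied, the DOI funnel: total descriptions, those with
#' at least one DOI citation (BibTeX-only citations do not count toward
#' this stage), those mapped one-to-one to a registry entry by
#' [match_corpus()] in strict mode, and those annotated. Annotation
#' status is taken from `annotated_flags` when given (counted among
#' mapped descriptions, so the funnel is monotone by construction);
#' without flags every mapped description is assumed annotated.
#'
#' @param descs List of [tool_description()].
#' @param entries Optional list of `registry_entry` (enables the funnel).
#' @param annotated_flags Optional logical vector, one per description.
#' @param n_failed Number of documents that could not be parsed at all
#'   (reported alongside, not part of any rate).
#' @return An object of class `coverage_report`: counts, fractions
#'   (3 decimals), and the funnel when computable.
#' @export
coverage_report <- function(descs, entries = NULL, annotated_flags = NULL,
                            n_failed = 0L) {
  n <- length(descs)
  flags <- lapply(descs, completeness)
  count_of <- function(f) sum(vapply(flags, `[[`, TRUE, f))
  counts <- list(
    n_total = n,
    n_help = if (n) count_of("has_help") else 0L,
    n_description = if (n) count_of("has_description") else 0L,
    n_citations = if (n) count_of("has_citations") else 0L,
    n_hdc = if (n) count_of("has_hdc") else 0L,
    n_operations = if (n) count_of("has_operations") else 0L,
    n_topics = if (n) count_of("has_topics") else 0L
  )
  frac <- function(k) if (n == 0L) 0 else round(k / n, 3)
  fractions <- list(
    help = frac(counts$n_help),
    description = frac(counts$n_description),
    citations = frac(counts$n_citations),
    hdc = frac(counts$n_hdc),
    operations = frac(counts$n_operations),
    topics = frac(counts$n_topics)
  )
  funnel <- NULL
  if (!is.null(entries)) {
    with_doi <- vapply(descs, function(d) length(doi_set(d)) > 0L, TRUE)
    n_with_doi <- if (n) sum(with_doi) else 0L
    matches <- match_corpus(descs, entries, mode = "strict")
    mapped <- if (n) matches$status == "matched" else logical(0)
    n_mapped <- sum(mapped)
    n_annotated <- if (is.null(annotated_flags)) {
      n_mapped
    } else {
      stopifnot(length(annotated_flags) == n)
      sum(mapped & annotated_flags)
    }
    funnel <- list(n_total = n, n_with_doi = n_with_doi,
                   n_mapped = n_mapped, n_annotated = n_annotated)
  }
  structure(
    list(counts = counts, fractions = fractions, funnel = funnel,
         n_failed = as.integer(n_failed)),
    class = "coverage_report"
  )
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("<coverage_report> n =", x$counts$n_total, "\n")
  for (m in c("help", "description", "citations", "hdc",
              "operations", "topics")) {
    key <- paste0("n_", m)
    cat(sprintf("  %-12s %5d  (%.3f)\n", m, x$counts[[key]],
                x$fractions[[m]]))
  }
  if (!is.null(x$funnel)) {
    cat(sprintf("  funnel: total %d >= with DOI %d >= mapped %d >= annotated %d\n",
                x$funnel$n_total, x$funnel$n_with_doi,
                x$funnel$n_mapped, x$funnel$n_annotated))
  }
  if (x$n_failed > 0L) cat("  failed to parse:", x$n_failed, "\n")
  invisible(x)
}

#' Serialize a coverage report to JSON
#'
#' @param report A [coverage_report()].
#' @param file Optional path; when given the JSON is written there.
#' @return The JSON string, invisibly when written to a file.
#' @export
report_to_json <- function(report, file = NULL) {
  payload <- list(counts = report$counts, fractions = report$fractions,
                  funnel = report$funnel, n_failed = report$n_failed)
  payload <- payload[!vapply(payload, is.null, TRUE)]
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE,
                          digits = NA)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(as.character(txt)))
  }
  as.character(txt)
}

#' Serialize a coverage report as TSV, one row per metric
#'
#' @param report A [coverage_report()].
#' @param file Output path.
#' @export
report_to_tsv <- function(report, file) {
  metrics <- c("total", "help", "description", "citations", "hdc",
               "operations", "topics")
  keys <- c("n_total", "n_help", "n_description", "n_citations", "n_hdc",
            "n_operations", "n_topics")
  df <- data.frame(
    metric = metrics,
    count = vapply(keys, function(k) report$counts[[k]], 0L),
    fraction = c(if (report$counts$n_total > 0L) 1 else 0,
                 vapply(metrics[-1],
                        function(m) report$fractions[[m]], 0)),
    stringsAsFactors = FALSE
  )
  if (!is.null(report$funnel)) {
    df <- rbind(df, data.frame(
      metric = c("funnel_total", "funnel_with_doi", "funnel_mapped",
                 "funnel_annotated"),
      count = c(report$funnel$n_total, report$funnel$n_with_doi,
                report$funnel$n_mapped, report$funnel$n_annotated),
      fraction = NA_real_))
  }
  df <- rbind(df, data.frame(metric = "failed", count = report$n_failed,
                             fraction = NA_real_))
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(file)
}
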