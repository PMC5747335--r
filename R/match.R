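# DOI-based record linkage between a corpus of tool descriptions and a
# registry dump. Publication identifiers are the only shared key the two
# corpora reliably carry, and they are ambiguous: one paper can describe
# several tools and one tool several papers. The strict rule is therefore
# deliberately conservative -- two records are linked only when they
# refer to, and only to, the same set of publications, and that set
# identifies both records uniquely.

doi_key <- function(dois) paste(dois, collapse = "|")

#' Match tool descriptions to registry entries by DOI
#'
#' In `strict` mode (the default) a description matches an entry iff both
#' DOI sets are nonempty and equal as sets, no other entry has that DOI
#' set, and no other description has it either (one-to-one linkage). In
#' `relaxed` mode a nonempty DOI intersection with a unique candidate
#' entry suffices. Any multiplicity yields `status = "ambiguous"` with
#' the candidate count reported -- ambiguous links are surfaced, never
#' silently dropped. Descriptions without DOI citations are `unmatched`.
#' Only DOI-kind citations participate; BibTeX citations do not.
#'
#' @param descs List of [tool_description()].
#' @param entries List of `registry_entry`.
#' @param mode `"strict"` or `"relaxed"`.
#' @return A data.frame in description order with columns `desc_id`,
#'   `entry_id` (NA unless matched), `status` (matched / ambiguous /
#'   unmatched), `shared_dois` (semicolon-joined), `n_candidates`, `mode`.
#' @export
match_corpus <- function(descs, entries, mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  desc_ids <- vapply(descs, `[[`, "", "id")
  desc_sets <- lapply(descs, doi_set)
  entry_ids <- vapply(entries, `[[`, "", "biotools_id")
  entry_sets <- lapply(entries, function(e) {
    kinds <- vapply(e$publications, `[[`, "", "kind")
    vals <- vapply(e$publications, `[[`, "", "value")
    sort(unique(vals[kinds == "doi"]))
  })

  desc_keys <- vapply(desc_sets, doi_key, "")
  entry_keys <- vapply(entry_sets, doi_key, "")

  rows <- lapply(seq_along(descs), function(i) {
    d_set <- desc_sets[[i]]
    if (length(d_set) == 0L) {
      return(list(desc_id = desc_ids[i], entry_id = NA_character_,
                  status = "unmatched", shared_dois = "",
                  n_candidates = 0L))
    }
    if (mode == "strict") {
      cand <- which(entry_keys == desc_keys[i] & nzchar(entry_keys))
      dup_descs <- sum(desc_keys == desc_keys[i])
      if (length(cand) == 1L && dup_descs == 1L) {
        list(desc_id = desc_ids[i], entry_id = entry_ids[cand],
             status = "matched",
             shared_dois = paste(d_set, collapse = ";"),
             n_candidates = 1L)
      } else if (length(cand) == 0L) {
        list(desc_id = desc_ids[i], entry_id = NA_character_,
             status = "unmatched", shared_dois = "",
             n_candidates = 0L)
      } else {
        # several candidate entries, or several descriptions with this
        # DOI set competing for them
        list(desc_id = desc_ids[i], entry_id = NA_character_,
             status = "ambiguous",
             shared_dois = paste(d_set, collapse = ";"),
             n_candidates = length(cand))
      }
    } else {
      overlap <- vapply(entry_sets, function(s) {
        length(intersect(s, d_set)) > 0L
      }, TRUE)
      cand <- which(overlap)
      if (length(cand) == 1L) {
        list(desc_id = desc_ids[i], entry_id = entry_ids[cand],
             status = "matched",
             shared_dois = paste(intersect(entry_sets[[cand]], d_set),
                                 collapse = ";"),
             n_candidates = 1L)
      } else if (length(cand) == 0L) {
        list(desc_id = desc_ids[i], entry_id = NA_character_,
             status = "unmatched", shared_dois = "",
             n_candidates = 0L)
      } else {
        list(desc_id = desc_ids[i], entry_id = NA_character_,
             status = "ambiguous",
             shared_dois = paste(d_set, collapse = ";"),
             n_candidates = length(cand))
      }
    }
  })
  out <- data.frame(
    desc_id = vapply(rows, `[[`, "", "desc_id"),
    entry_id = vapply(rows, `[[`, "", "entry_id"),
    status = vapply(rows, `[[`, "", "status"),
    shared_dois = vapply(rows, `[[`, "", "shared_dois"),
    n_candidates = vapply(rows, `[[`, 0L, "n_candidates"),
    stringsAsFactors = FALSE
  )
  out$mode <- mode
  out
}

#' Write a match table as TSV
#'
#' @param matches Result of [match_corpus()].
#' @param file Output path.
#' @export
write_match_tsv <- function(matches, file) {
  utils::write.table(
    matches[, c("desc_id", "entry_id", "status", "shared_dois")],
    file, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(file)
}
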