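# Independent brute-force oracle for DOI-based matching: explicit
# pairwise set comparisons, no shared code with match_corpus().

oracle_match <- function(desc_sets, entry_sets, mode = "strict") {
  vapply(seq_along(desc_sets), function(i) {
    d <- desc_sets[[i]]
    if (length(d) == 0L) return("unmatched")
    if (mode == "strict") {
      cand <- 0L
      for (e in entry_sets) {
        if (length(e) && setequal(d, e)) cand <- cand + 1L
      }
      twins <- 0L
      for (d2 in desc_sets) if (setequal(d, d2)) twins <- twins + 1L
      if (cand == 0L) "unmatched"
      else if (cand == 1L && twins == 1L) "matched"
      else "ambiguous"
    } else {
      cand <- 0L
      for (e in entry_sets) {
        if (length(intersect(d, e)) > 0L) cand <- cand + 1L
      }
      if (cand == 0L) "unmatched"
      else if (cand == 1L) "matched"
      else "ambiguous"
    }
  }, "")
}

# build descriptions / registry entries holding given DOI sets
desc_with_dois <- function(id, dois) {
  tool_description(id, citations = lapply(dois, function(d)
    citation_ref("doi", d)))
}

entry_with_dois <- function(id, dois) {
  parse_registry_entry(list(
    name = id, biotoolsID = id,
    publication = lapply(dois, function(d)
      list(doi = d, type = "Primary"))))
}

# random DOI-set corpora over a small universe (collisions are the point)
random_doi_corpus <- function(n_desc, n_entry, universe_size = 12L) {
  universe <- sprintf("10.5555/u.%d", seq_len(universe_size))
  draw <- function() sample(universe, sample(0:3, 1))
  list(
    desc_sets = replicate(n_desc, draw(), simplify = FALSE),
    entry_sets = replicate(n_entry, draw(), simplify = FALSE)
  )
}

minimal_entry <- function(id = "reg1", doi = "10.1000/x",
                          topics = "topic_0622",
                          operations = "operation_0004",
                          description = "registry description") {
  parse_registry_entry(list(
    name = paste("Entry", id), biotoolsID = id,
    description = description,
    homepage = "https://example.org/tool",
    topic = lapply(topics, function(a)
      list(uri = paste0("http://edamontology.org/", a))),
    `function` = list(list(operation = lapply(operations, function(a)
      list(uri = paste0("http://edamontology.org/", a))))),
    publication = list(list(doi = doi, type = "Primary"))))
}
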