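test_that("unique exact DOI sets match one-to-one in strict mode", {
  descs <- list(desc_with_dois("d1", "10.1000/a"))
  entries <- list(entry_with_dois("e1", "10.1000/a"))
  m <- match_corpus(descs, entries, mode = "strict")
  expect_equal(m$status, "matched")
  expect_equal(m$entry_id, "e1")
  expect_equal(m$shared_dois, "10.1000/a")
})

test_that("duplicated registry DOI sets yield ambiguity, not a match", {
  descs <- list(desc_with_dois("d1", "10.1000/a"))
  entries <- list(entry_with_dois("e1", "10.1000/a"),
                  entry_with_dois("e2", "10.1000/a"))
  m <- match_corpus(descs, entries, mode = "strict")
  expect_equal(m$status, "ambiguous")
  expect_true(is.na(m$entry_id))
  expect_equal(m$n_candidates, 2L)
  # brute-force confirmation
  expect_equal(oracle_match(list("10.1000/a"),
                            list("10.1000/a", "10.1000/a")), "ambiguous")
})

test_that("set equality vs intersection separates strict from relaxed", {
  descs <- list(desc_with_dois("d1", c("10.1000/a", "10.1000/b")))
  entries <- list(entry_with_dois("e1", "10.1000/a"))
  strict <- match_corpus(descs, entries, mode = "strict")
  relaxed <- match_corpus(descs, entries, mode = "relaxed")
  expect_equal(strict$status, "unmatched")
  expect_equal(relaxed$status, "matched")
  # oracle agrees on the same pair
  ds <- list(c("10.1000/a", "10.1000/b")); es <- list("10.1000/a")
  expect_equal(oracle_match(ds, es, "strict"), "unmatched")
  expect_equal(oracle_match(ds, es, "relaxed"), "matched")
})

test_that("descriptions without DOIs are unmatched; BibTeX does not count", {
  d_bib <- tool_description("d1", citations = list(
    citation_ref("bibtex", "@article{k, title={x}}")))
  m <- match_corpus(list(d_bib),
                    list(entry_with_dois("e1", "10.1000/a")))
  expect_equal(m$status, "unmatched")
})

test_that("two descriptions sharing a DOI set are both ambiguous", {
  descs <- list(desc_with_dois("d1", "10.1000/a"),
                desc_with_dois("d2", "10.1000/a"))
  entries <- list(entry_with_dois("e1", "10.1000/a"))
  m <- match_corpus(descs, entries, mode = "strict")
  expect_equal(m$status, c("ambiguous", "ambiguous"))
})

test_that("matcher agrees with the brute-force oracle on random corpora", {
  set.seed(31)
  for (rep in 1:40) {
    co <- random_doi_corpus(sample(1:25, 1), sample(1:25, 1))
    descs <- lapply(seq_along(co$desc_sets), function(i) {
      desc_with_dois(sprintf("d%03d", i), co$desc_sets[[i]])
    })
    entries <- lapply(seq_along(co$entry_sets), function(j) {
      entry_with_dois(sprintf("e%03d", j), co$entry_sets[[j]])
    })
    for (mode in c("strict", "relaxed")) {
      got <- match_corpus(descs, entries, mode = mode)$status
      want <- oracle_match(co$desc_sets, co$entry_sets, mode)
      expect_identical(got, want)
    }
  }
})

test_that("permuting description order permutes results identically", {
  set.seed(32)
  co <- random_doi_corpus(12, 12)
  descs <- lapply(seq_along(co$desc_sets), function(i) {
    desc_with_dois(sprintf("d%03d", i), co$desc_sets[[i]])
  })
  entries <- lapply(seq_along(co$entry_sets), function(j) {
    entry_with_dois(sprintf("e%03d", j), co$entry_sets[[j]])
  })
  base <- match_corpus(descs, entries)
  perm <- sample(length(descs))
  shuffled <- match_corpus(descs[perm], entries)
  reordered <- shuffled[match(base$desc_id, shuffled$desc_id), ]
  rownames(reordered) <- NULL
  expect_identical(base, reordered)
})

test_that("coverage counts, fractions and degenerate corpora behave", {
  full <- tool_description("d1", description = "d", help_text = "h",
                           citations = list(citation_ref("doi", "10.1/a")),
                           topics = list(edam_term("topic_0622")),
                           operations = list(edam_term("operation_0004")))
  empty <- tool_description("d2")
  rep2 <- coverage_report(list(full, empty))
  expect_equal(rep2$counts$n_total, 2)
  expect_equal(rep2$fractions$help, 0.5)
  expect_equal(rep2$fractions$hdc, 0.5)
  rep0 <- coverage_report(list())
  expect_true(all(unlist(rep0$counts) == 0))
  expect_true(all(unlist(rep0$fractions) == 0))
})

test_that("the funnel is monotone and serializes to JSON and TSV", {
  co <- generate_corpus(corpus_config(n_tools = 120, seed = 5))
  descs <- lapply(co$galaxy_docs, parse_galaxy)
  rep <- coverage_report(descs, entries = co$registry)
  f <- rep$funnel
  expect_true(f$n_total >= f$n_with_doi)
  expect_true(f$n_with_doi >= f$n_mapped)
  expect_true(f$n_mapped >= f$n_annotated)
  tf_json <- tempfile(fileext = ".json")
  report_to_json(rep, tf_json)
  parsed <- jsonlite::fromJSON(tf_json)
  expect_named(parsed, c("counts", "fractions", "funnel", "n_failed"))
  expect_equal(parsed$funnel$n_total, f$n_total)
  tf_tsv <- tempfile(fileext = ".tsv")
  report_to_tsv(rep, tf_tsv)
  tab <- utils::read.delim(tf_tsv)
  expect_equal(names(tab), c("metric", "count", "fraction"))
  expect_true(all(c("help", "hdc", "funnel_mapped") %in% tab$metric))
})

test_that("annotated flags are counted among mapped descriptions only", {
  co <- generate_corpus(corpus_config(n_tools = 60, seed = 6,
                                      ambiguity_rate = 0))
  descs <- lapply(co$galaxy_docs, parse_galaxy)
  flags <- rep(c(TRUE, FALSE), length.out = length(descs))
  rep1 <- coverage_report(descs, entries = co$registry,
                          annotated_flags = flags)
  expect_true(rep1$funnel$n_annotated <= rep1$funnel$n_mapped)
  # all-false flags: nothing annotated
  rep2 <- coverage_report(descs, entries = co$registry,
                          annotated_flags = rep(FALSE, length(descs)))
  expect_equal(rep2$funnel$n_annotated, 0)
})
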