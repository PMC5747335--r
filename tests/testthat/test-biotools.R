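test_that("registry entries map their recognized fields", {
  e <- parse_registry_entry(list(
    name = "T", biotoolsID = "t",
    topic = list(list(uri = "http://edamontology.org/topic_0622",
                      term = "Genomics"))))
  expect_equal(vapply(e$topics, `[[`, "", "accession"), "topic_0622")
  expect_equal(e$topics[[1]]$label, "Genomics")
  # no function block: parse succeeds with empty functions
  expect_length(e$functions, 0)
})

test_that("a missing name aborts, unknown fields do not", {
  expect_error(parse_registry_entry(list(biotoolsID = "x")),
               class = "toolscribe_missing_field")
  e <- parse_registry_entry(list(name = "T", biotoolsID = "t",
                                 somethingNovel = "ignored"))
  expect_equal(e$biotools_id, "t")
})

test_that("publication DOIs are normalized at parse time", {
  e <- parse_registry_entry(list(
    name = "T", biotoolsID = "t",
    publication = list(list(doi = "HTTPS://DOI.ORG/10.1000/X"),
                       list(pmid = "123456"))))
  dois <- Filter(function(p) p$kind == "doi", e$publications)
  # oracle: the standalone normalizer applied by hand
  expect_equal(dois[[1]]$value, normalize_doi("HTTPS://DOI.ORG/10.1000/X"))
  expect_equal(dois[[1]]$value, "10.1000/x")
  pmids <- Filter(function(p) p$kind == "pmid", e$publications)
  expect_length(pmids, 1)  # retained on the entry ...
  m <- entry_to_model(e)
  expect_length(m$citations, 1)  # ... but only DOIs become citations
  expect_equal(m$citations[[1]]$kind, "doi")
})

test_that("registry dumps load with partial tolerance", {
  tf <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    list(name = "A", biotoolsID = "a"),
    list(biotoolsID = "no_name"),
    list(name = "C", biotoolsID = "c")
  ), tf, auto_unbox = TRUE)
  entries <- load_registry_dump(tf)
  expect_length(entries, 2)
  expect_equal(vapply(entries, `[[`, "", "biotools_id"), c("a", "c"))
  fails <- attr(entries, "failures")
  expect_length(fails, 1)
  expect_equal(fails[[1]]$index, 2)
  # empty dump: empty list plus a warning
  tf2 <- tempfile(fileext = ".json")
  writeLines("[]", tf2)
  expect_warning(e2 <- load_registry_dump(tf2),
                 class = "toolscribe_empty_dump")
  expect_length(e2, 0)
})

test_that("entry_to_model unions operations and uses the first function", {
  e <- parse_registry_entry(list(
    name = "T", biotoolsID = "t",
    `function` = list(
      list(operation = list(list(uri = "http://edamontology.org/operation_0004")),
           input = list(
             list(data = list(uri = "http://edamontology.org/data_0006"),
                  format = list(list(uri = "http://edamontology.org/format_1929"))),
             list(data = list(uri = "http://edamontology.org/data_2044")))),
      list(operation = list(list(uri = "http://edamontology.org/operation_2403")),
           input = list(list(data = list(uri = "http://edamontology.org/data_1383")))))))
  m <- entry_to_model(e)
  expect_setequal(vapply(m$operations, `[[`, "", "accession"),
                  c("operation_0004", "operation_2403"))
  # first function only; stated naming rule input_<k>, file-typed
  expect_equal(vapply(m$inputs, `[[`, "", "name"), c("input_1", "input_2"))
  expect_true(all(vapply(m$inputs, `[[`, "", "value_type") == "file"))
  expect_equal(m$inputs[[1]]$edam_data$accession, "data_0006")
  expect_equal(m$command_template, "")
  # zero functions: degenerate model
  e0 <- parse_registry_entry(list(name = "T", biotoolsID = "t"))
  m0 <- entry_to_model(e0)
  expect_length(m0$inputs, 0)
  expect_length(m0$outputs, 0)
})

test_that("entry help text lists homepage and documentation, labeled", {
  e <- parse_registry_entry(list(
    name = "T", biotoolsID = "t", description = "does x",
    homepage = "https://example.org",
    documentation = list(list(url = "https://example.org/docs",
                              type = "documentation"))))
  m <- entry_to_model(e)
  lines <- strsplit(m$help_text, "\n")[[1]]
  expect_equal(lines[1], "does x")
  expect_equal(lines[2], "Homepage: https://example.org")
  expect_equal(lines[3], "Documentation: https://example.org/docs")
})

test_that("entries round-trip through their JSON serialization", {
  e <- minimal_entry("rt1", doi = "10.1000/rt")
  e2 <- parse_registry_entry(entry_to_json(e))
  expect_identical(e, e2)
  # and through a dump file
  tf <- tempfile(fileext = ".json")
  write_registry_dump(list(e), tf)
  e3 <- load_registry_dump(tf)[[1]]
  expect_identical(e, e3)
})

test_that("models derived from entries have no duplicate terms or DOIs", {
  e <- parse_registry_entry(list(
    name = "T", biotoolsID = "t",
    `function` = list(
      list(operation = list(list(uri = "http://edamontology.org/operation_0004"))),
      list(operation = list(list(uri = "http://edamontology.org/operation_0004")))),
    publication = list(list(doi = "10.1000/x"),
                       list(doi = "https://doi.org/10.1000/X"))))
  m <- entry_to_model(e)
  expect_length(m$operations, 1)
  expect_length(m$citations, 1)
  # DOI normalization is a fixed point across the module boundary
  expect_equal(m$citations[[1]]$value,
               normalize_doi(m$citations[[1]]$value))
})
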