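test_that("EDAM terms validate accessions and infer branch", {
  t <- edam_term("topic_0622", "Genomics")
  expect_equal(t$uri, "http://edamontology.org/topic_0622")
  expect_equal(edam_branch(t), "topic")
  u <- edam_term("http://edamontology.org/format_1929")
  expect_equal(u$accession, "format_1929")
  expect_error(edam_term("topic_62"), class = "toolscribe_bad_edam")
  expect_error(edam_term("pathway_0001"), class = "toolscribe_bad_edam")
})

test_that("branch-contradicting terms are rejected at construction", {
  expect_error(
    tool_description("t", topics = list(edam_term("format_1929"))),
    class = "toolscribe_bad_edam_branch")
  expect_error(
    tool_description("t", operations = list(edam_term("topic_0622"))),
    class = "toolscribe_bad_edam_branch")
  expect_error(
    tool_parameter("p", edam_data = edam_term("format_1929")),
    class = "toolscribe_bad_edam_branch")
})

test_that("description construction enforces core invariants", {
  expect_error(tool_description("has space"),
               class = "toolscribe_bad_description")
  expect_error(tool_description(""), class = "toolscribe_bad_description")
  p <- tool_parameter("x")
  expect_error(tool_description("t", inputs = list(p, p)),
               class = "toolscribe_bad_description")
  expect_error(tool_parameter("sel", "choice"),
               class = "toolscribe_bad_parameter")
  expect_error(tool_parameter("s", "string", choices = c("a")),
               class = "toolscribe_bad_parameter")
  # duplicates collapse by accession / normalized DOI
  d <- tool_description("t",
    topics = list(edam_term("topic_0622"), edam_term("topic_0622")),
    citations = list(citation_ref("doi", "10.1000/x"),
                     citation_ref("doi", "https://doi.org/10.1000/X")))
  expect_length(d$topics, 1)
  expect_length(d$citations, 1)
})

test_that("additive merge fills gaps and never overwrites", {
  base <- tool_description("t", description = "X",
                           command_template = "run_t")
  extra <- tool_description("t", description = "Y", help_text = "H",
                            citations = list(citation_ref("doi",
                                                          "10.1000/x")))
  m <- merge_metadata(base, extra)
  expect_equal(m$description, "X")          # no-overwrite rule
  expect_equal(m$help_text, "H")            # fill of an empty field
  expect_length(m$citations, 1)
  expect_equal(m$command_template, "run_t") # structural core untouched
  # identity
  d <- extra
  expect_true(desc_identical(merge_metadata(d, d), d))
})

test_that("merge unions list metadata with base elements first", {
  base <- tool_description("t", topics = list(edam_term("topic_0080")))
  extra <- tool_description("t",
    topics = list(edam_term("topic_0622"), edam_term("topic_0080")))
  m <- merge_metadata(base, extra)
  expect_equal(vapply(m$topics, `[[`, "", "accession"),
               c("topic_0080", "topic_0622"))
})

test_that("overwrite policy lets nonempty extra scalars win", {
  base <- tool_description("t", description = "old")
  extra <- tool_description("t", description = "new")
  expect_equal(merge_metadata(base, extra, policy = "overwrite")$description,
               "new")
  # but an empty extra never erases
  empty <- tool_description("t")
  expect_equal(merge_metadata(base, empty, policy = "overwrite")$description,
               "old")
})

test_that("the unknown-version sentinel behaves as an empty scalar", {
  base <- tool_description("t")              # version "unknown"
  extra <- tool_description("t", version = "2.1")
  expect_equal(merge_metadata(base, extra)$version, "2.1")
  expect_equal(merge_metadata(extra, base)$version, "2.1")
})

test_that("merge is idempotent and completeness-monotone on random pairs", {
  ds <- random_descriptions(40, seed = 101)
  for (i in seq(1, 39, by = 2)) {
    b <- ds[[i]]; e <- ds[[i + 1]]
    m1 <- merge_metadata(b, e)
    m2 <- merge_metadata(m1, e)
    expect_true(desc_identical(m1, m2))
    fb <- unlist(completeness(b))
    fm <- unlist(completeness(m1))
    expect_true(all(fm >= fb))
  }
})

test_that("completeness reflects field presence, hdc is the conjunction", {
  full <- tool_description("t", description = "d", help_text = "h",
                           citations = list(citation_ref("doi",
                                                         "10.1/a")),
                           topics = list(edam_term("topic_0622")),
                           operations = list(edam_term("operation_0004")))
  expect_true(all(unlist(completeness(full))))
  empty <- tool_description("t")
  expect_false(any(unlist(completeness(empty))))
  # help + description but no citations: the conjunction fails
  hd <- tool_description("t", description = "d", help_text = "h")
  fl <- completeness(hd)
  expect_true(fl$has_help && fl$has_description)
  expect_false(fl$has_hdc)
  # whitespace-only help does not count
  ws <- tool_description("t", help_text = "  \n\t ")
  expect_false(completeness(ws)$has_help)
})

test_that("canonicalize sorts, is idempotent and order-insensitive", {
  t1 <- edam_term("topic_0080"); t2 <- edam_term("topic_0622")
  t3 <- edam_term("topic_3168")
  d <- tool_description("t", topics = list(t2, t1))
  expect_equal(vapply(canonicalize(d)$topics, `[[`, "", "accession"),
               c("topic_0080", "topic_0622"))
  expect_identical(canonicalize(canonicalize(d)), canonicalize(d))
  # all 3! orderings of a 3-term list canonicalize identically
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  canon <- lapply(perms, function(p) {
    canonicalize(tool_description("t", topics = list(t1, t2, t3)[p]))
  })
  for (i in 2:6) expect_identical(canon[[1]], canon[[i]])
})
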