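worked_spec <- function() {
  parse_clispec(list(
    program = "integron_finder",
    description = "identify integrons in bacterial genomes",
    arguments = list(
      list(kind = "positional", dest = "replicon", type = "file",
           help = "input genome"),
      list(kind = "option", dest = "threads", flags = list("-t", "--threads"),
           type = "integer", default = 4L),
      list(kind = "flag", dest = "local_max", flags = list("--local-max"))
    )))
}

test_that("CLI specs parse with order, defaults and type checks", {
  spec <- worked_spec()
  expect_equal(spec$program, "integron_finder")
  expect_length(spec$arguments, 3)
  expect_equal(spec$arguments[[1]]$kind, "positional")
  expect_equal(spec$arguments[[2]]$default, 4L)
  # flag kind implies boolean, default off
  expect_equal(spec$arguments[[3]]$value_type, "boolean")
  expect_false(spec$arguments[[3]]$default)
})

test_that("bad CLI specs raise the right classed errors", {
  expect_error(parse_clispec(list(program = "p", arguments = list(
    list(kind = "option", dest = "k", flags = list("-k"),
         type = "integer", default = "abc")))),
    class = "toolscribe_type_mismatch")
  expect_error(parse_clispec(list(program = "p", arguments = list(
    list(kind = "option", dest = "k", flags = list("-k")),
    list(kind = "positional", dest = "k", type = "file")))),
    class = "toolscribe_duplicate_dest")
  expect_error(parse_clispec(list(arguments = list())),
               class = "toolscribe_missing_field")
})

test_that("CLI specs load from JSON and YAML files alike", {
  tf_json <- tempfile(fileext = ".json")
  writeLines('{"program": "p", "arguments": [
    {"kind": "positional", "dest": "genome", "type": "file"}]}', tf_json)
  s1 <- parse_clispec(tf_json)
  expect_equal(s1$arguments[[1]]$dest, "genome")
  tf_yaml <- tempfile(fileext = ".yml")
  writeLines(c("program: p", "arguments:",
               "- kind: positional", "  dest: genome", "  type: file"),
             tf_yaml)
  expect_identical(parse_clispec(tf_yaml), s1)
})

test_that("command templates follow the stated grammar", {
  spec <- parse_clispec(list(program = "p", arguments = list(
    list(kind = "option", dest = "k", flags = list("--k"),
         type = "integer"),
    list(kind = "positional", dest = "f", type = "file"))))
  expect_equal(render_command(spec), "p --k $k $f")
  # no arguments: bare program
  expect_equal(render_command(parse_clispec(list(program = "p"))), "p")
  # flags-only: every token guarded, no bare flags
  spec3 <- parse_clispec(list(program = "p", arguments = list(
    list(kind = "flag", dest = "a", flags = list("-a")),
    list(kind = "flag", dest = "b", flags = list("-b")),
    list(kind = "flag", dest = "c", flags = list("-c")))))
  cmd <- render_command(spec3)
  for (tok in c("a", "b", "c")) {
    guarded <- sprintf("#if $%s#-%s#end if#", tok, tok)
    expect_match(cmd, guarded, fixed = TRUE)
  }
  expect_false(grepl("(^| )-[abc]( |$)", cmd))  # no unguarded flags
})

test_that("every dest appears exactly once in the template", {
  spec <- worked_spec()
  cmd <- render_command(spec)
  for (a in spec$arguments) {
    hits <- gregexpr(paste0("\\$", a$dest, "\\b"), cmd)[[1]]
    expect_length(hits[hits > 0], 1)
  }
})

test_that("skeletons carry one parameter per argument, built as stated", {
  spec <- worked_spec()
  d <- skeleton_from_clispec(spec)
  expect_equal(d$id, "integron_finder")
  expect_length(d$inputs, 3)
  # field-by-field against the stated construction
  p1 <- d$inputs[[1]]
  expect_equal(p1$value_type, "file")
  expect_equal(p1$cli_binding$position, 1L)
  p2 <- d$inputs[[2]]
  expect_equal(p2$value_type, "integer")
  expect_equal(p2$default, 4L)
  expect_equal(p2$cli_binding$flag, "--threads")  # longest flag wins
  p3 <- d$inputs[[3]]
  expect_equal(p3$value_type, "boolean")
  expect_false(p3$default)
  expect_equal(p3$cli_binding$flag, "--local-max")
  # one placeholder output without a collection pattern (the stated gap)
  expect_length(d$outputs, 1)
  expect_null(d$outputs[[1]]$from_pattern)
  expect_true(nzchar(d$command_template))
})

test_that("choice options become choice parameters", {
  spec <- parse_clispec(list(program = "p", arguments = list(
    list(kind = "option", dest = "mode", flags = list("--mode"),
         type = "choice", choices = list("a", "b")))))
  d <- skeleton_from_clispec(spec)
  expect_equal(d$inputs[[1]]$value_type, "choice")
  expect_equal(d$inputs[[1]]$choices, c("a", "b"))
})

test_that("registry metadata merges into the skeleton without touching structure", {
  entry <- minimal_entry("bt_if", doi = "10.1000/if")
  d <- skeleton_from_clispec(worked_spec(), merge_with = entry)
  expect_length(d$inputs, 3)                      # structure intact
  expect_equal(d$command_template,
               render_command(worked_spec()))
  expect_length(d$citations, 1)                   # metadata merged
  expect_equal(vapply(d$topics, `[[`, "", "accession"), "topic_0622")
})

test_that("skeleton parameter count is conserved through Galaxy emission", {
  spec <- worked_spec()
  x <- write_galaxy(skeleton_from_clispec(spec))
  n_params <- length(xml2::xml_find_all(xml2::read_xml(x),
                                        "//inputs/param"))
  expect_equal(n_params, length(spec$arguments))
})
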