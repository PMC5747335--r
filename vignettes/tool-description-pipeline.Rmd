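---
title: "Generating, enriching and auditing workbench tool descriptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating, enriching and auditing workbench tool descriptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toolscribe)
```

## The model

Every reader and writer in the package works through one format-neutral
object model, `tool_description`. It separates a description into a
*structural core* — typed parameters with command-line bindings, output
specifications, the command template — and *metadata* — a description
line, help text, citations (DOI or BibTeX), EDAM topic and operation
annotations, documentation links, license, version. The two halves have
different provenance: structure comes from interface introspection (or a
registry entry's typed function signature), metadata comes from the
registry. Enrichment operates on metadata only and never modifies the
structural core; this is an invariant of `merge_metadata()`, not a
convention.

EDAM terms are typed by branch (`topic`, `operation`, `data`, `format`),
inferred from the accession prefix, and a term in the wrong slot (a
format term among topics) is rejected when the object is constructed.
That choice makes the branch invariants testable at every module
boundary instead of at serialization time. Validation is syntactic —
the accession pattern `(topic|operation|data|format)_[0-9]{4}` — not
semantic: terms are not resolved against the ontology graph, so a
well-formed but retired accession passes.

## Additive merging

`merge_metadata(base, extra)` is additive by default: an empty scalar of
`base` (empty after ASCII-whitespace trimming — whitespace-only help
sections occur in real corpora) takes `extra`'s value; a nonempty scalar
is never changed; list metadata becomes the deduplicated union with
`base`'s elements first. The version string has a sentinel, `"unknown"`,
which merging treats as empty. Whether enrichment should add EDAM terms
to a description that already carries *different* terms is genuinely
open; the package unions them, on the view that enrichment completes and
a wrong existing term is an authoring error outside its mandate. The
non-default `overwrite` policy (extra's nonempty scalars win) exists for
deliberate correction runs and is never implied by any other operation.

Two consequences worth stating: merging is idempotent
(`merge(merge(b, e), e) = merge(b, e)`), and the six completeness flags
are monotone under merging — enrichment can only gain metadata.

## Formats and determinism

Both serializers first canonicalize the description (terms sorted by
accession, citations by value, links by kind then URL, scalars trimmed)
and then emit a fixed layout: Galaxy XML with 2-space indentation,
attributes in the order id/name/version and child blocks in a fixed
order; CWL YAML with a fixed key order. Determinism is what makes the
enrichment contract checkable at the byte level: the second enrichment
of a file is a no-op *as bytes*, not merely as a model.

Parsing stores any unrecognized content — child elements of `<tool>`
outside the supported subset, top-level YAML keys outside the supported
set — in an opaque passthrough store that the writer re-emits. A
parse/enrich/write cycle therefore never destroys an author's `<tests>`
section or a vendor extension key. Passthrough content is opaque by
design: it is not part of model equality.

The two dialects cannot represent exactly the same information, and the
package treats the differences as documented conventions rather than
hiding them:

* CWL has no native version field; the writer emits
  `s:softwareVersion` in the metadata block. It has no help field
  either; `doc` carries the description and, after a blank line, the
  help text. The parser splits at the first blank line, which is exact
  as long as the description is a single paragraph — the model treats it
  as a one-line summary.
* CWL keeps only the first token of a command template as
  `baseCommand`; the full mapping is carried by `inputBinding`
  prefixes/positions instead. Galaxy keeps the whole template verbatim,
  `$` placeholders included.
* Galaxy has no attribute for a parameter's `data`-branch EDAM term or
  for command-line bindings; the `format` attribute carries
  comma-separated EDAM format accessions (this package's convention —
  stock Galaxy uses datatype extensions there), and EDAM topic and
  operation tags carry bare accessions as element text.
* `license` and documentation links live in the model (they come from
  registry entries) but in neither output dialect.
* The Galaxy `optional` attribute is emitted exactly when a parameter is
  not required and has no default; on parse, a parameter with a default
  is taken as not required. A required parameter *with* a default is
  thus not representable in the Galaxy dialect, which is consistent with
  how such parameters behave on a command line.

Round-trip identity (`parse(write(d))` equals `canonicalize(d)`) and
cross-format agreement therefore hold on the shared representable
subset, and the random-description generator used by the property
harnesses samples exactly that subset: single-token command templates,
descriptions present whenever help is, no defaults on required
parameters, no per-parameter `data` terms, empty license/links. The
registry-to-model map is deliberately wider than this subset; what it
adds beyond the subset (license, links) simply does not survive
serialization, and nothing downstream depends on it surviving.

## Registry mapping

`entry_to_model()` maps a registry entry onto the model: topics copied;
operations unioned over *all* registry functions; DOI publications
normalized and turned into citations, primary publications first
(PMID/PMCID identifiers are parsed and kept on the entry but do not
cross over — workbench citation blocks anchor on DOI or BibTeX); help
text composed from the description, homepage and documentation links,
one labeled line each. Structure comes from the *first* function only:
a workbench description wraps one command, and a multi-function entry
does not say which function that command implements. Registry inputs
become file-typed parameters named `input_1`, `input_2`, ... — registry
functions describe data flows, not scalar flags. The command template is
left empty and the single generated output has no filename pattern:
neither mapping exists in registry metadata, and both are flagged for
the author rather than guessed.

## CLI specifications

The generation module starts from a declarative JSON/YAML description
of a program's interface rather than from source code: running
third-party code to introspect it is excluded for safety and
portability, and the declarative payload is what a language-specific
introspection plugin would emit anyway. Flags become boolean parameters
(default off); the longest flag string is kept as the binding
(`--threads` over `-t`) for readable wrappers; positionals are bound by
their order. The rendered command template lists options in declaration
order as `FLAG $dest`, boolean flags as guarded tokens
(`#if $dest#FLAG#end if#`) so no flag appears unconditionally, then
positionals as bare `$dest` — every destination token exactly once.
Repeatable arguments map to `multiple`/array types; more exotic arities
(fixed counts, "one or more" with separators) are out of scope and
rejected at parse time rather than approximated.

## DOI matching

`normalize_doi()` strips resolver prefixes and case and trailing
punctuation; every DOI in the system is stored in this canonical form,
so matching is exact string-set comparison. The strict rule links a
description to an entry only when (i) both DOI sets are nonempty and
equal as sets, (ii) no other entry has that DOI set, and (iii) no other
description has it either. Publication identifiers are genuinely
ambiguous keys — one paper can describe several tools — and every
violation of uniqueness is reported as `ambiguous` with the candidate
count, never dropped: the ambiguous population is exactly what a curator
needs to inspect. The relaxed mode (nonempty intersection, unique
candidate entry) trades precision for recall and is never the default.
BibTeX citations count toward the `has_citations` coverage flag but not
toward DOI matching or the funnel's has-DOI stage, which distinguishes
"cites something" from "citable by identifier".

The matcher is verified against an independent brute-force oracle
(explicit pairwise set comparison) on randomized corpora, including
planted ambiguities.

## Coverage audits and the funnel

`coverage_report()` counts the six completeness flags over a corpus and
reports fractions to three decimals. With a registry dump it also
computes the funnel *total ≥ has-DOI ≥ mapped ≥ annotated*: mapped uses
the strict matcher; annotated is taken from caller-supplied flags
counted among mapped descriptions (so the funnel is monotone by
construction), because "successfully annotated" depends on what the
caller did with the mapping — the acceptance script, for instance,
enriches every mapped description and checks that both EDAM branches are
present afterwards. Without flags, every mapped description is assumed
annotated. Reports serialize to JSON and to a one-row-per-metric TSV;
documents that fail to parse at all are counted in a separate `failed`
field and excluded from every rate.

## The synthetic corpus

`generate_corpus()` emulates a real workbench corpus: each tool's
metadata fields are planted independently at configured rates, planted
DOIs use the reserved `10.5555/` example prefix, a configurable fraction
of DOIs also appears in the registry dump, extra registry entries have
no corpus counterpart, and a small ambiguity rate duplicates a DOI
across two registry entries. The defaults — 665 tools, citation rate
0.60, registry-link rate 0.56, ambiguity 0.03, help 0.85, description
0.90, EDAM 0.10 — describe a corpus in which most tools are documented,
citations are the weak point, EDAM annotation is rare, and roughly a
third of the corpus can be mapped to the registry; they are fixed
properties of the generator, chosen once as realistic study conditions.
The generator emits real files in the exact dialects of the format
modules (`tools/*.xml`, `registry.json`, `truth.tsv`), so the
command-line layer is exercised end to end, and the same seed yields
byte-identical output.

What the generator does *not* emulate: realistic help prose, Galaxy
conditionals/repeats and macros, CWL corpora (a Galaxy corpus suffices
to exercise the audit), version skew between description and registry,
and DOI typos — its DOIs are exact by construction. Passing tests on
synthetic corpora therefore demonstrate the pipeline's contracts
(determinism, idempotence, monotonicity, matcher correctness), not
robustness to dirty real-world metadata.

## Problem sizes and numerical choices

The test suite runs 100-description round-trip harnesses per format, 50
enrichment pairs, 200 random matcher corpora up to 50×50 against the
brute-force oracle, and a 1000-tool corpus for rate recovery (each
observed rate is required to sit within three binomial standard errors
of its planted rate, and counts must agree with the truth table
exactly). Sorting uses radix order on ASCII strings, so canonical order
is locale-independent. Ties cannot arise in term sorting (accessions are
unique within a list after deduplication); citation order is by value
then kind. Fractions are rounded half-even to three decimals only at the
reporting boundary; internal comparisons use counts.

## Limitations

* Galaxy conditionals, repeats, macro expansion and the YAML variant of
  Galaxy tools are not parsed; such content survives only as
  passthrough.
* CWL expressions, Docker hints and Workflow documents are out of scope
  (`class: Workflow` is rejected).
* EDAM validation is syntactic; no ontology lookup.
* Matching is DOI-only by design: no fuzzy name or homepage matching,
  no PubMed ID resolution.
* The registry is always a local JSON file; there is no network access
  anywhere in the package.
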