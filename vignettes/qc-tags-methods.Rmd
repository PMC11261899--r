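---
title: "Annotating sequence quality with standardized contextual-data tags"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating sequence quality with standardized contextual-data tags}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qctags)
registry <- qc_term_registry()
```

## The problem and the model

Quality control of pathogen sequence data is criterion-dependent: the same
consensus genome can fail a phylogenetics pipeline's coverage threshold and
still carry a fully covered resistance locus. When sub-optimal data is
shared, the *known issues* need to travel with the repository record in a
form that is searchable and unambiguous across institutions. The PHA4GE
community standard does this with five contextual-data fields — method
name, method version, determination, issues, details — whose enumerated
values are GenEpiO ontology terms. A value is exchanged as
`label [PREFIX:0000000]`; the identifier, not the label, is the ground
truth, because labels drift with institutional terminology while CURIEs do
not. Two further fields (`experimental specimen role type` / `details`)
mark synthetic lab constructs, which must not inherit metadata from any
biological source.

`qctags` models this as three layers:

1. a **term registry** (`qc_term_registry()`): 23 core (label, CURIE)
   pairs — 5 field terms, 6 determinations, 10 issues, 2 miscellaneous —
   plus the two CURIE-less specimen fields, with case-insensitive
   label/synonym lookup and zero-padded CURIE lookup;
2. a **record model** (`build_record()`, `qc_record`): ordered method/
   version pairs, ordered resolved term references (which keep the
   as-written spelling alongside the canonical label), atomic free-text
   details, and a verbatim passthrough map for foreign columns;
3. **dialects and emitters**: the semicolon multi-value dialect, two
   field-name dialects (sentence-case display names and the snake_case SRA
   attribute names), canonical JSON, SRA TSV and ENA XML writers that are
   byte-stable and refuse invalid records.

## Vocabulary decisions

Several choices were genuinely open and are fixed here deliberately:

- **Synonyms, not duplicates.** The spelling `"sequenced contaminated"`
  occurs in the wild with the same CURIE as `"sequence contaminated"`; it
  is registered as a synonym, and `render_record(labels = "as_given")`
  reproduces whichever spelling a record arrived with.
- **`excess frameshift mutations detected` (GENEPIO:0100751)** is carried
  as a core issue term: it appears in published usage with a printed CURIE
  even where the main field table omits it.
- **Method names are an open vocabulary.** `qc_method_names()` is a
  suggestion list only; nothing validates against it.
- **The specimen fields have no published CURIEs**; the registry leaves
  them empty rather than guessing, and they render as bare labels.
- **Extensions are first-class.** `register_extension()` models the New
  Term Request escalation locally: extension terms (e.g. GenomeTrakr's
  determination `"significant quality control issues"`) join every lookup
  and validation pass, and CURIE-less extensions render as bare labels.

## The rule engine

`validate_record()` never throws; every finding is a report row with a
rule id and severity, and a record *passes* iff it has no error-severity
findings.

| Rule | Severity | Check |
|---|---|---|
| R1 | error | determination/issues/details present without a method name |
| R2 | warning | method without a version |
| R3 | warning | version neither `X.Y.Z` nor a calendar-valid `YYYY-MM-DD` |
| R4 | error | version count ≠ method count (both non-empty) |
| R5 | error (strict) / warning (lenient) | value not in the registry |
| R6 | info | duplicate values within a list |
| R7 | error | synthetic lab construct with inherited sample fields |
| R8 | warning | term outside its category; `not performed` with issues |
| R9 | warning | `Not Applicable` mixed with other values |
| N1 | info | issues without a determination (note, not a rule) |

Notable calibrations: R3 is a warning because version is declared a free
string — the ISO 8601 / semantic-versioning guidance is best practice, not
format law. R9 is introduced by this package: published records use
`Not Applicable` only as a sole value, but exclusivity is never stated, so
a violation warns rather than fails. R7's "inherited sample metadata" has
no published field list; the default (`host`, `isolation_source`,
`collection_date`, `geo_loc_name`, `host_disease`, `isolate`, `strain`,
`lat_lon`) covers the common INSDC BioSample attributes and is an
argument, as are all severities (`severity_overrides`), so a network can
tighten or relax rules per deployment. Whether a determination is
*required* when issues are present is deliberately left at info level
(N1): published examples always pair them but never mandate it.

Construction is more permissive than validation: `build_record()` will
happily construct an R1- or R4-violating record, because the validator is
the single enforcement point and must be able to report on real-world
input. Strict construction mode rejects only unresolvable or
cross-category terms; lenient mode records them as written and defers to
R5/R8 — which is how the synthetic-mix scenario (a determination-category
term placed in the issues field) is represented faithfully and flagged
with R8 warnings, not errors.

## Adapters and thresholds

Each adapter is an explicit rule table from a normalized tool report to
tags; determination strength (flagged / failed / minor) follows each
tool's own semantics — tools that emit warnings without a pass/fail verdict
map to *flagged*, hard metric failures to *failed*, borderline assembly
statistics to *minor*.

Only one threshold is anchored by a tool itself: ncov-tools' excess-
ambiguity rule fires strictly above 5 ambiguous consensus sites
(`max_ambiguous = 5`, strict `>`). The remaining defaults are this
package's documented choices, exposed as arguments because QC thresholds
legitimately differ across laboratories: Kraken2 off-target read fraction
0.2 (strict `>`, unclassified reads excluded from the denominator by
default), per-locus minimum depth 10 (strict `<`), assembly limits of 200
contigs and 30× mean depth. Details cells often carry wet-lab context the
tool cannot know (a Ct value, a DNA concentration); adapters therefore
accept an operator-supplied `details` override and otherwise emit a
mechanical description, or the `Not Applicable` term when there is nothing
to say.

```{r adapter}
rec <- adapt_kraken2(
  tool_report("Kraken2", "2.1.3",
              taxa = tibble::tibble(taxon = c("SARS-CoV-2", "Homo sapiens"),
                                    fraction = c(0.55, 0.45))),
  registry, target_taxon = "SARS-CoV-2",
  details = "high host reads present from clinical specimen")
tidy(rec)
```

Input parsers (`parse_fastqc_summary()`, `parse_kraken2_report()`, ...)
read minimal canonical text forms of each tool's report — the FastQC
`summary.txt` status lines, the 6-column Kraken2 report, 3-column
`samtools depth` output aggregated per sequence, tab-separated key/value
or metric/status tables for the rest. Full native-format fidelity across
tool versions is explicitly out of scope; the adapters are the stable
surface.

## Numerical and formatting choices

- **Separator**: emitted multi-value cells always use `"; "`. Comma
  splitting exists only in lenient parsing (applied when a cell contains
  no semicolon), normalizing toward the documented semicolon convention.
- **Version alignment** is positional; a missing version in a multi-method
  record renders as an empty segment so later versions keep their slots,
  and the version splitter retains empty segments for the same reason.
- **CURIE normalization**: prefixes uppercase, local parts zero-padded to
  7 digits, so `GENEPIO:1619` and `GENEPIO:0001619` are one identifier.
- **Percentages** in determination breakdowns are `100·n/total` rounded
  half-up to integers and deliberately not renormalized, so they can sum
  to 100 ± the number of categories. With multi-determination records the
  default convention counts a record once per distinct category (counts
  may then exceed the record total; `count = "first"` switches to
  first-determination-only).
- **TSV cells** may not contain tabs or newlines; the writer rejects them
  with an error rather than escaping silently, because repository ingest
  behavior for escaped cells is undefined.
- **Degenerate inputs**: empty collections write header-only tables and
  zero-record JSON documents; an empty record renders to an empty map; a
  PHoeNIx report with an overall SUCCESS but no metrics passes vacuously
  with an informational note.

## Synthetic fixtures: what they emulate and what they don't

`generate_fixture_collection()` draws strictly-valid records with
determination categories and method names sampled from weight maps. The
defaults emulate the published wastewater-surveillance pilot conditions: a
0.61 / 0.10 / 0.28 / 0.01 mix over *no issues* / *minor* / *flagged* /
*significant quality control issues* (the last a CURIE-less network
extension), distributed over the network's two analysis pipelines. A
single integer seed is threaded through `withr::with_seed()`; the global
RNG state is never touched, and a fixed seed reproduces the collection
exactly.

The generator emulates the *contextual-data* layer only: category
frequencies, plausible issue co-annotations, version strings. It does not
emulate correlated missingness, institutional label drift, free-text noise
or multi-network dialect mixtures found in live repository tables — so
passing the seeded recovery tests (observed category fractions within 2
percentage points of the weights at n = 10 000) demonstrates the
aggregation and generation machinery, not fidelity to any real
repository's content. The pilot's published totals (2255 records,
61/10/28/1 %) rest on external repository data and are intentionally not
re-derived. Problem sizes used by the test suite — 500 randomized records
for the four interchange roundtrips (render/parse, TSV, JSON, XML),
10 000 for weight recovery — were chosen as comfortably demonstrative for
these properties.

```{r breakdown, fig.width = 6, fig.height = 3}
coll <- generate_fixture_collection(2255, seed = 61)
autoplot(summarize_determinations(coll))
```

## Known limitations

- Validation is metadata-level only: no QC claim is verified against
  sequence data (coverage is never recomputed).
- The ENA writer emits the experiment-attribute fragment, not the full
  EXPERIMENT-set schema; submission itself (SRA or ENA) is out of scope.
- The canonical JSON layout is this package's documented schema
  (`spec_version`, `records[]`, terms as `{curie, label}`); it does not
  track any external repository file's exact shape.
- Adapter coverage targets the scenarios above; other tools are served by
  constructing `tool_report()` objects directly or via
  `register_extension()` plus `build_record()`.
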