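# qctags

Standardized quality-control contextual-data tags for pathogen sequence
submissions.

Public health laboratories routinely produce sequence datasets that fall
short of a given pipeline's QC thresholds yet remain valuable — for
validating assays, benchmarking tools, training staff, and representing
real-world performance. Sharing such data safely requires that the known
issues travel with the record. The PHA4GE community standard defines five
contextual-data fields for this purpose, with controlled vocabulary drawn
from the Genomic Epidemiology Ontology (GenEpiO):

| Field | GenEpiO ID | Values |
|---|---|---|
| quality control method name | GENEPIO:0100557 | free text (e.g. `ncov-tools`) |
| quality control method version | GENEPIO:0100558 | free text; ISO 8601 date or `X.Y.Z` recommended |
| quality control determination | GENEPIO:0100559 | 6-value picklist (`GENEPIO:0100562`–`0100567`) |
| quality control issues | GENEPIO:0100560 | 10-value picklist (`GENEPIO:0100568`–`0100575`, `0100751`, `0101038`) |
| quality control details | GENEPIO:0100561 | free text |

plus `experimental specimen role type` / `details` for synthetic lab
constructs (`synthetic lab construct [GENEPIO:0101039]`). Picklist values
are exchanged as `label [CURIE]`, multiple values separated by semicolons,
and identifiers — not labels — are the ground truth of the standard.

`qctags` implements the standard as a tidyverse-native toolkit:

- **term registry** — all 23 core (label, CURIE) pairs with bidirectional
  label/CURIE resolution, synonym support, and local extension-term
  registration (the New Term Request analogue);
- **record model + validator** — a `qc_record` data model and a rule engine
  (R1–R9) encoding the best practices: method-name requirement, version
  format and name↔version ordering, picklist membership, synthetic-construct
  metadata isolation, `Not Applicable` exclusivity;
- **adapters** — rule tables translating outputs of ncov-tools, FastQC,
  Kraken2, samtools depth, Quast+Samtools, Nextclade, VADR, PHoeNIx and
  taxonomic-consensus calls into tag records;
- **submission I/O** — SRA user-defined attribute tables (TSV), ENA
  experiment-attribute XML fragments, a canonical JSON interchange form,
  and a submission-template generator;
- **reporting & fixtures** — GenomeTrakr-pilot-style determination
  breakdowns and seeded synthetic collection/report generators.

## Worked example

An ncov-tools run reports 7 IUPAC-ambiguous sites in a SARS-CoV-2 consensus
— above the tool's ">5 ambiguous sites" excess-ambiguity rule, which may
indicate contamination or a real mixed infection:

```r
library(qctags)
registry <- qc_term_registry()

report <- tool_report("ncov-tools", "1.9.1",
                      metrics = list(ambiguous_sites = 7))
record <- adapt_ncov_tools(report, registry,
  details = ">5 ambiguous sites in consensus, sequence indicative of contamination or real mixed infection")
record
#> <qc_record>
#>   Quality control method name: ncov-tools
#>   Quality control method version: 1.9.1
#>   Quality control determination: sequence flagged for potential quality control issues [GENEPIO:0100566]
#>   Quality control issues: sequence contaminated [GENEPIO:0100569]
#>   Quality control details: >5 ambiguous sites in consensus, sequence indicative of contamination or real mixed infection
```

The determination says the sequence is *flagged* (the tool issues warnings,
not a pass/fail), the issue names the standardized reason with its
ontology identifier, and the details preserve the operator's free-text
context. The record validates cleanly and writes straight into a
submission table:

```r
report_passed(validate_record(record, registry, profile = "strict"))
#> [1] TRUE
cat(write_sra_table(qc_collection(list(record)), registry = registry))
#> quality_control_method_name	quality_control_method_version	quality_control_determination	...
#> ncov-tools	1.9.1	sequence flagged for potential quality control issues [GENEPIO:0100566]	...
```

Pilot-style reporting over a collection:

```r
coll <- generate_fixture_collection(2255, seed = 61)
summarize_determinations(coll)
#> <qc_breakdown: 2255 record(s) with determinations>
#> # A tibble: 4 × 3
#>   determination                                             n percent
#> 1 no quality control issues identified                   1395      62
#> 2 sequence flagged for potential quality control issues   599      27
#> 3 minor quality control issues identified                 229      10
#> 4 significant quality control issues                       32       1
```

A thin CLI wraps the same functions
(`inst/cli/qctags.R`: `terms`, `validate`, `convert`, `annotate`,
`summarize`).

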