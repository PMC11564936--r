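---
title: "Curating and validating phenopacket corpora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating and validating phenopacket corpora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenocurator)
```

## The curation model

`phenocurator` operates on corpora of phenopackets: one record per
published individual, carrying a subject block (identifier, sex, age at
last examination, vital status), a set of phenotypic features (HPO terms
asserted present or explicitly excluded, optionally with an age of onset),
one disease diagnosis (OMIM or Mondo), and a genomic interpretation whose
variation descriptor holds the HGNC gene, HGVS expressions or a qualitative
structural-variant label, and a GENO zygosity class.

Three conventions hold the corpus together, and the validator enforces all
of them:

1. **Identifiers.** Every phenopacket id is `PMID_<pmid>_<individual>`,
   built by `make_phenopacket_id()`. Individual identifiers are taken from
   the source publication (falling back to the word `individual`) and
   sanitized to the alphabet `[A-Za-z0-9_.-]` so that one-file-per-record
   storage is filesystem- and URL-safe. The combination of PMID and
   individual id must be unique across the corpus (rules C1/C2). The
   sanitization rule (replace, collapse runs of `_`, strip ends,
   idempotent) is a declared convention of this package: source
   publications do not define legal identifier characters, and a single
   documented normalization beats ad hoc cleanup.
2. **Diagnosis cross-reference.** The disease cited by an interpretation's
   diagnosis must match an entry of the top-level disease list (rule R2,
   ERROR). The model permits several diseases per record because the
   schema does, but one disease per subject is the corpus convention, so a
   longer list is only a warning (R10).
3. **Ontology consistency.** Annotation semantics propagate over the
   `is_a` graph: an observed term implies all of its ancestors, and an
   excluded term implies exclusion of all of its descendants. A
   contradiction — an observed feature with an excluded ancestor, including
   the degenerate case of the same term both observed and excluded — is an
   ERROR (R6). Redundancy — an observed feature whose proper ancestor is
   also observed, or an excluded feature whose proper ancestor is also
   excluded — is hygiene, not contradiction, and warns (R7). One issue is
   emitted per offending feature, which makes fault-injection tests exact.
   Severity assignments are this package's reconstruction of curation
   practice; every rule's level can be overridden or the rule disabled via
   `rule_config()`.

## Ontology handling

`load_ontology()` reads the obographs JSON subset (`nodes` with
id/label/deprecation, `edges` with `sub`/`pred`/`obj`). Only
`is_a`/`subClassOf` predicates become edges; anything else is counted and
ignored, because subsumption is all that consistency QC needs. IRIs are
converted to CURIEs by fragment extraction (`.../HP_0001250` →
`HP:0001250`). Obsolete terms load and are flagged; using one in a
phenopacket is a warning (R4), since corpora are expected to be QC'd
against a current ontology release. The release itself is an explicit input
— nothing is pinned.

Structural guarantees are checked at construction: CURIE syntax, no
self-parenting, resolvable parents, acyclicity (Kahn's algorithm; a cycle
error names a member). When more than one parentless term remains, a
virtual root (`owl:Thing`) is synthesized internally so the ancestor
closure is total; it is never reported by `ancestors()` nor written by
`write_ontology()`. Attaching *all* parentless terms (obsolete ones
included) keeps the closure total without special cases.

## Ages

Ages are ISO 8601 durations restricted to whole Y/M/W/D components in that
order. Comparison needs a total order, so components are converted to days
with fixed constants: 1 year = 365.25 d, 1 month = 30.437 d, 1 week = 7 d.
The constants make ordering deterministic and testable — `P1Y` sorts
strictly after `P12M` (365.25 vs 365.244 days) — which is all the curation
workflow requires of them; they are not calendar arithmetic. Rule R8 warns
when a feature or disease onset exceeds the subject's age at last
examination.

## Canonical JSON

Serialization follows the protobuf JSON mapping: lowerCamelCase keys in
schema declaration order, enums as strings, 2-space indent, trailing
newline, and default values omitted rather than written as `null` — so
`"excluded": true` is a positive assertion and `false` is absent, and a
`deceased = FALSE` is normalized to absent at construction because the wire
format cannot distinguish the two. These choices make equal objects produce
byte-identical files, which the test suite exploits: `read(write(p))` is an
identity and `write ∘ read ∘ write` is byte-stable. The reader accepts both
camelCase and snake_case spellings and collects unknown keys into an
attribute instead of failing, to interoperate with files from other schema
tooling.

## The curation template

The tabular dialect is fully specified here on purpose — a single concrete,
documented layout rather than a configurable zoo. Two header rows: labels,
then a marker row holding `str`/`age`/`optional` for the fixed columns and
the HPO CURIE for each term column. Term cells take `observed`,
`excluded`, `na` (blank counts as `na`, since spreadsheets routinely leave
cells empty), or an ISO 8601 age meaning observed-with-onset. Any other
text is an ERROR with row/column coordinates: curation safety over
convenience. Alleles follow the zygosity rule (equal pair → homozygous
single descriptor; distinct pair → two heterozygous; single → heterozygous,
or hemizygous on request), and allele text without an HGVS-style
`:c.`/`:g.`/`:p.` core becomes a qualitative structural-variant label,
mirroring how large structural variants are reported in the literature
(e.g. `"gene deletion"`). `ingest_template()` writes only records with zero
ERROR-level findings and returns the full issue list.

## Cohort statistics

Cohorts are keyed by the gene symbol of the *first* genomic interpretation;
records without an interpretation go to a `_NO_GENE_` bucket that is
excluded from aggregates and reported. Allele identity is the literal pair
(gene symbol, first HGVS expression value or SV label) — no normalization,
because literal matching is reproducible and descriptors in this convention
carry one expression. Publication identity comes from the id prefix, the
single source of truth for PMIDs. Aggregate rows use half-up rounding to
one decimal (`round_half_up()`, not R's banker's rounding) and the median
of an even cohort count is the mean of the two middle values. The
per-disease mean divides total phenopackets by total distinct diseases,
summing per-cohort disease counts — exact when no disease is shared across
gene cohorts, which the generator guarantees and real gene-partitioned
corpora approximate. Per-individual means (`individual_summaries()`) are
totals divided by the number of phenopackets.

## What the synthetic generator emulates — and what it does not

`generate_corpus()` plants a known ground truth and emits a corpus that is
rule-clean *by construction*, so that injected faults are the only source
of validation findings:

* feature sets are sampled as **antichains** of the ontology (greedy
  selection of pairwise-incomparable terms), which rules out conflicts and
  redundancy structurally;
* onsets are drawn below the age at last examination; diagnosis ids always
  match the disease list; identifiers are globally unique; every CURIE
  prefix is registered in the metadata.

Defaults encode the corpus conditions the package targets: cohort sizes
uniform on 1–30 (a scaled-down version of the 1–463 range seen in large
literature corpora, mean ≈ 15.5), one disease per gene, Poisson(8.2)
present and Poisson(11.8) excluded terms per individual, onset probability
0.043, sex recorded with probability 0.756 (male fraction 0.528 among
recorded), roughly one publication per seven cohort members, and a
log-normal age distribution (median 10 y, capped at 89 y) reflecting the
pediatric skew of rare-disease case reports. Synthetic identifiers come
from visibly fake ranges (PMIDs ≥ 90000000, `OMIM:9xxxxx`, `HP:9xxxxxx`)
so they can never be mistaken for real records.

The generator does **not** model disease-specific phenotype frequencies,
inter-feature correlation, curation noise, or imprecise (non-leaf)
annotation habits. Passing tests therefore demonstrate that the pipeline is
exact on structurally realistic data, not that it is robust to the
messiness of real literature curation — that robustness rests on the
validator, whose job is precisely to surface such messiness.

`inject_faults()` mutates exactly *k* seeded, independent sites per rule
and guarantees no collateral findings; for the structural rules this uses
ontology geometry (a free child below an excluded term for R6, a parent
with exactly one annotated descendant for R7).

## Numerical and degenerate-input choices

* Rounding: half away from zero at one decimal wherever summary tables
  print one decimal.
* Sex percentages among specified individuals are `NA` (reported absent)
  when no record specifies sex; the onset fraction is `NA` for a corpus
  with no features.
* Age histogram bins are half-open `[kw, (k+1)w)`; a boundary age falls in
  the upper bin; individuals without a recorded age are counted separately.
* `read_corpus()` sorts files by path with radix (byte) order for locale
  independence, tolerates per-file failures with a summary, and errors only
  on an empty corpus.
* Validation is pure (same inputs, identical issue tibble) and issue
  reports sort by severity (ERROR first), rule id, then phenopacket id.

## Problem sizes used by the test suite

The suite exercises: 100 random DAGs of 5–50 nodes against an
exhaustive-path reachability oracle; byte-stable round-trips over a
~200-record synthetic corpus; exact fault-injection recovery for all twelve
rules at k ∈ {1, 3, 10} on a ~110-record corpus; parameter recovery on a
corpus with ≥ 5,000 feature annotations (rates within three binomial
standard errors, counts exact); and a 20-row template ingested and compared
record-by-record against direct row construction. These sizes give sharp
oracles at interactive runtimes.

## Known limitations

HGVS strings are carried, not parsed — no validation against reference
transcripts and no normalization, so allele counting is literal. The
ontology loader implements the obographs subset needed for subsumption QC,
not full OWL semantics. Cross-publication duplicate individuals (the same
person published twice under different identifiers) are deliberately out of
scope for the validator: that determination needs information the records
do not carry, and curators are instead advised to watch for it upstream.
XLSX ingestion reads the first sheet only.
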