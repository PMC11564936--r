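# phenocurator

Curate, validate, and summarize corpora of GA4GH phenopackets.

Deep phenotyping of published rare-disease case reports produces collections
of **phenopackets** — one structured record per individual, linking Human
Phenotype Ontology (HPO) annotations (present or explicitly excluded
features, optionally with ages of onset), a disease diagnosis (OMIM/Mondo),
and a genomic interpretation (HGNC gene, HGVS variant expressions or a
qualitative structural-variant label, GENO zygosity). Such corpora feed
phenotype-driven diagnostic tools, and their value depends on strict
curation conventions: stable `PMID_<pmid>_<individual>` identifiers,
diagnosis cross-references, and ontology-consistent annotation sets.
`phenocurator` implements that curation stack for R, for biocurators
building corpora from tabular case-report data and for developers who need
realistic, validated test corpora.

## What it does

* **Ontology subsumption** — load an obographs-style JSON ontology
  (`load_ontology()`), query ancestor/descendant closure over `is_a` edges
  (`ancestors()`, `is_ancestor()`).
* **Schema model** — typed constructors for the phenopacket subset used in
  literature curation (`phenopacket()`, `individual()`,
  `phenotypic_feature()`, `disease_dx()`, `variation_descriptor()`, …) with
  all invariants enforced at construction, plus the identifier algebra
  (`make_phenopacket_id()`, `sanitize_id()`) and ISO 8601 age arithmetic
  (`parse_age()`, `compare_age()`).
* **Canonical JSON I/O** — one phenopacket per file, lowerCamelCase keys,
  deterministic byte-stable output (`write_phenopacket()`,
  `read_phenopacket()`, `read_corpus()`).
* **Tabular ingest** — convert a two-header-row curation template
  (CSV/TSV/XLSX; rows = individuals, one column per HPO term) into a
  validated corpus (`read_template()`, `row_to_phenopacket()`,
  `ingest_template()`).
* **Validation** — a configurable rule engine (`validate_phenopacket()`,
  `validate_corpus()`, rules R1–R10 and corpus rules C1–C2) covering id
  format, diagnosis cross-references, unknown/obsolete/mislabeled terms,
  annotation conflicts and redundancy under subsumption propagation
  (an observed term implies its ancestors; an excluded term excludes its
  descendants), onset ordering, metadata prefix coverage, and uniqueness.
* **Cohort statistics** — partition by causal gene (`partition_by_gene()`),
  per-cohort tallies and the aggregate mean/median/min/max/total table
  (`cohort_summaries()`, `corpus_table()`), per-individual summaries and
  corpus rates (`individual_summaries()`), age histograms
  (`age_histogram()`), with `tidy()`/`glance()`/`autoplot()` methods.
* **Synthetic corpora** — a seeded generator with planted ground truth
  (`generate_ontology()`, `generate_corpus()`) whose output is rule-clean
  by construction, and exact fault injection (`inject_faults()`) so each
  validation rule can be tested against a sharp oracle.
* **CLI** — `run_cli()` and `inst/cli/phenocurator.R` expose `ingest`,
  `validate`, `stats`, `simulate`, and `convert` subcommands; exit status 0
  (clean), 1 (validation errors), 2 (usage error) for CI gates.

The headline corpus statistics follow the conventions of gene-cohort
summary tables: for a corpus of $N$ phenopackets in $G$ gene cohorts with
$D$ distinct diseases, the per-cohort mean is $N/G$, the per-disease mean is
$N/D$, and the onset fraction is the share of the $F$ feature annotations
carrying an age of onset — all rounded half-up to one decimal
(`corpus_overview()`).

## Worked example

```r
library(phenocurator)

cfg <- generator_config(seed = 42, n_genes = 5)
sim <- generate_corpus(cfg)
sim$phenopackets[[1]]
#> <phenopacket> PMID_90000001_individual_1
#>   subject: individual_1 (FEMALE)
#>   features: 5 present, 13 excluded
#>   diseases: 1; interpretations: 1

nrow(validate_corpus(sim$phenopackets, sim$ontology))
#> [1] 0            # generated corpora are rule-clean by construction

glance(corpus_table(cohort_summaries(sim$phenopackets)))
#> # A tibble: 1 × 8
#>   n_cohorts n_phenopackets n_diseases n_unique_alleles n_publications ...
#> 1         5            108          5               45             15

glance(individual_summaries(sim$phenopackets))
#> # A tibble: 1 × 9
#>   n_phenopackets mean_present mean_excluded pct_sex_specified ...
#> 1            108          7.9          12.3              77.8

mut <- inject_faults(sim$phenopackets, "R6", 2, seed = 1, ontology = sim$ontology)
validate_corpus(mut$phenopackets, sim$ontology)
#> # A tibble: 2 × 4
#>   level rule_id phenopacket_id              message
#> 1 ERROR R6      PMID_90000007_individual_42 observed HP:9000050 conflicts with …
#> 2 ERROR R6      PMID_90000011_individual_71 observed HP:9000227 conflicts with …
```

The 108 individuals fall into 5 gene cohorts with 45 distinct causal
alleles drawn from 15 synthetic publications; on average each carries 7.9
present and 12.3 excluded HPO terms, and 77.8% have a recorded sex. The two
injected annotation conflicts (an observed term whose ancestor is excluded
in the same record) are recovered exactly, and nothing else fires.

From a shell, the same workflow is:

```sh
Rscript inst/cli/phenocurator.R simulate --seed 42 --out sim/
Rscript inst/cli/phenocurator.R validate --corpus sim/phenopackets --ontology sim/ontology.json
Rscript inst/cli/phenocurator.R stats --corpus sim/phenopackets --out table.tsv
```

## Not in scope

Variant normalization or validation against reference transcripts (HGVS
strings and structural-variant labels are carried literally), protobuf wire
format, measurement/treatment schema elements, and semantic-similarity
measures over the ontology.
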