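test_that("gene partition groups by first interpretation and logs the rest", {
  sim <- small_corpus(seed = 31, n_genes = 3, cohort_size = dist_uniform(2, 4))
  parts <- partition_by_gene(sim$phenopackets)
  expect_setequal(names(parts), sim$ground_truth$cohorts$gene_symbol)
  expect_equal(sum(lengths(parts)), length(sim$phenopackets))

  orphan <- minimal_packet(id = "PMID_90009999_orphan",
                           subject = individual("orphan"))
  expect_message(parts2 <- partition_by_gene(c(sim$phenopackets, list(orphan))),
                 "without a genomic interpretation")
  expect_length(parts2[["_NO_GENE_"]], 1)
  expect_equal(partition_by_gene(list()), setNames(list(), character(0)))
})

test_that("cohort summaries count alleles, publications, and annotations", {
  gene <- gene_context("HGNC:91234", "GENE001")
  disease <- ontology_class("OMIM:900001", "d")
  hom <- function(pid) interpretation(
    paste0(pid, "-i"), diagnosis_disease = disease,
    genomic_interpretations = list(genomic_interpretation(variation_descriptor(
      "v1", gene, expressions = list(hgvs_expression("hgvs.c", "NM_1.1:c.5G>A")),
      allelic_state = geno_allelic_state("homozygous")))))
  mk <- function(pid, subject_id, n_obs, n_exc) {
    feats <- c(
      purrr::map(seq_len(n_obs), ~ phenotypic_feature(
        ontology_class(sprintf("HP:900%04d", .x), paste("t", .x)))),
      purrr::map(seq_len(n_exc), ~ phenotypic_feature(
        ontology_class(sprintf("HP:901%04d", .x), paste("x", .x)), excluded = TRUE)))
    minimal_packet(id = pid, subject = individual(subject_id), features = feats,
                   diseases = list(disease_dx(disease)),
                   interpretations = list(hom(pid)))
  }
  one <- summarize_cohort(list(mk("PMID_90000001_a", "a", 3, 2)))
  expect_equal(as.list(one[, -1]),
               list(n_phenopackets = 1L, n_diseases = 1L, n_unique_alleles = 1L,
                    n_publications = 1L, n_present_annotations = 3L,
                    n_excluded_annotations = 2L, n_distinct_terms = 5L))
  # same homozygous allele in two individuals counts once; two PMIDs count twice
  two <- summarize_cohort(list(mk("PMID_90000001_a", "a", 3, 2),
                               mk("PMID_90000002_b", "b", 1, 0)))
  expect_equal(two$n_unique_alleles, 1L)
  expect_equal(two$n_publications, 2L)
})

test_that("cohort summaries recover the generator's planted ground truth", {
  sim <- small_corpus(seed = 47, n_genes = 6, cohort_size = dist_uniform(2, 10))
  cs <- cohort_summaries(sim$phenopackets)
  gt <- sim$ground_truth$cohorts
  expect_equal(as.data.frame(dplyr::arrange(cs, gene_symbol)),
               as.data.frame(dplyr::arrange(gt, gene_symbol)),
               ignore_attr = TRUE)
})

test_that("corpus table aggregates use half-up rounding and exact totals", {
  summaries <- tibble::tibble(
    gene_symbol = c("A", "B", "C"),
    n_phenopackets = c(1L, 2L, 4L), n_diseases = c(1L, 1L, 2L),
    n_unique_alleles = c(1L, 3L, 5L), n_publications = c(1L, 1L, 2L),
    n_present_annotations = c(3L, 10L, 20L),
    n_excluded_annotations = c(2L, 8L, 15L), n_distinct_terms = c(5L, 9L, 12L))
  ct <- corpus_table(summaries)
  agg <- function(stat) ct$aggregates[ct$aggregates$statistic == stat, ]
  expect_equal(agg("total")$n_phenopackets, 7)
  expect_equal(agg("mean")$n_phenopackets, round_half_up(7 / 3, 1))
  expect_equal(agg("median")$n_phenopackets, 2)
  expect_equal(agg("minimum")$n_phenopackets, 1)
  expect_equal(agg("maximum")$n_phenopackets, 4)
  expect_equal(agg("total")$n_total_annotations, 58)
  expect_equal(agg("mean")$phenopackets_per_disease, round_half_up(7 / 4, 1))
  # totals are permutation invariant
  ct2 <- corpus_table(summaries[c(3, 1, 2), ])
  expect_equal(ct2$aggregates, ct$aggregates)
  # single cohort degenerates to that cohort's values
  ct1 <- corpus_table(summaries[1, ])
  expect_true(all(ct1$aggregates$n_phenopackets == 1))
  # tidy/glance expose the two layers
  expect_equal(nrow(tidy(ct)), 3)
  expect_equal(glance(ct)$phenopackets_per_disease, 1.8)
})

test_that("median of an even cohort count is the mean of the middle values", {
  summaries <- tibble::tibble(
    gene_symbol = c("A", "B", "C", "D"),
    n_phenopackets = c(1L, 2L, 5L, 10L), n_diseases = 1L,
    n_unique_alleles = 1L, n_publications = 1L,
    n_present_annotations = 1L, n_excluded_annotations = 1L,
    n_distinct_terms = 1L)
  ct <- corpus_table(summaries)
  expect_equal(ct$aggregates$n_phenopackets[ct$aggregates$statistic == "median"],
               3.5)
})

test_that("half-up rounding differs from banker's rounding where it matters", {
  expect_equal(round_half_up(15.75, 1), 15.8)
  expect_equal(round_half_up(14.05, 1), 14.1)
  expect_equal(round_half_up(-2.25, 1), -2.3)
  expect_equal(round_half_up(4913 / 115291 * 100, 1), 4.3)
})

test_that("individual summaries compute counts, sex splits, and onset fraction", {
  mk <- function(pid, sex, n_obs, n_exc, onset_first = FALSE, age = NULL) {
    feats <- purrr::map(seq_len(n_obs + n_exc), function(k) phenotypic_feature(
      ontology_class(sprintf("HP:902%04d", k), paste("t", k)),
      excluded = k > n_obs,
      onset = if (k == 1 && onset_first) "P1Y"))
    minimal_packet(id = pid, features = feats,
                   subject = individual(pid, sex = sex,
                                        time_at_last_encounter = age))
  }
  ps <- list(mk("PMID_1_a", "MALE", 2, 1, TRUE, "P10Y"),
             mk("PMID_1_b", "FEMALE", 1, 2, FALSE, "P2Y6M"),
             mk("PMID_1_c", "UNKNOWN_SEX", 3, 0, TRUE),
             mk("PMID_1_d", "MALE", 0, 3))
  isum <- individual_summaries(ps)
  expect_equal(isum$individuals$n_present, c(2, 1, 3, 0))
  expect_equal(isum$individuals$n_excluded, c(1, 2, 0, 3))
  a <- isum$aggregate
  expect_equal(a$mean_present, round_half_up(6 / 4, 1))
  expect_equal(a$pct_sex_specified, 75)
  expect_equal(a$pct_male_of_specified, round_half_up(200 / 3, 1))
  expect_equal(a$onset_fraction_pct, round_half_up(200 / 12, 1))
  expect_equal(glance(isum)$n_features, 12L)
  expect_equal(nrow(tidy(isum)), 4)
  # degenerate all-unknown corpus: sex split undefined, reported as NA
  unk <- individual_summaries(list(mk("PMID_1_e", "UNKNOWN_SEX", 1, 0)))
  expect_equal(unk$aggregate$pct_sex_specified, 0)
  expect_true(is.na(unk$aggregate$pct_male_of_specified))
})

test_that("age histograms use half-open bins and conserve counts", {
  mk <- function(pid, age, sex = "MALE") minimal_packet(
    id = pid, subject = individual(pid, sex = sex, time_at_last_encounter = age))
  ps <- list(mk("PMID_1_a", "P6M"), mk("PMID_1_b", "P1Y6M", "FEMALE"),
             mk("PMID_1_c", "P1Y11M"), mk("PMID_1_d", NULL))
  h <- age_histogram(ps, bin_width_years = 1)
  expect_equal(h$overall$bin_start, c(0, 1))
  expect_equal(h$overall$n, c(1, 2))
  expect_equal(h$n_missing, 1)
  expect_equal(sum(h$by_sex$n), sum(h$overall$n))
  # an age exactly on a boundary falls in the upper bin
  h2 <- age_histogram(list(mk("PMID_1_e", "P2Y")), bin_width_years = 2)
  expect_equal(h2$overall$bin_start, 2)
  expect_s3_class(autoplot(h), "ggplot")
  sim <- small_corpus(seed = 53, n_genes = 2)
  hs <- age_histogram(sim$phenopackets, 10)
  n_aged <- sum(!purrr::map_lgl(sim$phenopackets,
                                ~ is.null(.x$subject$time_at_last_encounter)))
  expect_equal(sum(hs$overall$n), n_aged)
})

test_that("corpus overview reproduces headline ratios from a totals record", {
  totals <- readr::read_tsv(
    system.file("extdata", "release_totals.tsv", package = "phenocurator"),
    show_col_types = FALSE)
  ov <- corpus_overview(totals)
  expect_equal(ov$phenopackets_per_cohort_mean, 15.8)
  expect_equal(ov$phenopackets_per_disease_mean, 14.0)
  expect_equal(ov$onset_fraction_pct, 4.3)
  expect_error(corpus_overview(list(n_phenopackets = 1)),
               class = "phenocurator_argument_error")
})
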