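# rows: fixed columns then one cell per term column
row_cells <- function(pmid, indiv, cells,
                      disease_id = "OMIM:900001", disease_label = "Synthetic disease",
                      hgnc = "HGNC:91234", gene = "GENE001", transcript = "NM_900001.1",
                      allele_1 = "NM_900001.1:c.59G>A", allele_2 = "",
                      age_of_onset = "", age_last = "P10Y", deceased = "", sex = "M") {
  c(pmid, "A synthetic case report", indiv, disease_id, disease_label,
    hgnc, gene, transcript, allele_1, allele_2, age_of_onset, age_last,
    deceased, sex, cells)
}

tree_terms <- function(g = tree_ontology()) {
  ids <- attr(g, "ids")
  list(ids = unname(ids[c("p2", "c1", "c2")]), labels = c("P2", "C1", "C2"))
}

test_that("templates parse with two header rows and term columns by CURIE", {
  g <- tree_ontology(); tt <- tree_terms(g)
  f <- withr::local_tempfile(fileext = ".csv")
  template_csv(f, list(
    row_cells("90000001", "a", c("observed", "excluded", "na")),
    row_cells("90000001", "b", c("na", "P2Y", ""))
  ), tt$labels, tt$ids)
  tab <- read_template(f)
  expect_equal(tab$n_rows, 2)
  expect_equal(tab$terms$term_id, tt$ids)
  expect_equal(tab$fixed$PMID, c("90000001", "90000001"))
})

test_that("missing fixed columns and duplicate term CURIEs are format errors", {
  g <- tree_ontology(); tt <- tree_terms(g)
  f <- withr::local_tempfile(fileext = ".csv")
  lines <- readLines(template_csv(f, list(row_cells("1", "a", c("na", "na", "na"))),
                                  tt$labels, tt$ids))
  # drop the PMID column (first of both header rows and the body row)
  broken <- vapply(lines, function(l) sub("^[^,]*,", "", l), character(1))
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(broken, f2)
  expect_error(read_template(f2), regexp = "PMID",
               class = "phenocurator_format_error")

  f3 <- withr::local_tempfile(fileext = ".csv")
  template_csv(f3, list(row_cells("1", "a", c("na", "na", "na"))),
               tt$labels, c(tt$ids[[1]], tt$ids[[1]], tt$ids[[3]]))
  expect_error(read_template(f3), regexp = "duplicate",
               class = "phenocurator_format_error")
})

test_that("the same template parses identically from csv and tsv dialects", {
  g <- tree_ontology(); tt <- tree_terms(g)
  f <- withr::local_tempfile(fileext = ".csv")
  template_csv(f, list(row_cells("90000001", "a", c("observed", "excluded", "na"))),
               tt$labels, tt$ids)
  tab_csv <- read_template(f)
  f_tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(gsub(",", "\t", readLines(f)), f_tsv)
  tab_tsv <- read_template(f_tsv)
  expect_equal(tab_tsv$fixed, tab_csv$fixed)
  expect_equal(tab_tsv$cells, tab_csv$cells)
})

test_that("term cells translate to present/excluded/onset features", {
  g <- tree_ontology(); tt <- tree_terms(g)
  f <- withr::local_tempfile(fileext = ".csv")
  template_csv(f, list(row_cells("90000001", "a", c("observed", "P2Y", "na"))),
               tt$labels, tt$ids)
  p <- row_to_phenopacket(read_template(f), 1)
  expect_equal(p$id, "PMID_90000001_a")
  expect_length(p$phenotypic_features, 2)
  expect_false(p$phenotypic_features[[1]]$excluded)
  expect_null(p$phenotypic_features[[1]]$onset)
  expect_equal(p$phenotypic_features[[2]]$onset$iso8601, "P2Y")
  expect_equal(p$subject$sex, "MALE")
  expect_equal(p$subject$time_at_last_encounter$iso8601, "P10Y")
  expect_equal(p$diseases[[1]]$term$id, "OMIM:900001")
  expect_equal(p$interpretations[[1]]$diagnosis_disease$id, "OMIM:900001")
})

test_that("allele pairs determine zygosity and descriptor count", {
  g <- tree_ontology(); tt <- tree_terms(g)
  hgvs <- "NM_900001.1:c.59G>A"
  f <- withr::local_tempfile(fileext = ".csv")
  template_csv(f, list(
    row_cells("1", "hom", c("na", "na", "na"), allele_1 = hgvs, allele_2 = hgvs),
    row_cells("1", "het2", c("na", "na", "na"), allele_1 = hgvs,
              allele_2 = "c.100del"),
    row_cells("1", "het1", c("na", "na", "na"), allele_1 = hgvs),
    row_cells("1", "sv", c("na", "na", "na"), allele_1 = "gene deletion")
  ), tt$labels, tt$ids)
  tab <- read_template(f)

  gis <- function(p) p$interpretations[[1]]$genomic_interpretations
  hom <- gis(row_to_phenopacket(tab, 1))
  expect_length(hom, 1)
  expect_equal(hom[[1]]$descriptor$allelic_state$label, "homozygous")

  het2 <- gis(row_to_phenopacket(tab, 2))
  expect_length(het2, 2)
  expect_equal(purrr::map_chr(het2, ~ .x$descriptor$allelic_state$label),
               rep("heterozygous", 2))
  # bare c. allele is completed with the transcript
  expect_equal(het2[[2]]$descriptor$expressions[[1]]$value,
               "NM_900001.1:c.100del")

  het1 <- gis(row_to_phenopacket(tab, 3))
  expect_length(het1, 1)
  expect_equal(het1[[1]]$descriptor$allelic_state$label, "heterozygous")
  hemi <- gis(row_to_phenopacket(tab, 3, options = list(hemizygous = TRUE)))
  expect_equal(hemi[[1]]$descriptor$allelic_state$label, "hemizygous")

  sv <- gis(row_to_phenopacket(tab, 4))
  expect_equal(sv[[1]]$descriptor$sv_label, "gene deletion")
  expect_length(sv[[1]]$descriptor$expressions, 0)
})

test_that("bad cells raise coordinates; unknown cell text is never silent", {
  g <- tree_ontology(); tt <- tree_terms(g)
  f <- withr::local_tempfile(fileext = ".csv")
  template_csv(f, list(
    row_cells("1", "a", c("sometimes", "na", "na")),
    row_cells("1", "b", c("na", "na", "na"), age_last = "ten years"),
    row_cells("1", "c", c("na", "na", "na"), sex = "W")
  ), tt$labels, tt$ids)
  tab <- read_template(f)
  expect_error(row_to_phenopacket(tab, 1), regexp = "row 1.*sometimes",
               class = "phenocurator_cell_error")
  expect_error(row_to_phenopacket(tab, 2), regexp = "age_at_last_encounter",
               class = "phenocurator_cell_error")
  expect_error(row_to_phenopacket(tab, 3), regexp = "sex",
               class = "phenocurator_cell_error")
  expect_error(row_to_phenopacket(tab, 9), class = "phenocurator_argument_error")
})

test_that("ingest writes clean rows only and reports issues for the rest", {
  g <- tree_ontology(); tt <- tree_terms(g)
  rows <- purrr::map(1:5, function(i)
    row_cells("90000001", paste0("ind", i), c("observed", "excluded", "na")))
  # row 3: diagnosis id in the interpretation will mismatch the disease list
  f <- withr::local_tempfile(fileext = ".csv")
  template_csv(f, rows, tt$labels, tt$ids)
  out <- withr::local_tempdir()
  res <- ingest_template(read_template(f), g, out)
  expect_equal(res$written, 5)
  expect_equal(nrow(res$issues), 0)
  expect_length(read_corpus(out), 5)

  rows_bad <- rows
  rows_bad[[3]][1] <- "not-a-pmid"
  f2 <- withr::local_tempfile(fileext = ".csv")
  template_csv(f2, rows_bad, tt$labels, tt$ids)
  out2 <- withr::local_tempdir()
  res2 <- ingest_template(read_template(f2), g, out2)
  expect_equal(res2$written, 4)
  expect_equal(res2$issues$rule_id, "CELL")
  expect_equal(res2$issues$level, "ERROR")
})

test_that("ingested corpus equals direct row-level construction", {
  g <- tree_ontology(); tt <- tree_terms(g)
  rows <- purrr::map(1:6, function(i)
    row_cells("90000001", paste0("ind", i),
              c("observed", if (i %% 2) "excluded" else "P1Y", "na")))
  f <- withr::local_tempfile(fileext = ".csv")
  template_csv(f, rows, tt$labels, tt$ids)
  tab <- read_template(f)
  out <- withr::local_tempdir()
  ingest_template(tab, g, out)
  loaded <- read_corpus(out)
  direct <- purrr::map(1:6, ~ row_to_phenopacket(tab, .x))
  direct <- direct[order(purrr::map_chr(direct, "id"), method = "radix")]
  expect_equal(purrr::map(loaded, unclass), purrr::map(direct, unclass))
  # emitted features per row == non-"na" term cells
  for (k in 1:6) {
    expect_length(direct[[k]]$phenotypic_features,
                  sum(!tab$cells[k, ] %in% c("na", "")))
  }
})
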