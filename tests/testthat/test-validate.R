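make_tree_packet <- function(features, g = tree_ontology(), ...) {
  ids <- attr(g, "ids")
  feats <- purrr::map(features, function(spec) {
    tid <- ids[[spec$term]]
    phenotypic_feature(
      ontology_class(tid, g$terms$label[match(tid, g$terms$id)]),
      excluded = isTRUE(spec$excluded))
  })
  minimal_packet(features = feats, ...)
}

test_that("a mismatched diagnosis id yields exactly one R2 error", {
  g <- tree_ontology()
  disease <- ontology_class("OMIM:101600", "Disease A")
  other <- ontology_class("OMIM:616868", "Disease B")
  p <- minimal_packet(
    diseases = list(disease_dx(disease)),
    interpretations = list(interpretation("i1", diagnosis_disease = other)))
  issues <- validate_phenopacket(p, g)
  expect_equal(issues$rule_id, "R2")
  expect_equal(issues$level, "ERROR")
  expect_match(issues$message, "OMIM:616868")
})

test_that("observed child with excluded parent is a single R6 conflict", {
  g <- tree_ontology()
  issues <- validate_phenopacket(
    make_tree_packet(list(list(term = "c1"), list(term = "p1", excluded = TRUE))), g)
  expect_equal(issues$rule_id, "R6")
  expect_equal(issues$level, "ERROR")
  # same term observed and excluded is also a propagation conflict
  issues2 <- validate_phenopacket(
    make_tree_packet(list(list(term = "c1"), list(term = "c1", excluded = TRUE))), g)
  expect_true("R6" %in% issues2$rule_id)
})

test_that("redundant observed ancestors and excluded descendants warn via R7", {
  g <- tree_ontology()
  obs <- validate_phenopacket(
    make_tree_packet(list(list(term = "c1"), list(term = "p1"))), g)
  expect_equal(obs$rule_id, "R7")
  expect_equal(obs$level, "WARNING")
  exc <- validate_phenopacket(
    make_tree_packet(list(list(term = "c1", excluded = TRUE),
                          list(term = "p1", excluded = TRUE))), g)
  expect_equal(exc$rule_id, "R7")
  # siblings are an antichain: clean
  clean <- validate_phenopacket(
    make_tree_packet(list(list(term = "c1"), list(term = "c2", excluded = TRUE))), g)
  expect_equal(nrow(clean), 0)
})

test_that("R6/R7 agree with the propagated-annotation oracle on random cases", {
  sim <- small_corpus(seed = 21, n_genes = 2)
  g <- sim$ontology
  terms <- ontology_terms(g)
  pool <- terms$id[!terms$obsolete & terms$id != g$root]
  set.seed(99)
  for (i in 1:40) {
    chosen <- sample(pool, sample(2:8, 1))
    split <- sample(c(TRUE, FALSE), length(chosen), replace = TRUE)
    observed <- chosen[!split]; excluded <- chosen[split]
    feats <- c(
      purrr::map(observed, ~ phenotypic_feature(
        ontology_class(.x, terms$label[match(.x, terms$id)]))),
      purrr::map(excluded, ~ phenotypic_feature(
        ontology_class(.x, terms$label[match(.x, terms$id)]), excluded = TRUE))
    )
    issues <- validate_phenopacket(minimal_packet(features = feats), g)
    expect_equal(any(issues$rule_id == "R6"),
                 oracle_conflict(g, observed, excluded))
    expect_equal(any(issues$rule_id == "R7"),
                 oracle_redundancy(g, observed, excluded))
  }
})

test_that("unknown, obsolete, and mislabeled terms map to R3/R4/R5", {
  g <- generate_ontology(depth = 2, branching = 2, n_obsolete = 1)
  terms <- ontology_terms(g)
  obsolete_id <- terms$id[terms$obsolete][[1]]
  feats <- list(
    phenotypic_feature(ontology_class("HP:8888888", "nope")),
    phenotypic_feature(ontology_class(obsolete_id,
                                      terms$label[match(obsolete_id, terms$id)])),
    phenotypic_feature(ontology_class("HP:9000002", "wrong label"))
  )
  issues <- validate_phenopacket(minimal_packet(features = feats), g)
  expect_setequal(issues$rule_id, c("R3", "R4", "R5"))
  expect_equal(issues$level[issues$rule_id == "R3"], "ERROR")
  expect_equal(issues$level[issues$rule_id == "R4"], "WARNING")
})

test_that("onset after last encounter, missing prefixes, multi-disease warn", {
  g <- tree_ontology()
  ids <- attr(g, "ids")
  p <- phenopacket(
    id = "PMID_90000001_late",
    subject = individual("late", time_at_last_encounter = "P5Y"),
    phenotypic_features = list(phenotypic_feature(
      ontology_class(ids[["c1"]], "C1"), onset = "P9Y")),
    diseases = list(
      disease_dx(ontology_class("OMIM:900001", "d1"), onset = "P6Y"),
      disease_dx(ontology_class("MONDO:0000001", "d2"))),
    interpretations = list(),
    meta_data = test_metadata(c("HP", "OMIM"))  # MONDO unregistered
  )
  issues <- validate_phenopacket(p, g)
  expect_equal(sum(issues$rule_id == "R8"), 2)  # feature and disease onset
  expect_equal(sum(issues$rule_id == "R9"), 1)
  expect_match(issues$message[issues$rule_id == "R9"], "MONDO")
  expect_equal(sum(issues$rule_id == "R10"), 1)
  expect_true(all(issues$level == "WARNING"))
})

test_that("corpus rules flag duplicate ids and duplicate individuals", {
  sim <- small_corpus(seed = 13, n_genes = 3, cohort_size = dist_uniform(4, 8))
  ps <- sim$phenopackets
  expect_equal(nrow(validate_corpus(ps, sim$ontology)), 0)

  dup <- ps
  dup[[2]]$id <- dup[[1]]$id
  issues <- validate_corpus(dup, sim$ontology)
  expect_equal(issues$rule_id, "C1")

  dup2 <- inject_faults(ps, "C2", 2, seed = 5)$phenopackets
  issues2 <- validate_corpus(dup2, sim$ontology)
  expect_equal(sort(issues2$rule_id), c("C2", "C2"))
})

test_that("validation is pure and configurable", {
  sim <- small_corpus(seed = 17, n_genes = 2)
  mut <- inject_faults(sim$phenopackets, "R5", 3, seed = 1,
                       ontology = sim$ontology)$phenopackets
  a <- validate_corpus(mut, sim$ontology)
  b <- validate_corpus(mut, sim$ontology)
  expect_identical(a, b)
  # disable R5: silence; promote R5 to ERROR: level changes
  expect_equal(nrow(validate_corpus(mut, sim$ontology,
                                    rule_config(disable = "R5"))), 0)
  up <- validate_corpus(mut, sim$ontology, rule_config(levels = c(R5 = "ERROR")))
  expect_true(all(up$level == "ERROR"))
  expect_error(rule_config(disable = "R99"), class = "phenocurator_argument_error")
})

test_that("issue reports are sorted, stable, and mirror across formats", {
  issues <- dplyr::bind_rows(
    tibble::tibble(level = "WARNING", rule_id = "R7", phenopacket_id = "b",
                   message = "m1"),
    tibble::tibble(level = "ERROR", rule_id = "R2", phenopacket_id = "a",
                   message = "m2"),
    tibble::tibble(level = "ERROR", rule_id = "C1", phenopacket_id = "c",
                   message = "m3"))
  tsv <- issue_report(issues, "tsv")
  lines <- strsplit(tsv, "\n")[[1]]
  expect_equal(lines[[1]], "level\trule_id\tphenopacket_id\tmessage")
  expect_match(lines[[2]], "^ERROR\tC1")
  expect_match(lines[[4]], "^WARNING\tR7")
  expect_identical(tsv, issue_report(issues[c(3, 1, 2), ], "tsv"))
  js <- jsonlite::fromJSON(issue_report(issues, "json"))
  expect_equal(js$rule_id, c("C1", "R2", "R7"))
  # empty report is header-only
  expect_equal(strsplit(issue_report(issues[0, ], "tsv"), "\n")[[1]],
               "level\trule_id\tphenopacket_id\tmessage")
})
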