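# Shared fixtures and independent oracles, built in code at test time.

# --- tiny ontologies --------------------------------------------------------

# root <- A <- B chain, ids in the synthetic HP:9xxxxxx range
chain_ontology <- function() {
  ontology_graph(
    tibble::tibble(
      id = c("HP:9000001", "HP:9000002", "HP:9000003"),
      label = c("root", "A", "B"),
      obsolete = FALSE
    ),
    list("HP:9000001" = character(),
         "HP:9000002" = "HP:9000001",
         "HP:9000003" = "HP:9000002")
  )
}

# A small fixed tree: root with children P1, P2; P1 with children C1, C2
tree_ontology <- function() {
  ids <- c(root = "HP:9100001", p1 = "HP:9100002", p2 = "HP:9100003",
           c1 = "HP:9100004", c2 = "HP:9100005")
  g <- ontology_graph(
    tibble::tibble(id = unname(ids),
                   label = c("root", "P1", "P2", "C1", "C2"),
                   obsolete = FALSE),
    list("HP:9100001" = character(), "HP:9100002" = "HP:9100001",
         "HP:9100003" = "HP:9100001", "HP:9100004" = "HP:9100002",
         "HP:9100005" = "HP:9100002")
  )
  attr(g, "ids") <- ids
  g
}

# Random single-root DAG: node i > 1 draws 1-2 parents among nodes 1..(i-1),
# so every decreasing parent chain terminates at node 1.
random_dag <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("HP:9%06d", seq_len(n))
  parents <- vector("list", n)
  names(parents) <- ids
  parents[[1]] <- character()
  for (i in seq_len(n)[-1]) {
    k <- if (i > 2 && runif(1) < 0.4) 2 else 1
    parents[[i]] <- ids[sample.int(i - 1, min(k, i - 1))]
  }
  list(ids = ids, parents = parents,
       graph = ontology_graph(
         tibble::tibble(id = ids, label = paste("term", seq_len(n)),
                        obsolete = FALSE),
         parents))
}

# Write a parent-list DAG as an obographs JSON file (independent of
# write_ontology, so the loader is tested against hand-built JSON)
write_obographs <- function(ids, parents, path, labels = NULL,
                            obsolete = character(), pred = "is_a") {
  nodes <- lapply(seq_along(ids), function(i) {
    n <- list(id = ids[[i]], lbl = (labels %||% paste("term", seq_along(ids)))[[i]])
    if (ids[[i]] %in% obsolete) n$meta <- list(deprecated = TRUE)
    n
  })
  edges <- list()
  for (id in names(parents)) {
    for (p in parents[[id]]) {
      edges <- c(edges, list(list(sub = id, pred = pred, obj = p)))
    }
  }
  writeLines(jsonlite::toJSON(list(graphs = list(list(nodes = nodes, edges = edges))),
                              auto_unbox = TRUE), path)
  path
}

# --- oracles ----------------------------------------------------------------

# Exhaustive-path reachability: enumerate every parent path from t, collect
# the nodes visited. Independent of the package's BFS closure.
oracle_ancestors <- function(parents, t) {
  out <- character(0)
  walk <- function(node) {
    for (p in parents[[node]]) {
      out <<- c(out, p)
      walk(p)
    }
  }
  walk(t)
  unique(out)
}

# Propagated-annotation oracle for conflict/redundancy: materialize
# observed terms with all their ancestors and excluded terms with all their
# descendants, then intersect.
oracle_conflict <- function(g, observed, excluded) {
  up <- unique(unlist(lapply(observed, function(t)
    c(t, ancestors(g, t, include_self = FALSE)))))
  down <- unique(unlist(lapply(excluded, function(t)
    c(t, descendants(g, t, include_self = FALSE)))))
  length(intersect(up, down)) > 0
}

oracle_redundancy <- function(g, observed, excluded) {
  obs_red <- any(vapply(observed, function(t)
    length(intersect(setdiff(observed, t), ancestors(g, t))) > 0, logical(1)))
  exc_red <- any(vapply(excluded, function(t)
    length(intersect(setdiff(excluded, t), ancestors(g, t))) > 0, logical(1)))
  obs_red || exc_red
}

# --- phenopacket builders ---------------------------------------------------

test_metadata <- function(prefixes = c("HP", "OMIM", "GENO", "HGNC")) {
  meta_data(created = "2024-01-01T00:00:00Z", created_by = "test",
            resources = default_resources(prefixes))
}

minimal_packet <- function(id = "PMID_90000001_individual_1",
                           features = list(), diseases = list(),
                           interpretations = list(),
                           subject = individual("individual_1"),
                           md = test_metadata()) {
  phenopacket(id = id, subject = subject, phenotypic_features = features,
              diseases = diseases, interpretations = interpretations,
              meta_data = md)
}

# A fully populated packet exercising every serializable field
rich_packet <- function() {
  gene <- gene_context("HGNC:91234", "GENE001")
  disease <- ontology_class("OMIM:900001", "Synthetic disease")
  phenopacket(
    id = "PMID_90000001_BAB3022",
    subject = individual("BAB3022", sex = "FEMALE",
                         time_at_last_encounter = "P10Y",
                         deceased = TRUE, age_of_death = "P12Y"),
    phenotypic_features = list(
      phenotypic_feature(ontology_class("HP:9000002", "A"), excluded = FALSE,
                         onset = "P2Y3M"),
      phenotypic_feature(ontology_class("HP:9000003", "B"), excluded = TRUE)
    ),
    diseases = list(disease_dx(disease, onset = "P1Y")),
    interpretations = list(interpretation(
      id = "PMID_90000001_BAB3022-interpretation",
      diagnosis_disease = disease,
      genomic_interpretations = list(
        genomic_interpretation(variation_descriptor(
          id = "var-1", gene = gene,
          expressions = list(hgvs_expression("hgvs.c", "NM_900001.1:c.59G>A")),
          allelic_state = geno_allelic_state("heterozygous"))),
        genomic_interpretation(build_sv_descriptor(
          gene, "gene deletion", geno_allelic_state("heterozygous"), id = "var-2"))
      )
    )),
    meta_data = test_metadata()
  )
}

# small, fast synthetic corpus used across tests
small_corpus <- function(seed = 3, n_genes = 4,
                         cohort_size = dist_uniform(2, 6)) {
  generate_corpus(generator_config(seed = seed, n_genes = n_genes,
                                   cohort_size = cohort_size))
}

# A toy curation template as CSV text; terms drawn from chain/tree fixtures
# are not needed here -- callers pass the ontology whose terms are used.
template_csv <- function(path, rows, term_labels, term_ids) {
  fixed <- c("PMID", "title", "individual_id", "disease_id", "disease_label",
             "hgnc_id", "gene_symbol", "transcript", "allele_1", "allele_2",
             "age_of_onset", "age_at_last_encounter", "deceased", "sex")
  markers <- c("str", "str", "str", "str", "str", "str", "str", "str", "str",
               "str", "age", "age", "optional", "str")
  header1 <- c(fixed, term_labels)
  header2 <- c(markers, term_ids)
  lines <- c(paste(header1, collapse = ","), paste(header2, collapse = ","),
             vapply(rows, paste, character(1), collapse = ","))
  writeLines(lines, path)
  path
}
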