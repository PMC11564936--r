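#' Distribution specifications for the corpus generator
#'
#' Count-valued generator parameters are distribution specs: a single number
#' is a constant, `dist_uniform()` draws integers uniformly on
#' `[min, max]`, and `dist_poisson()` draws Poisson counts truncated below
#' at `min`.
#'
#' @param min,max Integer bounds (inclusive).
#' @param lambda Poisson mean.
#' @return A `dist_spec` object.
#' @export
dist_uniform <- function(min, max) {
  stopifnot(min <= max)
  structure(list(kind = "uniform", min = min, max = max), class = "dist_spec")
}

#' @rdname dist_uniform
#' @export
dist_poisson <- function(lambda, min = 0) {
  stopifnot(lambda > 0)
  structure(list(kind = "poisson", lambda = lambda, min = min), class = "dist_spec")
}

draw_count <- function(spec, n = 1) {
  if (is.numeric(spec)) return(rep(as.integer(spec), n))
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$kind,
    uniform = as.integer(floor(runif(n, spec$min, spec$max + 1))),
    poisson = pmax(spec$min, rpois(n, spec$lambda))
  )
}

#' Synthetic-corpus generator configuration
#'
#' Defaults emulate the structure of a literature-curated rare-disease
#' corpus: gene cohorts of 1--30 individuals (mean ~15.5), one Mendelian
#' disease per gene, Poisson(8.2) present and Poisson(11.8) excluded HPO
#' terms per individual, 4.3% of feature annotations carrying an age of
#' onset, sex specified for 75.6% of individuals (52.8% of those male), and
#' roughly one publication per seven cohort members. Synthetic identifiers
#' are drawn from visibly fake ranges (PMIDs 90000000+, `OMIM:9xxxxx`,
#' `HP:9xxxxxx`) so they can never collide with real records.
#'
#' @param seed Integer seed; every draw is reproducible from it.
#' @param n_genes Number of gene cohorts.
#' @param diseases_per_gene,cohort_size,n_present,n_excluded,allele_pool_size
#'   Distribution specs (see [dist_uniform()]).
#' @param p_onset Probability a feature annotation has an onset age.
#' @param p_sex_specified Probability the sex is recorded.
#' @param p_male_given_specified Male fraction among recorded sexes.
#' @param p_has_age Probability the age at last examination is recorded.
#' @param p_disease_onset Probability the disease onset is recorded (only
#'   when the individual has an examination age).
#' @param p_sv Probability an individual's causal variant is the gene's
#'   qualitative structural-variant allele (`"gene deletion"`).
#' @param ontology Depth/branching/obsolete-count of the generated ontology.
#' @return A `generator_config` object.
#' @export
generator_config <- function(seed = 1,
                             n_genes = 20,
                             diseases_per_gene = 1,
                             cohort_size = dist_uniform(1, 30),
                             n_present = dist_poisson(8.2, min = 1),
                             n_excluded = dist_poisson(11.8, min = 0),
                             allele_pool_size = 9,
                             p_onset = 0.043,
                             p_sex_specified = 0.756,
                             p_male_given_specified = 0.528,
                             p_has_age = 0.9,
                             p_disease_onset = 0.5,
                             p_sv = 0.1,
                             ontology = list(depth = 5, branching = 3,
                                             n_obsolete = 12)) {
  probs <- c(p_onset, p_sex_specified, p_male_given_specified, p_has_age,
             p_disease_onset, p_sv)
  stopifnot(all(probs >= 0 & probs <= 1), n_genes >= 1)
  structure(
    list(seed = as.integer(seed), n_genes = n_genes,
         diseases_per_gene = diseases_per_gene, cohort_size = cohort_size,
         n_present = n_present, n_excluded = n_excluded,
         allele_pool_size = allele_pool_size, p_onset = p_onset,
         p_sex_specified = p_sex_specified,
         p_male_given_specified = p_male_given_specified,
         p_has_age = p_has_age, p_disease_onset = p_disease_onset,
         p_sv = p_sv, ontology = ontology),
    class = "generator_config"
  )
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic HPO-like ontology
#'
#' A complete `branching`-ary tree of the given depth (so
#' `(branching^(depth+1) - 1) / (branching - 1)` terms for branching > 1),
#' with term ids in the `HP:9xxxxxx` range to avoid colliding with real HPO
#' identifiers, plus `n_obsolete` obsolete leaf terms attached to the root.
#' The structure is fully determined by the arguments.
#'
#' @param depth Levels below the root (>= 1).
#' @param branching Children per internal node (>= 1).
#' @param n_obsolete Number of obsolete terms.
#' @return An [ontology_graph()].
#' @export
generate_ontology <- function(depth = 5, branching = 3, n_obsolete = 12) {
  stopifnot(depth >= 1, branching >= 1)
  mk_id <- function(k) sprintf("HP:9%06d", k)
  ids <- mk_id(1)
  labels <- "Synthetic phenotypic abnormality (root)"
  parents <- list(character(0))
  level <- 1L          # indices of current level
  counter <- 1L
  for (d in seq_len(depth)) {
    next_level <- integer(0)
    for (parent_idx in level) {
      for (b in seq_len(branching)) {
        counter <- counter + 1L
        ids <- c(ids, mk_id(counter))
        labels <- c(labels, paste0("Synthetic term ", counter))
        parents <- c(parents, list(ids[[parent_idx]]))
        next_level <- c(next_level, counter)
      }
    }
    level <- next_level
  }
  obsolete <- rep(FALSE, counter)
  for (k in seq_len(n_obsolete)) {
    counter <- counter + 1L
    ids <- c(ids, mk_id(counter))
    labels <- c(labels, paste0("Obsolete synthetic term ", counter))
    parents <- c(parents, list(ids[[1]]))
    obsolete <- c(obsolete, TRUE)
  }
  ontology_graph(tibble(id = ids, label = labels, obsolete = obsolete),
                 setNames(parents, ids))
}

years_to_iso <- function(y) {
  yr <- floor(y)
  mo <- floor((y - yr) * 12)
  paste0("P", yr, "Y", mo, "M")
}

# Greedy antichain sample: pairwise incomparable terms under is_a
sample_antichain <- function(candidates, n, anc) {
  pool <- sample(candidates)
  chosen <- character(0)
  chosen_anc <- character(0)
  for (t in pool) {
    if (length(chosen) >= n) break
    # comparable iff t is an ancestor-or-self of a chosen term, or vice versa
    if (t %in% chosen_anc) next
    if (any(chosen %in% anc[[t]])) next
    chosen <- c(chosen, t)
    chosen_anc <- unique(c(chosen_anc, anc[[t]]))
  }
  chosen
}

#' Generate a synthetic phenopacket corpus with planted ground truth
#'
#' Every phenopacket is rule-clean by construction: feature sets are sampled
#' as antichains of the ontology (so no annotation conflicts or
#' redundancies), onsets never exceed the age at last examination, diagnosis
#' ids always match the disease list, identifiers are globally unique, and
#' all CURIE prefixes are registered in the metadata. Fault injection
#' ([inject_faults()]) is therefore the only source of validation findings.
#'
#' @param cfg A [generator_config()].
#' @param g The ontology to annotate against (from [generate_ontology()]);
#'   generated from `cfg$ontology` when `NULL`.
#' @return A list with `phenopackets`, `ground_truth` (list with `cohorts`
#'   tibble and `totals` list) and `ontology`.
#' @export
generate_corpus <- function(cfg = generator_config(), g = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  if (is.null(g)) {
    g <- generate_ontology(cfg$ontology$depth, cfg$ontology$branching,
                           cfg$ontology$n_obsolete)
  }
  with_local_seed(cfg$seed, {
    anc <- ancestor_map(g)
    terms <- ontology_terms(g)
    candidates <- terms$id[!terms$obsolete & terms$id != g$root]
    resources <- default_resources(c("HP", "OMIM", "GENO", "HGNC"))
    md <- meta_data(created = "2024-01-01T00:00:00Z",
                    created_by = "phenocurator-synthetic", resources = resources)

    packets <- list()
    cohort_rows <- list()
    pmid_counter <- 90000000L
    omim_counter <- 900000L
    indiv_counter <- 0L
    tot_onset <- 0L; tot_feats <- 0L
    sex_tally <- c(MALE = 0L, FEMALE = 0L, OTHER_SEX = 0L, UNKNOWN_SEX = 0L)

    for (j in seq_len(cfg$n_genes)) {
      gene_symbol <- sprintf("GENE%03d", j)
      gene <- gene_context(sprintf("HGNC:9%04d", j), gene_symbol)
      transcript <- sprintf("NM_9%05d.1", j)
      n_dis <- draw_count(cfg$diseases_per_gene)
      diseases <- map(seq_len(n_dis), function(d) {
        omim_counter <<- omim_counter + 1L
        ontology_class(sprintf("OMIM:%06d", omim_counter),
                       paste0("Synthetic disease ", gene_symbol, "-", d))
      })
      pool_size <- draw_count(cfg$allele_pool_size)
      hgvs_pool <- sprintf("%s:c.%dG>A", transcript, 10L + 7L * seq_len(pool_size))

      m <- draw_count(cfg$cohort_size)
      n_pubs <- max(1L, as.integer(round(m / 7)))
      pmids <- as.character(pmid_counter + seq_len(n_pubs))
      pmid_counter <- pmid_counter + n_pubs

      used_diseases <- character(0); used_alleles <- character(0)
      used_pmids <- character(0); used_terms <- character(0)
      coh_present <- 0L; coh_excluded <- 0L
      cohort_pk <- list()

      for (i in seq_len(m)) {
        indiv_counter <- indiv_counter + 1L
        subject_id <- paste0("individual_", indiv_counter)
        pmid <- sample(pmids, 1)
        used_pmids <- union(used_pmids, pmid)
        pid <- make_phenopacket_id(pmid, subject_id)

        sex <- if (runif(1) < cfg$p_sex_specified) {
          if (runif(1) < cfg$p_male_given_specified) "MALE" else "FEMALE"
        } else "UNKNOWN_SEX"
        sex_tally[[sex]] <- sex_tally[[sex]] + 1L

        age_years <- if (runif(1) < cfg$p_has_age)
          min(89, max(0.1, exp(rnorm(1, log(10), 1)))) else NA_real_
        last_enc <- if (!is.na(age_years)) parse_age(years_to_iso(age_years))

        np <- draw_count(cfg$n_present)
        ne <- draw_count(cfg$n_excluded)
        chosen <- sample_antichain(candidates, np + ne, anc)
        np <- min(np, length(chosen))
        feats <- imap(chosen, function(t, k) {
          onset <- NULL
          if (runif(1) < cfg$p_onset) {
            onset <- if (!is.na(age_years)) years_to_iso(runif(1, 0, age_years))
                     else years_to_iso(runif(1, 0, 10))
          }
          phenotypic_feature(ontology_class(t, term_label(g, t)),
                             excluded = k > np, onset = onset)
        })
        n_onset <- sum(map_lgl(feats, function(f) !is.null(f$onset)))
        tot_onset <- tot_onset + n_onset
        tot_feats <- tot_feats + length(feats)
        coh_present <- coh_present + min(np, length(chosen))
        coh_excluded <- coh_excluded + (length(chosen) - min(np, length(chosen)))
        used_terms <- union(used_terms, chosen)

        disease <- diseases[[sample.int(n_dis, 1)]]
        used_diseases <- union(used_diseases, disease$id)
        dis_onset <- if (!is.na(age_years) && runif(1) < cfg$p_disease_onset)
          years_to_iso(runif(1, 0, age_years))

        # causal variant: SV allele, or one/two HGVS alleles from the pool
        if (runif(1) < cfg$p_sv) {
          descs <- list(build_sv_descriptor(
            gene, "gene deletion", geno_allelic_state("heterozygous"),
            id = paste0(pid, "-var-1")))
        } else {
          zyg <- runif(1)
          mk <- function(val, state, k) variation_descriptor(
            id = paste0(pid, "-var-", k), gene = gene,
            expressions = list(hgvs_expression("hgvs.c", val)),
            allelic_state = geno_allelic_state(state))
          if (zyg < 0.3) {
            descs <- list(mk(sample(hgvs_pool, 1), "homozygous", 1))
          } else if (zyg < 0.7 && pool_size >= 2) {
            vals <- sample(hgvs_pool, 2)
            descs <- list(mk(vals[[1]], "heterozygous", 1),
                          mk(vals[[2]], "heterozygous", 2))
          } else {
            descs <- list(mk(sample(hgvs_pool, 1), "heterozygous", 1))
          }
        }
        p <- phenopacket(
          id = pid,
          subject = individual(subject_id, sex = sex,
                               time_at_last_encounter = last_enc),
          phenotypic_features = feats,
          diseases = list(disease_dx(disease, onset = dis_onset)),
          interpretations = list(interpretation(
            id = paste0(pid, "-interpretation"),
            diagnosis_disease = disease,
            genomic_interpretations = map(descs, genomic_interpretation)
          )),
          meta_data = md
        )
        used_alleles <- union(used_alleles, allele_keys(p))
        cohort_pk <- c(cohort_pk, list(p))
      }

      packets <- c(packets, cohort_pk)
      cohort_rows <- c(cohort_rows, list(tibble(
        gene_symbol = gene_symbol, n_phenopackets = m,
        n_diseases = length(used_diseases),
        n_unique_alleles = length(used_alleles),
        n_publications = length(used_pmids),
        n_present_annotations = coh_present,
        n_excluded_annotations = coh_excluded,
        n_distinct_terms = length(used_terms)
      )))
    }

    cohorts <- bind_rows(cohort_rows)
    totals <- list(
      n_phenopackets = length(packets),
      n_cohorts = cfg$n_genes,
      n_diseases = sum(cohorts$n_diseases),
      n_unique_alleles = sum(cohorts$n_unique_alleles),
      n_publications = sum(cohorts$n_publications),
      n_present = sum(cohorts$n_present_annotations),
      n_excluded = sum(cohorts$n_excluded_annotations),
      n_features = tot_feats,
      n_features_with_onset = tot_onset,
      sex_counts = as.list(sex_tally),
      planted = list(p_onset = cfg$p_onset,
                     p_sex_specified = cfg$p_sex_specified,
                     p_male_given_specified = cfg$p_male_given_specified)
    )
    list(phenopackets = packets,
         ground_truth = list(cohorts = cohorts, totals = totals),
         ontology = g)
  })
}

#' Inject rule violations into a clean corpus
#'
#' Mutates exactly `k` independent sites so that validation reports exactly
#' `k` issues of the named rule and nothing else — sharp oracles for
#' validator tests. Site selection is seeded and deterministic.
#'
#' @param ps List of [phenopacket()] objects (rule-clean, e.g. from
#'   [generate_corpus()]).
#' @param rule_id One of the ids in [validation_rules()].
#' @param k Number of violations (0 returns the corpus unchanged).
#' @param seed Integer seed for site selection.
#' @param ontology The [ontology_graph()] the corpus annotates against;
#'   required for R3--R7.
#' @return A list with `phenopackets` (mutated corpus) and `mutated_ids`.
#' @export
inject_faults <- function(ps, rule_id, k, seed = 1, ontology = NULL) {
  rule_id <- arg_match(rule_id, validation_rules()$rule_id)
  stopifnot(k >= 0)
  if (k == 0) return(list(phenopackets = ps, mutated_ids = character(0)))
  if (rule_id %in% c("R3", "R4", "R5", "R6", "R7") && is.null(ontology)) {
    abort("ontology required for feature-level fault injection",
          class = "phenocurator_argument_error")
  }
  with_local_seed(seed, {
    mutated <- switch(rule_id,
      R1 = inject_simple(ps, k, function(p) TRUE, function(p) {
        p$id <- sub("^PMID_", "BADID_", p$id); p
      }),
      R2 = inject_simple(ps, k, function(p) length(p$interpretations) > 0,
        function(p) {
          p$interpretations[[1]]$diagnosis_disease$id <- "OMIM:000001"
          p
        }),
      R3 = inject_feature(ps, k, function(p, f) TRUE, function(p, fi, n) {
        p$phenotypic_features[[fi]]$type$id <- sprintf("HP:888%04d", n)
        p
      }),
      R4 = inject_obsolete(ps, k, ontology),
      R5 = inject_feature(ps, k, function(p, f) has_term(ontology, f$type$id) &&
                            !term_obsolete(ontology, f$type$id),
        function(p, fi, n) {
          p$phenotypic_features[[fi]]$type$label <-
            paste0(p$phenotypic_features[[fi]]$type$label, " (mislabeled)")
          p
        }),
      R6 = inject_conflict(ps, k, ontology),
      R7 = inject_redundancy(ps, k, ontology),
      R8 = inject_feature(ps, k, function(p, f)
          !is.null(p$subject$time_at_last_encounter),
        function(p, fi, n) {
          p$phenotypic_features[[fi]]$onset <- parse_age("P99Y")
          p
        }),
      R9 = inject_simple(ps, k, function(p) {
          "GENO" %in% used_prefixes(p) &&
            "GENO" %in% map_chr(p$meta_data$resources, "namespace_prefix")
        }, function(p) {
          keep <- map_chr(p$meta_data$resources, "namespace_prefix") != "GENO"
          p$meta_data$resources <- p$meta_data$resources[keep]
          p
        }),
      R10 = inject_counted(ps, k, function(p) length(p$diseases) == 1,
        function(p, n) {
          extra <- disease_dx(ontology_class(sprintf("OMIM:999%03d", n),
                                             "Synthetic co-diagnosis"))
          p$diseases <- c(p$diseases, list(extra))
          p
        }),
      C1 = inject_duplicate_ids(ps, k),
      C2 = inject_duplicate_individuals(ps, k)
    )
    mutated
  })
}

infeasible <- function(rule, k, available) {
  abort(paste0("cannot inject ", k, " ", rule, " fault(s): only ", available,
               " feasible site(s)"), class = "phenocurator_argument_error")
}

inject_simple <- function(ps, k, eligible, mutate_fn) {
  sites <- which(map_lgl(ps, eligible))
  if (length(sites) < k) infeasible("packet-level", k, length(sites))
  picks <- sample(sites, k)
  for (i in picks) ps[[i]] <- mutate_fn(ps[[i]])
  list(phenopackets = ps, mutated_ids = map_chr(ps[picks], "id"))
}

inject_counted <- function(ps, k, eligible, mutate_fn) {
  sites <- which(map_lgl(ps, eligible))
  if (length(sites) < k) infeasible("packet-level", k, length(sites))
  picks <- sample(sites, k)
  for (n in seq_along(picks)) ps[[picks[[n]]]] <- mutate_fn(ps[[picks[[n]]]], n)
  list(phenopackets = ps, mutated_ids = map_chr(ps[picks], "id"))
}

# sites are (packet, feature) pairs; each injection hits a distinct feature
inject_feature <- function(ps, k, eligible, mutate_fn) {
  sites <- list()
  for (i in seq_along(ps)) {
    for (fi in seq_along(ps[[i]]$phenotypic_features)) {
      if (eligible(ps[[i]], ps[[i]]$phenotypic_features[[fi]])) {
        sites <- c(sites, list(c(i, fi)))
      }
    }
  }
  if (length(sites) < k) infeasible("feature-level", k, length(sites))
  picks <- sample(sites, k)
  for (n in seq_along(picks)) {
    i <- picks[[n]][[1]]; fi <- picks[[n]][[2]]
    ps[[i]] <- mutate_fn(ps[[i]], fi, n)
  }
  list(phenopackets = ps,
       mutated_ids = unique(map_chr(picks, function(s) ps[[s[[1]]]]$id)))
}

inject_obsolete <- function(ps, k, g) {
  terms <- ontology_terms(g)
  obsolete <- terms[terms$obsolete, ]
  if (nrow(obsolete) < k) infeasible("R4", k, nrow(obsolete))
  obs_pick <- obsolete[sample.int(nrow(obsolete), k), ]
  inject_feature(ps, k, function(p, f) TRUE, function(p, fi, n) {
    p$phenotypic_features[[fi]]$type$id <- obs_pick$id[[n]]
    p$phenotypic_features[[fi]]$type$label <- obs_pick$label[[n]]
    p
  })
}

packet_term_ids <- function(p) map_chr(p$phenotypic_features, function(f) f$type$id)

# A child of `term` that is absent from the packet, not obsolete, and whose
# subtree contains no packet term (so adding it creates exactly one finding).
free_child <- function(g, term, terms_in_packet) {
  for (ch in g$children[[term]] %||% character()) {
    if (ch %in% terms_in_packet || term_obsolete(g, ch)) next
    if (length(intersect(descendants(g, ch, include_self = TRUE),
                         terms_in_packet)) == 0) return(ch)
  }
  NULL
}

inject_conflict <- function(ps, k, g) {
  sites <- list()   # (packet index, new observed child term)
  for (i in seq_along(ps)) {
    tids <- packet_term_ids(ps[[i]])
    excl <- tids[map_lgl(ps[[i]]$phenotypic_features, "excluded")]
    for (e in excl) {
      if (!has_term(g, e)) next
      ch <- free_child(g, e, tids)
      if (!is.null(ch)) { sites <- c(sites, list(list(i = i, child = ch))); break }
    }
  }
  if (length(sites) < k) infeasible("R6", k, length(sites))
  picks <- sample(sites, k)
  for (s in picks) {
    ps[[s$i]]$phenotypic_features <- c(
      ps[[s$i]]$phenotypic_features,
      list(phenotypic_feature(ontology_class(s$child, term_label(g, s$child)),
                              excluded = FALSE)))
  }
  list(phenopackets = ps, mutated_ids = map_chr(picks, function(s) ps[[s$i]]$id))
}

inject_redundancy <- function(ps, k, g) {
  sites <- list()   # (packet index, observed parent term to add)
  for (i in seq_along(ps)) {
    tids <- packet_term_ids(ps[[i]])
    obs <- tids[!map_lgl(ps[[i]]$phenotypic_features, "excluded")]
    for (o in obs) {
      if (!has_term(g, o)) next
      for (par in g$parents[[o]]) {
        if (par == g$root || (g$virtual_root && par == g$root)) next
        if (par %in% tids || term_obsolete(g, par)) next
        below <- intersect(descendants(g, par, include_self = FALSE), tids)
        if (identical(below, o)) {
          sites <- c(sites, list(list(i = i, parent = par)))
          break
        }
      }
      if (length(sites) > 0 && sites[[length(sites)]]$i == i) break
    }
  }
  if (length(sites) < k) infeasible("R7", k, length(sites))
  picks <- sample(sites, k)
  for (s in picks) {
    ps[[s$i]]$phenotypic_features <- c(
      ps[[s$i]]$phenotypic_features,
      list(phenotypic_feature(ontology_class(s$parent, term_label(g, s$parent)),
                              excluded = FALSE)))
  }
  list(phenopackets = ps, mutated_ids = map_chr(picks, function(s) ps[[s$i]]$id))
}

inject_duplicate_ids <- function(ps, k) {
  if (length(ps) < k + 1) infeasible("C1", k, length(ps) - 1)
  targets <- sample(2:length(ps), k)
  for (i in targets) ps[[i]]$id <- ps[[1]]$id
  list(phenopackets = ps, mutated_ids = map_chr(ps[targets], "id"))
}

inject_duplicate_individuals <- function(ps, k) {
  pmids <- pmid_of(map_chr(ps, "id"))
  groups <- split(seq_along(ps), pmids)
  groups <- groups[lengths(groups) >= 2]
  if (length(groups) < k) infeasible("C2", k, length(groups))
  picks <- sample(groups, k)
  ids <- character(0)
  for (grp in picks) {
    src <- grp[[1]]; tgt <- grp[[2]]
    ps[[tgt]]$subject$id <- ps[[src]]$subject$id
    ids <- c(ids, ps[[tgt]]$id)
  }
  list(phenopackets = ps, mutated_ids = ids)
}
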