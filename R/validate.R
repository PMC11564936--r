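#' Validation rule registry
#'
#' Quality-control rules applied to single phenopackets (R1--R10) and whole
#' corpora (C1--C2). Severity defaults encode curation practice: logical
#' contradictions and broken cross-references block publication (ERROR),
#' hygiene findings do not (WARNING).
#'
#' @return A tibble with columns `rule_id`, `level`, `description`.
#' @export
validation_rules <- function() {
  tibble(
    rule_id = c("R1", "R2", "R3", "R4", "R5", "R6", "R7", "R8", "R9", "R10",
                "C1", "C2"),
    level = c("ERROR", "ERROR", "ERROR", "WARNING", "WARNING", "ERROR",
              "WARNING", "WARNING", "WARNING", "WARNING", "ERROR", "ERROR"),
    description = c(
      "phenopacket id matches PMID_<pmid>_<individual>",
      "interpretation diagnosis id matches a top-level disease",
      "feature HPO term exists in the ontology",
      "feature HPO term is not obsolete",
      "feature label matches the ontology label (case-sensitive)",
      "no observed feature has an excluded ancestor (annotation conflict)",
      "no redundant observed-ancestor or excluded-descendant annotations",
      "feature/disease onset not later than age at last encounter",
      "every CURIE prefix used has a metadata resource",
      "at most one disease entry (corpus convention)",
      "phenopacket ids unique across the corpus",
      "(PMID, individual id) pairs unique across the corpus"
    )
  )
}

#' Configure validation rules
#'
#' Rules can be disabled or have their severity overridden (only between
#' ERROR and WARNING).
#'
#' @param disable Character vector of rule ids to switch off.
#' @param levels Named character vector of severity overrides, e.g.
#'   `c(R5 = "ERROR")`.
#' @return A `rule_config` object.
#' @export
rule_config <- function(disable = character(), levels = character()) {
  reg <- validation_rules()
  bad <- setdiff(c(disable, names(levels)), reg$rule_id)
  if (length(bad) > 0) {
    abort(paste0("unknown rule id: ", bad[[1]]), class = "phenocurator_argument_error")
  }
  if (length(levels) > 0 && !all(levels %in% c("ERROR", "WARNING"))) {
    abort("level overrides must be ERROR or WARNING",
          class = "phenocurator_argument_error")
  }
  reg$enabled <- !reg$rule_id %in% disable
  reg$level[match(names(levels), reg$rule_id)] <- unname(levels)
  structure(list(rules = reg), class = "rule_config")
}

issue_tibble <- function(level = character(), rule_id = character(),
                         phenopacket_id = character(), message = character()) {
  tibble(level = level, rule_id = rule_id, phenopacket_id = phenopacket_id,
         message = message)
}

emit <- function(cfg, rule_id, pid, message) {
  row <- cfg$rules[cfg$rules$rule_id == rule_id, ]
  if (!row$enabled) return(issue_tibble())
  issue_tibble(row$level, rule_id, pid, message)
}

#' Validate a single phenopacket
#'
#' Applies the per-phenopacket rules R1--R10 (see [validation_rules()]).
#' Issues are data, not exceptions: the return value is a tibble with one
#' row per finding.
#'
#' The ontology-consistency rules follow annotation-propagation logic: an
#' observed term implies all its ancestors, an excluded term implies
#' exclusion of all its descendants. R6 therefore flags an observed feature
#' whose term has an excluded ancestor (or is itself excluded); R7 flags
#' redundant annotations (an observed feature with an observed proper
#' ancestor, or an excluded feature with an excluded proper ancestor).
#'
#' @param p A [phenopacket()].
#' @param g An [ontology_graph()].
#' @param cfg A [rule_config()].
#' @param anc Precomputed ancestor map (internal; computed when `NULL`).
#' @return A tibble with columns `level`, `rule_id`, `phenopacket_id`,
#'   `message`.
#' @export
validate_phenopacket <- function(p, g, cfg = rule_config(), anc = NULL) {
  stopifnot(inherits(p, "phenopacket"), inherits(g, "ontology_graph"),
            inherits(cfg, "rule_config"))
  if (is.null(anc)) anc <- ancestor_map(g)
  pid <- p$id
  issues <- list()

  # R1 id format
  if (!is_phenopacket_id(pid)) {
    issues <- c(issues, list(emit(cfg, "R1", pid,
      paste0("id does not match PMID_<pmid>_<individual>: ", pid))))
  }

  # R2 diagnosis cross-reference
  disease_ids <- map_chr(p$diseases, function(d) d$term$id)
  for (i in p$interpretations) {
    if (!i$diagnosis_disease$id %in% disease_ids) {
      issues <- c(issues, list(emit(cfg, "R2", pid,
        paste0("diagnosis ", i$diagnosis_disease$id,
               " does not match any disease in the top-level list"))))
    }
  }

  feats <- p$phenotypic_features
  term_ids <- map_chr(feats, function(f) f$type$id)
  in_graph <- map_lgl(term_ids, function(t) has_term(g, t))

  # R3 term exists / R4 obsolete / R5 label match
  for (k in seq_along(feats)) {
    t <- term_ids[[k]]
    if (!in_graph[[k]]) {
      issues <- c(issues, list(emit(cfg, "R3", pid,
        paste0("HPO term not in ontology: ", t))))
      next
    }
    if (term_obsolete(g, t)) {
      issues <- c(issues, list(emit(cfg, "R4", pid,
        paste0("obsolete HPO term used: ", t))))
    }
    lbl <- term_label(g, t)
    if (!identical(feats[[k]]$type$label, lbl)) {
      issues <- c(issues, list(emit(cfg, "R5", pid,
        paste0("label mismatch for ", t, ": \"", feats[[k]]$type$label,
               "\" vs ontology \"", lbl, "\""))))
    }
  }

  # R6 conflict / R7 redundancy, over terms resolvable in the graph
  observed <- term_ids[in_graph & !map_lgl(feats, "excluded")]
  excluded <- term_ids[in_graph & map_lgl(feats, "excluded")]
  for (o in observed) {
    anc_self <- anc[[o]]                      # includes the term itself
    hit <- intersect(excluded, anc_self)
    if (length(hit) > 0) {
      issues <- c(issues, list(emit(cfg, "R6", pid,
        paste0("observed ", o, " conflicts with excluded ancestor ",
               hit[[1]]))))
    }
    prop_anc <- setdiff(anc_self, o)
    red <- intersect(observed, prop_anc)
    if (length(red) > 0) {
      issues <- c(issues, list(emit(cfg, "R7", pid,
        paste0("observed ", o, " is redundant: ancestor ", red[[1]],
               " also observed"))))
    }
  }
  for (e in excluded) {
    prop_anc <- setdiff(anc[[e]], e)
    red <- intersect(excluded, prop_anc)
    if (length(red) > 0) {
      issues <- c(issues, list(emit(cfg, "R7", pid,
        paste0("excluded ", e, " is redundant: ancestor ", red[[1]],
               " also excluded"))))
    }
  }

  # R8 onset ordering
  last_enc <- p$subject$time_at_last_encounter
  if (!is.null(last_enc)) {
    for (k in seq_along(feats)) {
      if (!is.null(feats[[k]]$onset) &&
          compare_age(feats[[k]]$onset, last_enc) > 0) {
        issues <- c(issues, list(emit(cfg, "R8", pid,
          paste0("feature ", term_ids[[k]], " onset ",
                 feats[[k]]$onset$iso8601, " later than last encounter ",
                 last_enc$iso8601))))
      }
    }
    for (d in p$diseases) {
      if (!is.null(d$onset) && compare_age(d$onset, last_enc) > 0) {
        issues <- c(issues, list(emit(cfg, "R8", pid,
          paste0("disease ", d$term$id, " onset ", d$onset$iso8601,
                 " later than last encounter ", last_enc$iso8601))))
      }
    }
  }

  # R9 prefix coverage
  registered <- map_chr(p$meta_data$resources, "namespace_prefix")
  for (pre in setdiff(used_prefixes(p), registered)) {
    issues <- c(issues, list(emit(cfg, "R9", pid,
      paste0("CURIE prefix ", pre, " has no metadata resource"))))
  }

  # R10 multi-disease
  if (length(p$diseases) > 1) {
    issues <- c(issues, list(emit(cfg, "R10", pid,
      paste0(length(p$diseases), " disease entries (corpus convention is 1)"))))
  }

  bind_rows(issue_tibble(), !!!issues)
}

#' Validate a corpus of phenopackets
#'
#' Runs [validate_phenopacket()] on every phenopacket and adds the
#' corpus-level rules: C1 (duplicate phenopacket ids; each duplicate beyond
#' the first is an ERROR) and C2 (duplicate (PMID, individual id) pairs).
#'
#' @param ps A list of [phenopacket()] objects.
#' @param g An [ontology_graph()].
#' @param cfg A [rule_config()].
#' @return An issue tibble (see [validate_phenopacket()]).
#' @export
validate_corpus <- function(ps, g, cfg = rule_config()) {
  anc <- ancestor_map(g)
  issues <- map(ps, validate_phenopacket, g = g, cfg = cfg, anc = anc)

  ids <- map_chr(ps, "id")
  dup <- duplicated(ids)
  for (k in which(dup)) {
    issues <- c(issues, list(emit(cfg, "C1", ids[[k]],
      paste0("duplicate phenopacket id: ", ids[[k]]))))
  }

  pair <- paste0(pmid_of(ids), "|", map_chr(ps, function(p) p$subject$id))
  pair[is.na(pmid_of(ids))] <- NA_character_
  dup2 <- duplicated(pair, incomparables = NA)
  for (k in which(dup2)) {
    issues <- c(issues, list(emit(cfg, "C2", ids[[k]],
      paste0("duplicate (PMID, individual id) pair: PMID ", pmid_of(ids[[k]]),
             ", individual ", ps[[k]]$subject$id))))
  }

  bind_rows(issue_tibble(), !!!issues)
}

#' Render an issue report
#'
#' Issues are sorted by (level descending so ERROR precedes WARNING, rule id,
#' phenopacket id) — a stable, deterministic order.
#'
#' @param issues An issue tibble.
#' @param format `"tsv"` or `"json"`.
#' @param path Optional output file; when `NULL` the document is returned as
#'   a string.
#' @return The report as a single string (invisibly when written to `path`).
#' @export
issue_report <- function(issues, format = c("tsv", "json"), path = NULL) {
  format <- arg_match(format)
  # severity descending: ERROR sorts before WARNING (alphabetical ascending)
  sorted <- arrange(issues, .data$level, .data$rule_id, .data$phenopacket_id)
  if (format == "tsv") {
    doc <- readr::format_tsv(sorted)
  } else {
    doc <- as.character(jsonlite::toJSON(sorted, dataframe = "rows", pretty = 2))
  }
  if (!is.null(path)) {
    writeLines(doc, path, sep = if (format == "tsv") "" else "\n", useBytes = TRUE)
    return(invisible(doc))
  }
  doc
}

n_errors <- function(issues) sum(issues$level == "ERROR")
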