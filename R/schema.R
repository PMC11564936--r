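#' Schema building blocks
#'
#' Constructors for the in-memory model of the Phenopacket Schema subset this
#' package curates: subject, phenotypic features, diseases, genomic
#' interpretations and metadata. Every constructor validates its invariants;
#' no partially valid object is observable.
#'
#' @name schema
NULL

SEX_VALUES <- c("MALE", "FEMALE", "OTHER_SEX", "UNKNOWN_SEX")

abort_validation <- function(field, msg) {
  abort(paste0(field, ": ", msg), class = "phenocurator_validation_error",
        field = field)
}

as_age <- function(x, field) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) {
    return(tryCatch(parse_age(x),
                    error = function(e) abort_validation(field, conditionMessage(e))))
  }
  if (!inherits(x, "age_value")) abort_validation(field, "not an age")
  x
}

chr1 <- function(x, field, allow_empty = FALSE) {
  if (!is.character(x) || length(x) != 1 || is.na(x)) {
    abort_validation(field, "must be a single string")
  }
  if (!allow_empty && !nzchar(x)) abort_validation(field, "must be nonempty")
  x
}

#' @rdname schema
#' @param id Identifier (CURIE for ontology classes).
#' @param label Human-readable label.
#' @export
ontology_class <- function(id, label) {
  id <- chr1(id, "id")
  label <- chr1(label, "label")
  if (!is_curie(id)) abort_validation("id", paste0("not a CURIE: ", id))
  structure(list(id = id, label = label), class = "ontology_class")
}

#' @rdname schema
#' @param sex One of `"MALE"`, `"FEMALE"`, `"OTHER_SEX"`, `"UNKNOWN_SEX"`.
#' @param time_at_last_encounter Optional age at the latest examination
#'   (`age_value` or ISO 8601 string).
#' @param deceased Optional logical; `FALSE` is normalized to absent
#'   (protobuf JSON default-omission semantics).
#' @param age_of_death Optional age; implies `deceased = TRUE`.
#' @export
individual <- function(id, sex = "UNKNOWN_SEX", time_at_last_encounter = NULL,
                       deceased = NULL, age_of_death = NULL) {
  id <- chr1(id, "id")
  sex <- arg_match(sex, SEX_VALUES)
  time_at_last_encounter <- as_age(time_at_last_encounter, "time_at_last_encounter")
  age_of_death <- as_age(age_of_death, "age_of_death")
  if (!is.null(deceased) && !isTRUE(deceased)) deceased <- NULL
  if (!is.null(age_of_death) && !isTRUE(deceased)) {
    abort_validation("deceased", "age_of_death present requires deceased = TRUE")
  }
  structure(
    list(id = id, sex = sex, time_at_last_encounter = time_at_last_encounter,
         deceased = deceased, age_of_death = age_of_death),
    class = "pheno_individual"
  )
}

#' @rdname schema
#' @param type An [ontology_class()] with an HPO id.
#' @param excluded `TRUE` when the feature was investigated and found absent.
#' @param onset Optional age of onset of the feature.
#' @export
phenotypic_feature <- function(type, excluded = FALSE, onset = NULL) {
  stopifnot(inherits(type, "ontology_class"))
  if (!is_hpo_id(type$id)) {
    abort_validation("type.id", paste0("not an HPO id: ", type$id))
  }
  stopifnot(is.logical(excluded), length(excluded) == 1, !is.na(excluded))
  structure(
    list(type = type, excluded = excluded, onset = as_age(onset, "onset")),
    class = "phenotypic_feature"
  )
}

#' @rdname schema
#' @param term An [ontology_class()] with an `OMIM:` or `MONDO:` id.
#' @export
disease_dx <- function(term, onset = NULL) {
  stopifnot(inherits(term, "ontology_class"))
  if (!curie_prefix(term$id) %in% c("OMIM", "MONDO")) {
    abort_validation("term.id", paste0("disease id must use OMIM or MONDO prefix: ", term$id))
  }
  structure(list(term = term, onset = as_age(onset, "onset")), class = "disease_dx")
}

#' @rdname schema
#' @param hgnc_id HGNC gene identifier, `HGNC:<digits>`.
#' @param symbol Gene symbol.
#' @export
gene_context <- function(hgnc_id, symbol) {
  hgnc_id <- chr1(hgnc_id, "hgnc_id")
  symbol <- chr1(symbol, "symbol")
  if (!grepl("^HGNC:[0-9]+$", hgnc_id)) {
    abort_validation("hgnc_id", paste0("must match HGNC:<digits>: ", hgnc_id))
  }
  structure(list(hgnc_id = hgnc_id, symbol = symbol), class = "gene_context")
}

#' @rdname schema
#' @param syntax One of `"hgvs.c"`, `"hgvs.g"`, `"hgvs.p"`.
#' @param value HGVS expression string.
#' @export
hgvs_expression <- function(syntax, value) {
  syntax <- arg_match(syntax, c("hgvs.c", "hgvs.g", "hgvs.p"))
  value <- chr1(value, "value")
  structure(list(syntax = syntax, value = value), class = "hgvs_expression")
}

#' GENO allelic-state classes
#'
#' The default zygosity vocabulary binding: GENO ontology classes for
#' heterozygous, homozygous and hemizygous states. The mapping is a plain
#' named list of id/label pairs and can be overridden where other bindings
#' are in use.
#'
#' @param state One of `"heterozygous"`, `"homozygous"`, `"hemizygous"`.
#' @param mapping A named list `state -> list(id, label)`.
#' @return An [ontology_class()].
#' @export
geno_allelic_state <- function(state, mapping = geno_default_mapping()) {
  state <- arg_match(state, names(mapping))
  ontology_class(mapping[[state]]$id, mapping[[state]]$label)
}

#' @rdname geno_allelic_state
#' @export
geno_default_mapping <- function() {
  list(
    heterozygous = list(id = "GENO:0000135", label = "heterozygous"),
    homozygous   = list(id = "GENO:0000136", label = "homozygous"),
    hemizygous   = list(id = "GENO:0000134", label = "hemizygous")
  )
}

#' @rdname schema
#' @param gene A [gene_context()].
#' @param expressions List of [hgvs_expression()] objects; mutually exclusive
#'   with `sv_label`.
#' @param sv_label Qualitative structural-variant description (e.g.
#'   `"gene deletion"`); mutually exclusive with `expressions`.
#' @param allelic_state An [ontology_class()] (GENO).
#' @export
variation_descriptor <- function(id, gene, expressions = list(), sv_label = NULL,
                                 allelic_state) {
  id <- chr1(id, "id")
  stopifnot(inherits(gene, "gene_context"), inherits(allelic_state, "ontology_class"))
  stopifnot(is.list(expressions))
  for (e in expressions) stopifnot(inherits(e, "hgvs_expression"))
  has_expr <- length(expressions) > 0
  has_sv <- !is.null(sv_label)
  if (has_sv) sv_label <- chr1(sv_label, "sv_label")
  if (has_expr == has_sv) {
    abort_validation("expressions",
                     "a variant is either HGVS-described or qualitatively labeled (exactly one)")
  }
  structure(
    list(id = id, gene = gene, expressions = expressions, sv_label = sv_label,
         allelic_state = allelic_state),
    class = "variation_descriptor"
  )
}

#' Build a qualitative structural-variant descriptor
#'
#' Structural variants reported in the literature only as qualitative
#' descriptions (e.g. `"gene deletion"`) are represented by a descriptor with
#' a label and no HGVS expressions.
#'
#' @param gene A [gene_context()].
#' @param label The qualitative description; must be nonempty.
#' @param allelic_state An [ontology_class()] (GENO).
#' @param id Descriptor identifier.
#' @return A [variation_descriptor()].
#' @export
build_sv_descriptor <- function(gene, label, allelic_state, id = "sv") {
  label <- chr1(label, "label")
  variation_descriptor(id = id, gene = gene, sv_label = label,
                       allelic_state = allelic_state)
}

#' @rdname schema
#' @param status Genomic-interpretation status; this corpus uses `"CAUSATIVE"`.
#' @param descriptor A [variation_descriptor()].
#' @export
genomic_interpretation <- function(descriptor, status = "CAUSATIVE") {
  status <- arg_match(status, "CAUSATIVE")
  stopifnot(inherits(descriptor, "variation_descriptor"))
  structure(list(status = status, descriptor = descriptor),
            class = "genomic_interpretation")
}

#' @rdname schema
#' @param progress_status Interpretation progress; this corpus uses `"SOLVED"`.
#' @param diagnosis_disease An [ontology_class()]; must match a disease in the
#'   owning phenopacket's top-level disease list (checked by
#'   [validate_phenopacket()]).
#' @param genomic_interpretations List of [genomic_interpretation()] objects.
#' @export
interpretation <- function(id, diagnosis_disease, genomic_interpretations = list(),
                           progress_status = "SOLVED") {
  id <- chr1(id, "id")
  progress_status <- arg_match(progress_status, "SOLVED")
  stopifnot(inherits(diagnosis_disease, "ontology_class"))
  stopifnot(is.list(genomic_interpretations))
  for (gi in genomic_interpretations) stopifnot(inherits(gi, "genomic_interpretation"))
  structure(
    list(id = id, progress_status = progress_status,
         diagnosis_disease = diagnosis_disease,
         genomic_interpretations = genomic_interpretations),
    class = "pheno_interpretation"
  )
}

#' @rdname schema
#' @param name,url,version,namespace_prefix,iri_prefix Resource fields as in
#'   the schema's metadata block.
#' @export
resource <- function(id, name, url, version, namespace_prefix, iri_prefix) {
  structure(
    list(id = chr1(id, "id"), name = chr1(name, "name"), url = chr1(url, "url"),
         version = chr1(version, "version"),
         namespace_prefix = chr1(namespace_prefix, "namespace_prefix"),
         iri_prefix = chr1(iri_prefix, "iri_prefix")),
    class = "pheno_resource"
  )
}

#' @rdname schema
#' @param created Creation timestamp string (RFC 3339).
#' @param created_by Curator or tool name.
#' @param resources List of [resource()] objects registering every CURIE
#'   prefix used in the phenopacket.
#' @param schema_version Phenopacket Schema version string.
#' @export
meta_data <- function(created, created_by, resources = list(),
                      schema_version = "2.0") {
  stopifnot(is.list(resources))
  for (r in resources) stopifnot(inherits(r, "pheno_resource"))
  structure(
    list(created = chr1(created, "created"),
         created_by = chr1(created_by, "created_by"),
         resources = resources,
         schema_version = chr1(schema_version, "schema_version")),
    class = "pheno_meta_data"
  )
}

#' Default metadata resources
#'
#' Resource entries for the CURIE prefixes this corpus convention uses:
#' HP, OMIM, MONDO, GENO and HGNC.
#'
#' @param prefixes Which namespace prefixes to include.
#' @return A list of [resource()] objects.
#' @export
default_resources <- function(prefixes = c("HP", "OMIM", "GENO", "HGNC")) {
  all <- list(
    HP = resource("hp", "human phenotype ontology", "http://purl.obolibrary.org/obo/hp.owl",
                  "unversioned", "HP", "http://purl.obolibrary.org/obo/HP_"),
    OMIM = resource("omim", "An Online Catalog of Human Genes and Genetic Disorders",
                    "https://www.omim.org", "unversioned", "OMIM",
                    "https://www.omim.org/entry/"),
    MONDO = resource("mondo", "Mondo Disease Ontology",
                     "http://purl.obolibrary.org/obo/mondo.obo", "unversioned",
                     "MONDO", "http://purl.obolibrary.org/obo/MONDO_"),
    GENO = resource("geno", "Genotype Ontology",
                    "http://purl.obolibrary.org/obo/geno.owl", "unversioned",
                    "GENO", "http://purl.obolibrary.org/obo/GENO_"),
    HGNC = resource("hgnc", "HUGO Gene Nomenclature Committee",
                    "https://www.genenames.org", "unversioned", "HGNC",
                    "https://www.genenames.org/data/gene-symbol-report/#!/hgnc_id/")
  )
  unname(all[prefixes])
}

#' Construct a phenopacket
#'
#' The top-level record for one individual: subject, phenotypic features
#' (present or excluded HPO terms, optionally with onset), disease
#' diagnoses, genomic interpretations, and provenance metadata. The id must
#' follow the `PMID_<pmid>_<individual>` convention and the feature list may
#' not contain duplicate (term, excluded) pairs.
#'
#' @param id Phenopacket identifier (see [make_phenopacket_id()]).
#' @param subject An [individual()].
#' @param phenotypic_features List of [phenotypic_feature()] objects.
#' @param diseases List of [disease_dx()] objects.
#' @param interpretations List of [interpretation()] objects.
#' @param meta_data A [meta_data()] block.
#' @return An object of class `phenopacket`.
#' @export
phenopacket <- function(id, subject, phenotypic_features = list(),
                        diseases = list(), interpretations = list(), meta_data) {
  id <- chr1(id, "id")
  if (!is_phenopacket_id(id)) {
    abort_validation("id", paste0("does not match PMID_<pmid>_<individual>: ", id))
  }
  stopifnot(inherits(subject, "pheno_individual"), inherits(meta_data, "pheno_meta_data"))
  stopifnot(is.list(phenotypic_features), is.list(diseases), is.list(interpretations))
  for (f in phenotypic_features) stopifnot(inherits(f, "phenotypic_feature"))
  for (d in diseases) stopifnot(inherits(d, "disease_dx"))
  for (i in interpretations) stopifnot(inherits(i, "pheno_interpretation"))
  keys <- map_chr(phenotypic_features, function(f) paste0(f$type$id, "|", f$excluded))
  if (anyDuplicated(keys)) {
    abort_validation("phenotypic_features",
                     paste0("duplicate (term, excluded) pair: ", keys[duplicated(keys)][[1]]))
  }
  structure(
    list(id = id, subject = subject, phenotypic_features = phenotypic_features,
         diseases = diseases, interpretations = interpretations,
         meta_data = meta_data),
    class = "phenopacket"
  )
}

#' @export
print.phenopacket <- function(x, ...) {
  n_obs <- sum(!map_lgl(x$phenotypic_features, "excluded"))
  n_exc <- length(x$phenotypic_features) - n_obs
  cat("<phenopacket> ", x$id, "\n",
      "  subject: ", x$subject$id, " (", x$subject$sex, ")\n",
      "  features: ", n_obs, " present, ", n_exc, " excluded\n",
      "  diseases: ", length(x$diseases),
      "; interpretations: ", length(x$interpretations), "\n", sep = "")
  invisible(x)
}

# All CURIE prefixes referenced anywhere in a phenopacket
used_prefixes <- function(p) {
  ids <- c(
    map_chr(p$phenotypic_features, function(f) f$type$id),
    map_chr(p$diseases, function(d) d$term$id),
    map_chr(p$interpretations, function(i) i$diagnosis_disease$id),
    unlist(map(p$interpretations, function(i)
      map_chr(i$genomic_interpretations, function(gi)
        gi$descriptor$allelic_state$id)), use.names = FALSE),
    unlist(map(p$interpretations, function(i)
      map_chr(i$genomic_interpretations, function(gi)
        gi$descriptor$gene$hgnc_id)), use.names = FALSE)
  )
  unique(curie_prefix(ids))
}

# Gene symbol of the first genomic interpretation, or NA
first_gene_symbol <- function(p) {
  for (i in p$interpretations) {
    for (gi in i$genomic_interpretations) {
      return(gi$descriptor$gene$symbol)
    }
  }
  NA_character_
}

# Allele keys (gene symbol + first HGVS expression value or sv_label)
allele_keys <- function(p) {
  out <- character(0)
  for (i in p$interpretations) {
    for (gi in i$genomic_interpretations) {
      d <- gi$descriptor
      val <- if (length(d$expressions) > 0) d$expressions[[1]]$value else d$sv_label
      out <- c(out, paste0(d$gene$symbol, "|", val))
    }
  }
  out
}
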