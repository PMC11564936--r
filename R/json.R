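#' Phenopacket JSON serialization
#'
#' Phenopackets are stored as one UTF-8 JSON file per individual. Output is
#' canonical so that equal objects produce byte-identical files: field names
#' in lowerCamelCase (the protobuf JSON mapping), object keys in schema
#' declaration order, 2-space indent, enums as strings, absent optionals and
#' default values (`false`, empty lists, `UNKNOWN_SEX`) omitted rather than
#' written as `null`, and a trailing newline.
#'
#' @name phenopacket_json
NULL

compact_list <- function(...) {
  x <- list(...)
  x[!vapply(x, is.null, logical(1))]
}

time_element_json <- function(age) {
  if (is.null(age)) return(NULL)
  list(age = list(iso8601duration = age$iso8601))
}

ontology_class_json <- function(oc) list(id = oc$id, label = oc$label)

phenopacket_to_list <- function(p) {
  subject <- compact_list(
    id = p$subject$id,
    timeAtLastEncounter = time_element_json(p$subject$time_at_last_encounter),
    sex = if (p$subject$sex != "UNKNOWN_SEX") p$subject$sex,
    deceased = p$subject$deceased,
    ageOfDeath = time_element_json(p$subject$age_of_death)
  )
  features <- map(p$phenotypic_features, function(f) compact_list(
    type = ontology_class_json(f$type),
    excluded = if (f$excluded) TRUE,
    onset = time_element_json(f$onset)
  ))
  interpretations <- map(p$interpretations, function(i) list(
    id = i$id,
    progressStatus = i$progress_status,
    diagnosis = list(
      disease = ontology_class_json(i$diagnosis_disease),
      genomicInterpretations = map(i$genomic_interpretations, function(gi) list(
        interpretationStatus = gi$status,
        variationDescriptor = compact_list(
          id = gi$descriptor$id,
          geneContext = list(valueId = gi$descriptor$gene$hgnc_id,
                             symbol = gi$descriptor$gene$symbol),
          expressions = if (length(gi$descriptor$expressions) > 0)
            map(gi$descriptor$expressions, function(e)
              list(syntax = e$syntax, value = e$value)),
          label = gi$descriptor$sv_label,
          allelicState = ontology_class_json(gi$descriptor$allelic_state)
        )
      ))
    )
  ))
  diseases <- map(p$diseases, function(d) compact_list(
    term = ontology_class_json(d$term),
    onset = time_element_json(d$onset)
  ))
  compact_list(
    id = p$id,
    subject = subject,
    phenotypicFeatures = if (length(features) > 0) features,
    interpretations = if (length(interpretations) > 0) interpretations,
    diseases = if (length(diseases) > 0) diseases,
    metaData = list(
      created = p$meta_data$created,
      createdBy = p$meta_data$created_by,
      resources = map(p$meta_data$resources, function(r) list(
        id = r$id, name = r$name, url = r$url, version = r$version,
        namespacePrefix = r$namespace_prefix, iriPrefix = r$iri_prefix
      )),
      phenopacketSchemaVersion = p$meta_data$schema_version
    )
  )
}

#' Write a phenopacket to a JSON file
#'
#' @param p A [phenopacket()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_phenopacket()]
#' @export
write_phenopacket <- function(p, path) {
  stopifnot(inherits(p, "phenopacket"))
  json <- jsonlite::toJSON(phenopacket_to_list(p), auto_unbox = TRUE, pretty = 2)
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) abort(paste0("cannot write ", path, ": ",
                                                   conditionMessage(e)),
                                            class = "phenocurator_io_error"))
  on.exit(close(con))
  writeLines(enc2utf8(as.character(json)), con, useBytes = TRUE)
  invisible(path)
}

# --- reading ----------------------------------------------------------------

camel_to_snake <- function(x) {
  tolower(gsub("([a-z0-9])([A-Z])", "\\1_\\2", x))
}

# Normalize one JSON object's keys to snake_case; record unknown keys.
take_keys <- function(obj, known, path, sink) {
  if (is.null(obj)) return(list())
  names(obj) <- camel_to_snake(names(obj))
  unknown <- setdiff(names(obj), known)
  if (length(unknown) > 0) {
    sink$keys <- c(sink$keys, paste0(path, ".", unknown))
  }
  obj[intersect(names(obj), known)]
}

read_time_element <- function(obj, path, sink) {
  if (is.null(obj)) return(NULL)
  names(obj) <- camel_to_snake(names(obj))
  if (!is.null(obj$age)) {
    obj <- take_keys(obj, "age", path, sink)
    iso <- obj$age$iso8601duration %||% obj$age$iso8601_duration
  } else {
    iso <- obj$iso8601duration %||% obj$iso8601_duration
  }
  if (is.null(iso)) {
    abort(paste0(path, ": time element has no iso8601duration"),
          class = "phenocurator_format_error")
  }
  parse_age(iso)
}

read_ontology_class <- function(obj, path) {
  if (is.null(obj$id) || is.null(obj$label)) {
    abort(paste0(path, ": ontology class needs id and label"),
          class = "phenocurator_format_error")
  }
  ontology_class(obj$id, obj$label)
}

#' Read a phenopacket from a JSON file
#'
#' Accepts both lowerCamelCase and snake_case key spellings. Unknown keys are
#' collected into the `"unknown_keys"` attribute of the result (a character
#' vector of dotted paths) rather than being fatal. All model invariants are
#' enforced on construction, so a file that parses but violates an invariant
#' raises a validation error naming the field.
#'
#' @param path Path to a phenopacket JSON file.
#' @return A [phenopacket()].
#' @export
read_phenopacket <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) abort(paste0("cannot parse ", path, ": ",
                                                   conditionMessage(e)),
                                            class = "phenocurator_format_error"))
  sink <- new.env(parent = emptyenv())
  sink$keys <- character(0)
  names(doc) <- camel_to_snake(names(doc))
  if (is.null(doc$id)) abort(paste0(path, ": missing \"id\""),
                             class = "phenocurator_format_error")
  if (is.null(doc$subject)) abort(paste0(path, ": missing \"subject\""),
                                  class = "phenocurator_format_error")
  doc <- take_keys(doc, c("id", "subject", "phenotypic_features", "interpretations",
                          "diseases", "meta_data"), "phenopacket", sink)

  s <- take_keys(doc$subject, c("id", "sex", "time_at_last_encounter", "deceased",
                                "age_of_death"), "subject", sink)
  subject <- individual(
    id = s$id %||% abort("subject: missing id", class = "phenocurator_format_error"),
    sex = s$sex %||% "UNKNOWN_SEX",
    time_at_last_encounter = read_time_element(s$time_at_last_encounter,
                                               "subject.timeAtLastEncounter", sink),
    deceased = s$deceased,
    age_of_death = read_time_element(s$age_of_death, "subject.ageOfDeath", sink)
  )

  features <- imap(doc$phenotypic_features %||% list(), function(f, idx) {
    pth <- paste0("phenotypicFeatures[", idx, "]")
    f <- take_keys(f, c("type", "excluded", "onset"), pth, sink)
    phenotypic_feature(
      type = read_ontology_class(f$type, paste0(pth, ".type")),
      excluded = isTRUE(f$excluded),
      onset = read_time_element(f$onset, paste0(pth, ".onset"), sink)
    )
  })

  diseases <- imap(doc$diseases %||% list(), function(d, idx) {
    pth <- paste0("diseases[", idx, "]")
    d <- take_keys(d, c("term", "onset"), pth, sink)
    disease_dx(term = read_ontology_class(d$term, paste0(pth, ".term")),
               onset = read_time_element(d$onset, paste0(pth, ".onset"), sink))
  })

  interpretations <- imap(doc$interpretations %||% list(), function(i, idx) {
    pth <- paste0("interpretations[", idx, "]")
    i <- take_keys(i, c("id", "progress_status", "diagnosis"), pth, sink)
    dg <- take_keys(i$diagnosis, c("disease", "genomic_interpretations"),
                    paste0(pth, ".diagnosis"), sink)
    gis <- imap(dg$genomic_interpretations %||% list(), function(gi, gidx) {
      gpth <- paste0(pth, ".diagnosis.genomicInterpretations[", gidx, "]")
      gi <- take_keys(gi, c("interpretation_status", "status", "variation_descriptor"),
                      gpth, sink)
      vd <- take_keys(gi$variation_descriptor,
                      c("id", "gene_context", "expressions", "label", "allelic_state"),
                      paste0(gpth, ".variationDescriptor"), sink)
      gc <- take_keys(vd$gene_context, c("value_id", "symbol"),
                      paste0(gpth, ".variationDescriptor.geneContext"), sink)
      genomic_interpretation(
        descriptor = variation_descriptor(
          id = vd$id %||% "variant",
          gene = gene_context(gc$value_id, gc$symbol),
          expressions = map(vd$expressions %||% list(), function(e)
            hgvs_expression(e$syntax, e$value)),
          sv_label = vd$label,
          allelic_state = read_ontology_class(vd$allelic_state,
                                              paste0(gpth, ".allelicState"))
        ),
        status = gi$interpretation_status %||% gi$status %||% "CAUSATIVE"
      )
    })
    interpretation(
      id = i$id, progress_status = i$progress_status %||% "SOLVED",
      diagnosis_disease = read_ontology_class(dg$disease, paste0(pth, ".diagnosis.disease")),
      genomic_interpretations = gis
    )
  })

  md <- take_keys(doc$meta_data %||%
                    abort(paste0(path, ": missing \"metaData\""),
                          class = "phenocurator_format_error"),
                  c("created", "created_by", "resources", "phenopacket_schema_version",
                    "schema_version"), "metaData", sink)
  metadata <- meta_data(
    created = md$created %||% "1970-01-01T00:00:00Z",
    created_by = md$created_by %||% "unknown",
    resources = imap(md$resources %||% list(), function(r, idx) {
      r <- take_keys(r, c("id", "name", "url", "version", "namespace_prefix",
                          "iri_prefix"), paste0("metaData.resources[", idx, "]"), sink)
      resource(r$id, r$name, r$url, r$version, r$namespace_prefix, r$iri_prefix)
    }),
    schema_version = md$phenopacket_schema_version %||% md$schema_version %||% "2.0"
  )

  p <- phenopacket(
    id = doc$id, subject = subject, phenotypic_features = features,
    diseases = diseases, interpretations = interpretations, meta_data = metadata
  )
  if (length(sink$keys) > 0) attr(p, "unknown_keys") <- sink$keys
  p
}

#' Read a directory of phenopacket JSON files
#'
#' Loads every `*.json` file under `dir` (recursively), in stable path order.
#' Files that fail to parse or validate are reported in the `"failures"`
#' attribute (a tibble with `path` and `message`) and summarized in a
#' message; they are not fatal unless no file loads at all.
#'
#' @param dir Corpus directory.
#' @return A list of [phenopacket()] objects with attribute `failures`.
#' @export
read_corpus <- function(dir) {
  if (!dir.exists(dir)) {
    abort(paste0("corpus directory does not exist: ", dir),
          class = "phenocurator_io_error")
  }
  paths <- list.files(dir, pattern = "\\.json$", recursive = TRUE, full.names = TRUE)
  paths <- paths[order(paths, method = "radix")]
  packets <- list()
  failures <- tibble(path = character(), message = character())
  for (pth in paths) {
    res <- tryCatch(read_phenopacket(pth), error = function(e) e)
    if (inherits(res, "error")) {
      failures <- bind_rows(failures, tibble(path = pth,
                                             message = conditionMessage(res)))
    } else {
      packets <- c(packets, list(res))
    }
  }
  if (length(packets) == 0) {
    abort(paste0("no readable phenopackets in ", dir),
          class = "phenocurator_empty_corpus_error")
  }
  if (nrow(failures) > 0) {
    inform(paste0("read_corpus: ", length(packets), " phenopacket(s) loaded, ",
                  nrow(failures), " file(s) failed"))
  }
  attr(packets, "failures") <- failures
  packets
}

#' Write a list of phenopackets to a corpus directory
#'
#' One JSON file per phenopacket, named `<id>.json`.
#'
#' @param ps List of [phenopacket()] objects.
#' @param dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
write_corpus <- function(ps, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- map_chr(ps, function(p) {
    path <- file.path(dir, paste0(p$id, ".json"))
    write_phenopacket(p, path)
    path
  })
  invisible(paths)
}
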