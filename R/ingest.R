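#' Curation template dialect
#'
#' The curation template is a spreadsheet with individuals in rows and one
#' column per data item. It has two header rows: row 1 carries column
#' labels; row 2 carries a type marker (`str`, `age` or `optional`) for the
#' fixed metadata columns and the HPO CURIE for phenotype term columns.
#' Term-column cells hold one of `observed`, `excluded`, `na` (or blank), or
#' an ISO 8601 age meaning "observed with this age of onset". Any other cell
#' text is a cell error — curation safety over convenience.
#'
#' Fixed columns: `PMID`, `title`, `individual_id`, `disease_id`,
#' `disease_label`, `hgnc_id`, `gene_symbol`, `transcript`, `allele_1`,
#' `allele_2`, `age_of_onset`, `age_at_last_encounter`, `deceased`, `sex`.
#'
#' @name curation_template
NULL

FIXED_COLUMNS <- c("PMID", "title", "individual_id", "disease_id",
                   "disease_label", "hgnc_id", "gene_symbol", "transcript",
                   "allele_1", "allele_2", "age_of_onset",
                   "age_at_last_encounter", "deceased", "sex")

#' Read a curation template
#'
#' @param path Path to the template file.
#' @param format `"csv"`, `"tsv"` or `"xlsx"`; inferred from the file
#'   extension when `NULL`.
#' @return A `curation_table`: list with `fixed` (tibble of the fixed
#'   metadata columns, character), `terms` (tibble with `label`, `term_id`),
#'   `cells` (character matrix, rows x term columns) and `n_rows`.
#' @export
read_template <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("csv", "tsv", "xlsx")) {
      abort(paste0("cannot infer template format from extension: ", path),
            class = "phenocurator_format_error")
    }
  }
  format <- arg_match(format, c("csv", "tsv", "xlsx"))
  raw <- switch(format,
    csv = readr::read_csv(path, col_names = FALSE, col_types = readr::cols(
      .default = readr::col_character()), progress = FALSE),
    tsv = readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(
      .default = readr::col_character()), progress = FALSE),
    xlsx = {
      x <- readxl::read_xlsx(path, col_names = FALSE, col_types = "text",
                             .name_repair = "minimal")
      names(x) <- paste0("X", seq_along(x))
      x
    }
  )
  mat <- as.matrix(raw)
  mat[is.na(mat)] <- ""
  if (nrow(mat) < 2) {
    abort("template must have two header rows", class = "phenocurator_format_error")
  }
  labels <- unname(trimws(mat[1, ]))
  markers <- unname(trimws(mat[2, ]))
  body <- if (nrow(mat) > 2) mat[-(1:2), , drop = FALSE] else
    matrix(character(), nrow = 0, ncol = ncol(mat))

  is_term_col <- is_hpo_id(markers)
  fixed_idx <- which(!is_term_col)
  term_idx <- which(is_term_col)

  missing <- setdiff(FIXED_COLUMNS, labels[fixed_idx])
  if (length(missing) > 0) {
    abort(paste0("template missing required column: ", missing[[1]]),
          class = "phenocurator_format_error")
  }
  bad_marker <- fixed_idx[!markers[fixed_idx] %in% c("str", "age", "optional")]
  if (length(bad_marker) > 0) {
    abort(paste0("column \"", labels[bad_marker[[1]]],
                 "\" has marker \"", markers[bad_marker[[1]]],
                 "\" (expected str/age/optional or an HPO CURIE)"),
          class = "phenocurator_format_error")
  }
  dup <- markers[term_idx][duplicated(markers[term_idx])]
  if (length(dup) > 0) {
    abort(paste0("duplicate HPO term column: ", dup[[1]]),
          class = "phenocurator_format_error")
  }

  fixed <- as_tibble(body[, match(FIXED_COLUMNS, labels), drop = FALSE],
                     .name_repair = "minimal")
  names(fixed) <- FIXED_COLUMNS
  cells <- body[, term_idx, drop = FALSE]
  colnames(cells) <- markers[term_idx]
  structure(
    list(fixed = fixed,
         terms = tibble(label = labels[term_idx], term_id = markers[term_idx]),
         cells = cells,
         n_rows = nrow(body)),
    class = "curation_table"
  )
}

#' @export
print.curation_table <- function(x, ...) {
  cat("<curation_table> ", x$n_rows, " individuals, ", nrow(x$terms),
      " HPO term columns\n", sep = "")
  invisible(x)
}

cell_error <- function(row, column, msg) {
  abort(paste0("row ", row, ", column \"", column, "\": ", msg),
        class = "phenocurator_cell_error", row = row, column = column)
}

parse_sex_cell <- function(x, row) {
  key <- tolower(trimws(x))
  if (key %in% c("", "na")) return("UNKNOWN_SEX")
  switch(key,
    m = , male = "MALE",
    f = , female = "FEMALE",
    o = , other = "OTHER_SEX",
    u = , unknown = "UNKNOWN_SEX",
    cell_error(row, "sex", paste0("unrecognized sex value \"", x, "\""))
  )
}

parse_deceased_cell <- function(x, row) {
  key <- tolower(trimws(x))
  if (key %in% c("", "na")) return(NULL)
  if (key %in% c("yes", "true")) return(TRUE)
  if (key %in% c("no", "false")) return(NULL)  # alive: protobuf default, omitted
  cell_error(row, "deceased", paste0("unrecognized deceased value \"", x, "\""))
}

parse_age_cell <- function(x, row, column) {
  x <- trimws(x)
  if (x %in% c("", "na")) return(NULL)
  tryCatch(parse_age(x), error = function(e) cell_error(row, column, conditionMessage(e)))
}

looks_hgvs <- function(x) grepl(":(c|g|p)\\.", x)

hgvs_syntax_of <- function(x) {
  m <- regmatches(x, regexpr(":(c|g|p)\\.", x))
  paste0("hgvs.", substr(sub("^:", "", m), 1, 1))
}

# One allele cell -> HGVS expression or qualitative SV label
interpret_allele <- function(value, transcript) {
  value <- trimws(value)
  if (looks_hgvs(value)) {
    return(list(kind = "hgvs", value = value, syntax = hgvs_syntax_of(value)))
  }
  if (grepl("^[cgp]\\.", value) && nzchar(trimws(transcript))) {
    full <- paste0(trimws(transcript), ":", value)
    return(list(kind = "hgvs", value = full, syntax = hgvs_syntax_of(full)))
  }
  list(kind = "sv", value = value)
}

make_descriptor <- function(allele, gene, state, id) {
  if (allele$kind == "hgvs") {
    variation_descriptor(id = id, gene = gene,
                         expressions = list(hgvs_expression(allele$syntax, allele$value)),
                         allelic_state = state)
  } else {
    build_sv_descriptor(gene = gene, label = allele$value,
                        allelic_state = state, id = id)
  }
}

#' Convert one template row to a phenopacket
#'
#' Applies the template dialect: term cells `observed`/`excluded` become
#' present/excluded phenotypic features, `na` (or blank) emits nothing, and
#' an ISO 8601 age becomes a present feature with that onset. The allele
#' pair builds one interpretation: identical alleles give a single
#' homozygous descriptor, distinct alleles two heterozygous descriptors, and
#' a single allele one heterozygous descriptor (hemizygous when
#' `options$hemizygous` is set). Allele text without an HGVS-style
#' `:c.`/`:g.`/`:p.` pattern becomes a qualitative structural-variant label.
#'
#' @param table A `curation_table` from [read_template()].
#' @param row_index Row number (1-based, counted below the header rows).
#' @param options List: `hemizygous` (logical), `created`, `created_by`
#'   (metadata strings).
#' @return A [phenopacket()].
#' @export
row_to_phenopacket <- function(table, row_index, options = list()) {
  stopifnot(inherits(table, "curation_table"))
  if (row_index < 1 || row_index > table$n_rows) {
    abort(paste0("row ", row_index, " does not exist"),
          class = "phenocurator_argument_error")
  }
  fx <- lapply(table$fixed, function(col) col[[row_index]])
  if (!grepl("^[0-9]+$", trimws(fx$PMID))) {
    cell_error(row_index, "PMID", paste0("not a digit string: \"", fx$PMID, "\""))
  }
  pid <- make_phenopacket_id(trimws(fx$PMID), fx$individual_id)

  subject <- individual(
    id = if (nzchar(trimws(fx$individual_id))) fx$individual_id else "individual",
    sex = parse_sex_cell(fx$sex, row_index),
    time_at_last_encounter = parse_age_cell(fx$age_at_last_encounter, row_index,
                                            "age_at_last_encounter"),
    deceased = parse_deceased_cell(fx$deceased, row_index)
  )

  features <- list()
  for (k in seq_len(nrow(table$terms))) {
    raw <- trimws(table$cells[row_index, k])
    term <- ontology_class(table$terms$term_id[[k]], table$terms$label[[k]])
    column <- table$terms$term_id[[k]]
    if (raw %in% c("", "na")) next
    if (raw == "observed") {
      features <- c(features, list(phenotypic_feature(term, excluded = FALSE)))
    } else if (raw == "excluded") {
      features <- c(features, list(phenotypic_feature(term, excluded = TRUE)))
    } else if (grepl("^P", raw)) {
      onset <- parse_age_cell(raw, row_index, column)
      features <- c(features, list(phenotypic_feature(term, excluded = FALSE,
                                                      onset = onset)))
    } else {
      cell_error(row_index, column,
                 paste0("unrecognized cell value \"", raw,
                        "\" (expected observed/excluded/na or an ISO 8601 age)"))
    }
  }

  diseases <- list()
  interpretations <- list()
  prefixes <- c("HP")
  if (nzchar(trimws(fx$disease_id))) {
    term <- tryCatch(
      disease_dx(ontology_class(trimws(fx$disease_id), fx$disease_label),
                 onset = parse_age_cell(fx$age_of_onset, row_index, "age_of_onset")),
      phenocurator_validation_error = function(e)
        cell_error(row_index, "disease_id", conditionMessage(e))
    )
    diseases <- list(term)
    prefixes <- c(prefixes, curie_prefix(trimws(fx$disease_id)))
  }

  a1 <- trimws(fx$allele_1)
  a2 <- trimws(fx$allele_2)
  if (nzchar(a1) || nzchar(a2)) {
    if (!nzchar(a1)) { a1 <- a2; a2 <- "" }
    gene <- tryCatch(gene_context(trimws(fx$hgnc_id), trimws(fx$gene_symbol)),
                     phenocurator_validation_error = function(e)
                       cell_error(row_index, "hgnc_id", conditionMessage(e)))
    al1 <- interpret_allele(a1, fx$transcript)
    gis <- if (nzchar(a2)) {
      if (identical(a1, a2)) {
        list(genomic_interpretation(make_descriptor(
          al1, gene, geno_allelic_state("homozygous"), paste0(pid, "-var-1"))))
      } else {
        al2 <- interpret_allele(a2, fx$transcript)
        list(
          genomic_interpretation(make_descriptor(
            al1, gene, geno_allelic_state("heterozygous"), paste0(pid, "-var-1"))),
          genomic_interpretation(make_descriptor(
            al2, gene, geno_allelic_state("heterozygous"), paste0(pid, "-var-2")))
        )
      }
    } else {
      state <- if (isTRUE(options$hemizygous)) "hemizygous" else "heterozygous"
      list(genomic_interpretation(make_descriptor(
        al1, gene, geno_allelic_state(state), paste0(pid, "-var-1"))))
    }
    if (length(diseases) == 0) {
      cell_error(row_index, "disease_id", "alleles given but no disease diagnosis")
    }
    interpretations <- list(interpretation(
      id = paste0(pid, "-interpretation"),
      diagnosis_disease = diseases[[1]]$term,
      genomic_interpretations = gis
    ))
    prefixes <- c(prefixes, "GENO", "HGNC")
  }

  phenopacket(
    id = pid, subject = subject, phenotypic_features = features,
    diseases = diseases, interpretations = interpretations,
    meta_data = meta_data(
      created = options$created %||% "2024-01-01T00:00:00Z",
      created_by = options$created_by %||% "phenocurator",
      resources = default_resources(unique(prefixes))
    )
  )
}

#' Ingest a curation template into a phenopacket corpus
#'
#' Converts every row with [row_to_phenopacket()], validates the batch with
#' [validate_corpus()], and writes only phenopackets with zero ERROR-level
#' findings as JSON files under `out_dir`. Row-conversion failures (bad
#' cells) become ERROR issues with rule id `"CELL"` rather than stopping the
#' run.
#'
#' @param table A `curation_table`.
#' @param ontology An [ontology_graph()].
#' @param out_dir Output corpus directory.
#' @param cfg A [rule_config()].
#' @param options Passed to [row_to_phenopacket()].
#' @return A list with `written` (count) and `issues` (tibble).
#' @export
ingest_template <- function(table, ontology, out_dir, cfg = rule_config(),
                            options = list()) {
  stopifnot(inherits(table, "curation_table"))
  packets <- list()
  issues <- issue_tibble()
  for (i in seq_len(table$n_rows)) {
    res <- tryCatch(row_to_phenopacket(table, i, options), error = function(e) e)
    if (inherits(res, "error")) {
      issues <- bind_rows(issues, issue_tibble(
        "ERROR", "CELL", paste0("row_", i), conditionMessage(res)))
    } else {
      packets <- c(packets, list(res))
    }
  }
  if (length(packets) > 0) {
    issues <- bind_rows(issues, validate_corpus(packets, ontology, cfg))
  }
  bad_ids <- unique(issues$phenopacket_id[issues$level == "ERROR"])
  keep <- keep(packets, function(p) !p$id %in% bad_ids)
  write_corpus(keep, out_dir)
  list(written = length(keep), issues = issues)
}
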