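#' Round half away from zero
#'
#' Summary tables print one decimal with conventional half-up rounding
#' (so 15.75 prints as 15.8), unlike R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Partition a corpus into gene cohorts
#'
#' Individuals are grouped by the gene harboring the disease-causing
#' mutation: the gene symbol of the first genomic interpretation.
#' Phenopackets with no interpretation are collected under `"_NO_GENE_"`;
#' cohort aggregates exclude that bucket and its size is reported in a
#' message.
#'
#' @param ps A list of [phenopacket()] objects.
#' @return A named list of phenopacket lists, one entry per gene symbol.
#' @export
partition_by_gene <- function(ps) {
  genes <- map_chr(ps, first_gene_symbol)
  genes[is.na(genes)] <- "_NO_GENE_"
  out <- split(ps, factor(genes, levels = unique(genes)))
  if ("_NO_GENE_" %in% names(out)) {
    inform(paste0("partition_by_gene: ", length(out[["_NO_GENE_"]]),
                  " phenopacket(s) without a genomic interpretation"))
  }
  out
}

#' Summarize one gene cohort
#'
#' Tallies for a cohort: phenopacket count, distinct diseases, unique
#' alleles, distinct publications, and present/excluded annotation counts.
#' The allele key is the literal pair (gene symbol, first HGVS expression
#' value or qualitative SV label), case-sensitive, with no normalization.
#' Publications are identified by the PMID prefix of the phenopacket id.
#'
#' @param cohort A nonempty list of [phenopacket()] objects.
#' @param gene_symbol Cohort gene symbol (defaults to the first
#'   interpretation's gene).
#' @return A one-row tibble (a cohort summary).
#' @export
summarize_cohort <- function(cohort, gene_symbol = NULL) {
  stopifnot(length(cohort) > 0)
  if (is.null(gene_symbol)) {
    gene_symbol <- first_gene_symbol(cohort[[1]])
    if (is.na(gene_symbol)) gene_symbol <- "_NO_GENE_"
  }
  feats <- map(cohort, "phenotypic_features")
  excl <- map(feats, function(fs) map_lgl(fs, "excluded"))
  terms <- unlist(map(feats, function(fs) map_chr(fs, function(f) f$type$id)),
                  use.names = FALSE)
  tibble(
    gene_symbol = gene_symbol,
    n_phenopackets = length(cohort),
    n_diseases = length(unique(unlist(map(cohort, function(p)
      map_chr(p$diseases, function(d) d$term$id)), use.names = FALSE))),
    n_unique_alleles = length(unique(unlist(map(cohort, allele_keys),
                                            use.names = FALSE))),
    n_publications = length(unique(stats::na.omit(pmid_of(map_chr(cohort, "id"))))),
    n_present_annotations = sum(!unlist(excl, use.names = FALSE)),
    n_excluded_annotations = sum(unlist(excl, use.names = FALSE)),
    n_distinct_terms = length(unique(terms))
  )
}

#' Summarize every gene cohort in a corpus
#'
#' @param ps A list of [phenopacket()] objects.
#' @return A tibble with one row per gene cohort (the `"_NO_GENE_"` bucket,
#'   if any, is dropped; its size is in the `n_no_gene` attribute).
#' @export
cohort_summaries <- function(ps) {
  parts <- partition_by_gene(ps)
  n_no_gene <- length(parts[["_NO_GENE_"]] %||% list())
  parts <- parts[setdiff(names(parts), "_NO_GENE_")]
  out <- map_dfr(names(parts), function(gene) summarize_cohort(parts[[gene]], gene))
  attr(out, "n_no_gene") <- n_no_gene
  out
}

#' Aggregate cohort summaries into a corpus table
#'
#' Produces the per-cohort rows plus aggregate rows (mean, median, minimum,
#' maximum, total) per column, and the per-disease phenopacket mean (total
#' phenopackets / total distinct diseases). Means are rounded half-up to one
#' decimal; the median of an even number of cohorts is the mean of the two
#' middle values.
#'
#' @param summaries A tibble of cohort summaries ([cohort_summaries()]).
#' @return An object of class `corpus_table` with elements `cohorts`
#'   (tibble) and `aggregates` (tibble with a `statistic` column).
#' @export
corpus_table <- function(summaries) {
  stopifnot(nrow(summaries) >= 1)
  cohorts <- mutate(as_tibble(summaries),
                    n_total_annotations = .data$n_present_annotations +
                      .data$n_excluded_annotations)
  num_cols <- c("n_phenopackets", "n_diseases", "n_unique_alleles",
                "n_publications", "n_present_annotations",
                "n_excluded_annotations", "n_total_annotations")
  agg_row <- function(stat, f) {
    vals <- map_dbl(num_cols, function(col) f(cohorts[[col]]))
    as_tibble(c(list(statistic = stat), setNames(as.list(vals), num_cols)))
  }
  aggregates <- bind_rows(
    agg_row("mean", function(v) round_half_up(mean(v), 1)),
    agg_row("median", median),
    agg_row("minimum", min),
    agg_row("maximum", max),
    agg_row("total", sum)
  )
  total_pk <- sum(cohorts$n_phenopackets)
  total_ds <- sum(cohorts$n_diseases)
  aggregates$phenopackets_per_disease <- c(
    round_half_up(total_pk / total_ds, 1), NA, NA, NA, NA)
  structure(list(cohorts = select(cohorts, -"n_total_annotations"),
                 aggregates = aggregates),
            class = "corpus_table")
}

#' @export
print.corpus_table <- function(x, ...) {
  cat("<corpus_table> ", nrow(x$cohorts), " gene cohorts\n", sep = "")
  print(x$aggregates)
  invisible(x)
}

#' @rdname corpus_table
#' @param x A `corpus_table`.
#' @param ... Unused.
#' @export
tidy.corpus_table <- function(x, ...) x$cohorts

#' @rdname corpus_table
#' @export
glance.corpus_table <- function(x, ...) {
  tot <- x$aggregates[x$aggregates$statistic == "total", ]
  mn <- x$aggregates[x$aggregates$statistic == "mean", ]
  tibble(
    n_cohorts = nrow(x$cohorts),
    n_phenopackets = tot$n_phenopackets,
    n_diseases = tot$n_diseases,
    n_unique_alleles = tot$n_unique_alleles,
    n_publications = tot$n_publications,
    n_annotations = tot$n_total_annotations,
    mean_phenopackets_per_cohort = mn$n_phenopackets,
    phenopackets_per_disease = mn$phenopackets_per_disease
  )
}

#' Per-individual summaries and corpus-level rates
#'
#' One row per phenopacket (present/excluded term counts, sex, age at last
#' encounter in years) plus aggregate rates: mean present and excluded
#' counts (rounded half-up to one decimal), sex counts, the percentage of
#' phenopackets with sex specified, the male/female split among those, and
#' the fraction of feature annotations carrying an onset (as a percentage,
#' one decimal). Percentages among specified sexes are `NA` when no
#' phenopacket specifies sex.
#'
#' @param ps A list of [phenopacket()] objects.
#' @return An object of class `individual_summary` with elements
#'   `individuals` (tibble) and `aggregate` (named list).
#' @export
individual_summaries <- function(ps) {
  individuals <- map_dfr(ps, function(p) {
    excl <- map_lgl(p$phenotypic_features, "excluded")
    tibble(
      phenopacket_id = p$id,
      n_present = sum(!excl),
      n_excluded = sum(excl),
      sex = p$subject$sex,
      age_last_encounter_years = age_in_years(p$subject$time_at_last_encounter)
    )
  })
  n_feats <- map_int(ps, function(p) length(p$phenotypic_features))
  n_onset <- map_int(ps, function(p)
    sum(map_lgl(p$phenotypic_features, function(f) !is.null(f$onset))))
  n <- length(ps)
  specified <- individuals$sex %in% c("MALE", "FEMALE", "OTHER_SEX")
  n_spec <- sum(specified)
  aggregate <- list(
    n_phenopackets = n,
    mean_present = round_half_up(mean(individuals$n_present), 1),
    mean_excluded = round_half_up(mean(individuals$n_excluded), 1),
    sex_counts = table(factor(individuals$sex, levels = SEX_VALUES)),
    pct_sex_specified = round_half_up(100 * n_spec / n, 1),
    pct_male_of_specified = if (n_spec > 0)
      round_half_up(100 * sum(individuals$sex == "MALE") / n_spec, 1) else NA_real_,
    pct_female_of_specified = if (n_spec > 0)
      round_half_up(100 * sum(individuals$sex == "FEMALE") / n_spec, 1) else NA_real_,
    n_features = sum(n_feats),
    n_features_with_onset = sum(n_onset),
    onset_fraction_pct = if (sum(n_feats) > 0)
      round_half_up(100 * sum(n_onset) / sum(n_feats), 1) else NA_real_
  )
  structure(list(individuals = individuals, aggregate = aggregate),
            class = "individual_summary")
}

#' @export
print.individual_summary <- function(x, ...) {
  a <- x$aggregate
  cat("<individual_summary> ", a$n_phenopackets, " phenopackets\n",
      "  mean terms per individual: ", a$mean_present, " present, ",
      a$mean_excluded, " excluded\n",
      "  sex specified: ", a$pct_sex_specified, "%",
      if (!is.na(a$pct_male_of_specified))
        paste0(" (", a$pct_male_of_specified, "% male of specified)"),
      "\n  annotations with onset: ", a$onset_fraction_pct, "% of ",
      a$n_features, "\n", sep = "")
  invisible(x)
}

#' @rdname individual_summaries
#' @param x An `individual_summary`.
#' @param ... Unused.
#' @export
tidy.individual_summary <- function(x, ...) x$individuals

#' @rdname individual_summaries
#' @export
glance.individual_summary <- function(x, ...) {
  a <- x$aggregate
  tibble(
    n_phenopackets = a$n_phenopackets,
    mean_present = a$mean_present,
    mean_excluded = a$mean_excluded,
    pct_sex_specified = a$pct_sex_specified,
    pct_male_of_specified = a$pct_male_of_specified,
    pct_female_of_specified = a$pct_female_of_specified,
    n_features = a$n_features,
    n_features_with_onset = a$n_features_with_onset,
    onset_fraction_pct = a$onset_fraction_pct
  )
}

#' Histogram of ages at last examination
#'
#' Bins ages of last encounter into half-open intervals
#' `[k*w, (k+1)*w)`, overall and by sex. Individuals without a recorded age
#' are excluded; their count is reported.
#'
#' @param ps A list of [phenopacket()] objects.
#' @param bin_width_years Bin width in years (> 0).
#' @return An object of class `age_histogram` with elements `overall`
#'   (tibble: `bin_start`, `bin_end`, `n`), `by_sex` (same plus `sex`) and
#'   `n_missing`.
#' @export
age_histogram <- function(ps, bin_width_years = 10) {
  stopifnot(bin_width_years > 0)
  ages <- map_dbl(ps, function(p) age_in_years(p$subject$time_at_last_encounter))
  sexes <- map_chr(ps, function(p) p$subject$sex)
  keep <- !is.na(ages)
  df <- tibble(age = ages[keep], sex = sexes[keep]) %>%
    mutate(bin = floor(.data$age / bin_width_years))
  bin_counts <- function(d) {
    d %>% group_by(.data$bin) %>% summarise(n = n(), .groups = "drop") %>%
      mutate(bin_start = .data$bin * bin_width_years,
             bin_end = (.data$bin + 1) * bin_width_years) %>%
      select("bin_start", "bin_end", "n") %>% arrange(.data$bin_start)
  }
  overall <- bin_counts(df)
  by_sex <- df %>% group_by(.data$sex, .data$bin) %>%
    summarise(n = n(), .groups = "drop") %>%
    mutate(bin_start = .data$bin * bin_width_years,
           bin_end = (.data$bin + 1) * bin_width_years) %>%
    select("sex", "bin_start", "bin_end", "n") %>%
    arrange(.data$sex, .data$bin_start)
  structure(list(overall = overall, by_sex = by_sex,
                 n_missing = sum(!keep), bin_width = bin_width_years),
            class = "age_histogram")
}

#' @export
print.age_histogram <- function(x, ...) {
  cat("<age_histogram> bin width ", x$bin_width, " y, ",
      sum(x$overall$n), " individuals binned, ", x$n_missing,
      " without age\n", sep = "")
  print(x$overall)
  invisible(x)
}

#' @rdname age_histogram
#' @param object An `age_histogram`.
#' @param by_sex Facet bars by sex?
#' @param ... Unused.
#' @export
autoplot.age_histogram <- function(object, by_sex = FALSE, ...) {
  df <- if (by_sex) object$by_sex else object$overall
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_start + object$bin_width / 2,
                                        y = .data$n)) +
    ggplot2::geom_col(width = object$bin_width * 0.92) +
    ggplot2::labs(x = "Age at last examination (years)", y = "Individuals")
  if (by_sex) p <- p + ggplot2::facet_wrap(~sex)
  p
}

#' @rdname individual_summaries
#' @param object An `individual_summary`.
#' @export
autoplot.individual_summary <- function(object, ...) {
  df <- object$individuals %>%
    mutate(total = .data$n_present + .data$n_excluded) %>%
    select(present = "n_present", excluded = "n_excluded", total = "total") %>%
    tidyr::pivot_longer(dplyr::everything(), names_to = "kind", values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$kind, y = .data$count)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "HPO terms per phenopacket")
}

#' Headline corpus ratios from a totals record
#'
#' Recomputes the corpus-level arithmetic summaries from a record of corpus
#' totals: mean phenopackets per gene cohort, mean phenopackets per disease,
#' and the percentage of feature annotations with an age of onset — each with
#' the package's half-up rounding to one decimal.
#'
#' @param totals A list or one-row data frame with `n_phenopackets`,
#'   `n_cohorts`, `n_diseases`, `n_features`, `n_features_with_onset`.
#' @return A one-row tibble.
#' @export
corpus_overview <- function(totals) {
  totals <- as.list(totals)
  need <- c("n_phenopackets", "n_cohorts", "n_diseases", "n_features",
            "n_features_with_onset")
  missing <- setdiff(need, names(totals))
  if (length(missing) > 0) {
    abort(paste0("totals record missing field: ", missing[[1]]),
          class = "phenocurator_argument_error")
  }
  tibble(
    phenopackets_per_cohort_mean =
      round_half_up(totals$n_phenopackets / totals$n_cohorts, 1),
    phenopackets_per_disease_mean =
      round_half_up(totals$n_phenopackets / totals$n_diseases, 1),
    onset_fraction_pct =
      round_half_up(100 * totals$n_features_with_onset / totals$n_features, 1),
    n_features = totals$n_features
  )
}

#' Corpus table as a flat tibble (cohort rows plus aggregate rows)
#'
#' Layout used by the TSV export: cohort rows first, then the aggregate
#' rows, with the aggregate name in the `gene_symbol` column.
#'
#' @param ct A `corpus_table`.
#' @return A tibble.
#' @export
corpus_table_tsv <- function(ct) {
  stopifnot(inherits(ct, "corpus_table"))
  cohorts <- mutate(ct$cohorts,
                    n_total_annotations = .data$n_present_annotations +
                      .data$n_excluded_annotations,
                    phenopackets_per_disease = NA_real_)
  agg <- ct$aggregates %>% rename(gene_symbol = "statistic") %>%
    mutate(n_distinct_terms = NA_real_)
  bind_rows(cohorts, agg)
}
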