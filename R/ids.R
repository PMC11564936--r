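#' Sanitize an individual identifier
#'
#' Phenopackets are stored one JSON file per individual, so identifiers must
#' be filesystem- and URL-safe. Every character outside `[A-Za-z0-9_.-]` is
#' replaced by `_`, runs of `_` are collapsed, and leading/trailing `_` are
#' stripped. The operation is idempotent. An identifier that sanitizes to the
#' empty string becomes `"individual"`.
#'
#' @param raw A character vector of raw identifiers.
#' @return A character vector of sanitized identifiers.
#' @examples
#' sanitize_id("patient 4 (II:2)")  # "patient_4_II_2"
#' @export
sanitize_id <- function(raw) {
  x <- gsub("[^A-Za-z0-9_.-]", "_", as.character(raw))
  x <- gsub("_+", "_", x)
  x <- gsub("^_|_$", "", x)
  x[x == "" | is.na(x)] <- "individual"
  x
}

#' Construct a phenopacket identifier
#'
#' Phenopacket identifiers prepend the PubMed ID of the source publication to
#' the individual identifier used in that publication:
#' `PMID_<pmid>_<individual>`. An empty or missing individual identifier
#' becomes the word `"individual"`.
#'
#' @param pmid PubMed ID as a digit string (no `PMID:` prefix).
#' @param individual_id Identifier of the individual within the publication;
#'   sanitized with [sanitize_id()].
#' @return A single string matching `^PMID_[0-9]+_[A-Za-z0-9_.-]+$`.
#' @examples
#' make_phenopacket_id("24126608", "BAB3022")  # "PMID_24126608_BAB3022"
#' @export
make_phenopacket_id <- function(pmid, individual_id = "") {
  pmid <- as.character(pmid)
  if (length(pmid) != 1 || is.na(pmid) || !grepl("^[0-9]+$", pmid)) {
    abort("pmid must be a nonempty digit string",
          class = "phenocurator_argument_error")
  }
  if (length(individual_id) != 1 || is.na(individual_id)) individual_id <- ""
  paste0("PMID_", pmid, "_", sanitize_id(individual_id))
}

is_phenopacket_id <- function(x) {
  grepl("^PMID_[0-9]+_[A-Za-z0-9_.-]+$", x)
}

pmid_of <- function(id) {
  out <- rep(NA_character_, length(id))
  ok <- is_phenopacket_id(id)
  out[ok] <- sub("^PMID_([0-9]+)_.*$", "\\1", id[ok])
  out
}
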