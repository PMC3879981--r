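# Taxonomy and annotation tables (header-bearing TSV).

TEMP_CLASSES <- c("mesophile", "thermophile", "hyperthermophile",
                  "psychrophile", "unknown")

#' Read a taxonomy table
#'
#' Header-bearing TSV mapping each genome to its classification.  Required
#' columns: `genome_id`, `domain`, `phylum`, `class_name`, `genus`,
#' `temp_class`; `temp_class` must come from the closed vocabulary
#' mesophile / thermophile / hyperthermophile / psychrophile / unknown.
#'
#' @param path Path to a TSV file.
#' @return A tibble, one row per genome.
#' @export
read_taxonomy <- function(path) {
  tx <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  need <- c("genome_id", "domain", "phylum", "class_name", "genus", "temp_class")
  miss <- setdiff(need, names(tx))
  if (length(miss) > 0) {
    abort(paste0("taxonomy table missing column(s): ", paste(miss, collapse = ", ")))
  }
  dup <- tx$genome_id[duplicated(tx$genome_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicated genome_id in taxonomy: ", paste(unique(dup), collapse = ", ")))
  }
  bad <- setdiff(unique(tx$temp_class), TEMP_CLASSES)
  if (length(bad) > 0) {
    abort(paste0("temp_class value(s) outside vocabulary: ", paste(bad, collapse = ", ")))
  }
  as_tibble(tx[need])
}

#' Write a taxonomy table
#' @param taxonomy Taxonomy tibble (see [read_taxonomy()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  readr::write_tsv(taxonomy, path, progress = FALSE)
  invisible(path)
}

#' Read a functional-annotation table
#'
#' Header-bearing TSV with at least `protein_id` and `cog_category`; optional
#' `go_term` and `evidence` columns (used for the GO fallback of
#' [assign_function()]).
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_annotations <- function(path) {
  an <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  need <- c("protein_id", "cog_category")
  miss <- setdiff(need, names(an))
  if (length(miss) > 0) {
    abort(paste0("annotation table missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"go_term" %in% names(an)) an$go_term <- NA_character_
  if (!"evidence" %in% names(an)) an$evidence <- NA_character_
  as_tibble(an)
}

#' @rdname read_annotations
#' @param annotations Annotation tibble.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_tsv(annotations, path, progress = FALSE)
  invisible(path)
}
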