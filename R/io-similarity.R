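# Reading/writing BLAST-style tabular similarity hits.

#' Read an all-vs-all protein similarity table
#'
#' Reads BLAST tabular output (`-outfmt 6`, no header).  Twelve-column files
#' use columns 1, 2, 11, 12 (query, subject, e-value, bit score); extra
#' columns are ignored.  Four-column files are taken as
#' `query, subject, evalue, bitscore` directly.  Hits above `max_evalue` are
#' dropped and duplicated ordered `(query, subject)` pairs are collapsed,
#' keeping the smallest e-value (ties: larger bit score, then first
#' occurrence).  Row order is the input order of first occurrence.
#'
#' @param path Path to a tab-separated hit table (plain or gzip).
#' @param max_evalue Keep only hits with `evalue <= max_evalue`.
#' @return A tibble with columns `query_id`, `subject_id`, `evalue`,
#'   `bitscore`.
#' @export
read_similarity_table <- function(path, max_evalue = Inf) {
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    return(tibble(query_id = character(), subject_id = character(),
                  evalue = double(), bitscore = double()))
  }
  nc <- ncol(raw)
  idx <- if (nc >= 12) c(1L, 2L, 11L, 12L) else if (nc >= 4) 1:4 else
    abort(paste0("similarity table must have >= 4 columns, found ", nc))
  hits <- tibble(
    query_id = raw[[idx[1]]], subject_id = raw[[idx[2]]],
    evalue = suppressWarnings(as.numeric(raw[[idx[3]]])),
    bitscore = suppressWarnings(as.numeric(raw[[idx[4]]]))
  )
  bad <- which(is.na(hits$evalue) | is.na(hits$bitscore) |
                 is.na(hits$query_id) | is.na(hits$subject_id) |
                 hits$query_id == "" | hits$subject_id == "")
  if (length(bad) > 0) {
    abort(paste0("malformed similarity row(s) at line ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  neg <- which(hits$evalue < 0)
  if (length(neg) > 0) {
    abort(paste0("negative e-value at line ", paste(head(neg, 5), collapse = ", ")))
  }
  hits <- dedup_hits(hits)
  hits[hits$evalue <= max_evalue, , drop = FALSE]
}

#' Collapse duplicated ordered (query, subject) hit records
#'
#' Keeps, per ordered pair, the record with the smallest e-value; ties are
#' broken by larger bit score, then first occurrence.  Output preserves the
#' input order of first occurrence.
#'
#' @param hits A hit tibble (`query_id`, `subject_id`, `evalue`, `bitscore`).
#' @return The deduplicated tibble.
#' @export
dedup_hits <- function(hits) {
  hits <- as_tibble(hits)
  first_seen <- match(paste(hits$query_id, hits$subject_id, sep = "\r"),
                      paste(hits$query_id, hits$subject_id, sep = "\r"))
  ord <- order(first_seen, hits$evalue, -hits$bitscore, seq_len(nrow(hits)))
  h <- hits[ord, , drop = FALSE]
  h <- h[!duplicated(first_seen[ord]), , drop = FALSE]
  h[order(first_seen[ord][!duplicated(first_seen[ord])]), , drop = FALSE]
}

#' Write a similarity table in 12-column BLAST tabular layout
#'
#' Unrecorded columns (identity, alignment length, ...) are written as 0 so
#' the file round-trips through [read_similarity_table()].
#'
#' @param hits Hit tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity_table <- function(hits, path) {
  z <- tibble(
    q = hits$query_id, s = hits$subject_id,
    pid = 0, len = 0, mm = 0, go = 0, qs = 0, qe = 0, ss = 0, se = 0,
    evalue = format(hits$evalue, scientific = TRUE, digits = 8),
    bitscore = hits$bitscore
  )
  readr::write_tsv(z, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
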