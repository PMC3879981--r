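# Confidence-annotated alignments and column trimming.
#
# An alignment travels as FASTA plus a sidecar ".conf" text file holding one
# comma-separated real in [0,1] per column (the consensus posterior
# probability of that column).  The sidecar is a bespoke but documented
# format: upstream aligners disagree on how to report per-column confidence,
# so the pipeline takes it as a single externally computed track.

#' Construct a confidence-annotated alignment
#'
#' @param sequences Named character vector of aligned residue strings (equal
#'   lengths; `-` and `.` are gap characters).
#' @param column_confidence Numeric vector in `[0, 1]`, one per column.
#' @return An object of class `conf_alignment`.
#' @export
conf_alignment <- function(sequences, column_confidence) {
  if (is.null(names(sequences)) || any(names(sequences) == "")) {
    abort("alignment sequences must be named")
  }
  w <- unique(nchar(sequences))
  if (length(w) > 1) {
    abort(paste0("ragged alignment: row widths ", paste(w, collapse = ", ")))
  }
  w <- if (length(w) == 0) 0L else w
  if (length(column_confidence) != w) {
    abort(paste0("column_confidence has length ", length(column_confidence),
                 " but alignment has ", w, " columns"))
  }
  if (w > 0 && any(column_confidence < 0 | column_confidence > 1)) {
    abort("column confidences must lie in [0, 1]")
  }
  structure(list(sequences = sequences,
                 column_confidence = as.numeric(column_confidence)),
            class = "conf_alignment")
}

#' @export
print.conf_alignment <- function(x, ...) {
  cat("<conf_alignment> ", length(x$sequences), " sequences x ",
      length(x$column_confidence), " columns\n", sep = "")
  invisible(x)
}

#' Read a confidence-annotated alignment
#'
#' @param fasta_path Aligned FASTA file.
#' @param conf_path Sidecar file: one line of comma-separated confidences.
#'   Defaults to `fasta_path` with a `.conf` extension appended.
#' @return A [conf_alignment()].
#' @export
read_conf_alignment <- function(fasta_path, conf_path = paste0(fasta_path, ".conf")) {
  aa <- Biostrings::readAAStringSet(fasta_path)
  seqs <- setNames(as.character(aa), names(aa))
  ln <- readLines(conf_path, warn = FALSE)
  ln <- ln[nzchar(trimws(ln))]
  if (length(ln) == 0) abort(paste0("empty confidence track: ", conf_path))
  conf <- as.numeric(strsplit(trimws(ln[1]), ",")[[1]])
  if (anyNA(conf)) abort(paste0("non-numeric confidence value in ", conf_path))
  conf_alignment(seqs, conf)
}

#' Write a confidence-annotated alignment
#'
#' @param aln A `conf_alignment`.
#' @param fasta_path,conf_path Output paths.
#' @return `fasta_path`, invisibly.
#' @export
write_conf_alignment <- function(aln, fasta_path,
                                 conf_path = paste0(fasta_path, ".conf")) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(aln$sequences), fasta_path)
  writeLines(paste(format(aln$column_confidence, trim = TRUE), collapse = ","),
             conf_path)
  invisible(fasta_path)
}

#' Remove low-confidence alignment columns
#'
#' Deletes exactly the columns whose consensus posterior probability is below
#' `threshold` (strictly less than), mirroring the usual treatment of
#' ambiguously aligned regions before tree inference.
#'
#' @param aln A [conf_alignment()].
#' @param threshold Confidence cutoff in `[0, 1]`; default 0.80.
#' @return A list with elements `alignment` (the trimmed `conf_alignment`),
#'   `removed_residue_count` (non-gap residues deleted) and
#'   `removed_fraction` (deleted non-gap residues over input non-gap
#'   residues; 0 when the input has none).
#' @export
trim_alignment <- function(aln, threshold = 0.80) {
  if (!inherits(aln, "conf_alignment")) {
    aln <- conf_alignment(aln$sequences, aln$column_confidence)
  }
  if (threshold < 0 || threshold > 1) abort("threshold must lie in [0, 1]")
  keep <- aln$column_confidence >= threshold
  mat <- do.call(rbind, strsplit(aln$sequences, "", fixed = TRUE))
  is_res <- !(mat %in% c("-", ".")) # gap characters carry no residues
  dim(is_res) <- dim(mat)
  total_res <- sum(is_res)
  removed <- sum(is_res[, !keep, drop = FALSE])
  kept_mat <- mat[, keep, drop = FALSE]
  seqs <- setNames(apply(kept_mat, 1, paste, collapse = ""), names(aln$sequences))
  if (ncol(kept_mat) == 0) seqs <- setNames(rep("", nrow(mat)), names(aln$sequences))
  list(
    alignment = conf_alignment(seqs, aln$column_confidence[keep]),
    removed_residue_count = removed,
    removed_fraction = if (total_res > 0) removed / total_res else 0
  )
}
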