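# Shared internal helpers: group tables, protein->genome maps, rounding.

#' Define genome groups
#'
#' Builds the group table used throughout the package: which genomes form the
#' focal clade and which form each named partner lineage (e.g. Archaea `R`,
#' Epsilonproteobacteria `E`, Thermotogae `T`).  Genomes absent from every
#' group are treated as "other" in phyletic patterns.
#'
#' For the focal group, a *named* character vector attaches one-letter codes
#' to the genomes (e.g. `c(A = "Aq", H = "Hb", S = "Sh")`); the order of the
#' vector is the seed/query priority order.  Unnamed vectors reuse genome
#' ids as codes.
#'
#' @param ... Named character vectors of genome ids, one per group.  Group
#'   names are short codes such as `"FOCAL"`, `"R"`, `"E"`, `"T"`.
#' @return A tibble with columns `group`, `genome_id`, `code` and `priority`.
#' @examples
#' group_def(FOCAL = c(A = "Aq", H = "Hb", S = "Sh"), E = c("E1", "E2"))
#' @export
group_def <- function(...) {
  gl <- list(...)
  if (is.null(names(gl)) || any(names(gl) == "")) {
    abort("every group passed to group_def() must be named")
  }
  out <- imap(gl, function(members, code) {
    codes <- names(members) %||% as.character(members)
    members <- as.character(members)
    codes[codes == ""] <- members[codes == ""]
    tibble(
      group = code, genome_id = unname(members), code = codes,
      priority = seq_along(members)
    )
  })
  out <- list_rbind(out)
  dup <- out$genome_id[duplicated(out$genome_id)]
  if (length(dup) > 0) {
    abort(paste0("genomes assigned to more than one group: ",
                 paste(unique(dup), collapse = ", ")))
  }
  out
}

# validate a group table and return it
as_group_tbl <- function(groups) {
  if (!is.data.frame(groups) ||
      !all(c("group", "genome_id") %in% names(groups))) {
    abort("`groups` must be a data frame with columns group and genome_id (see group_def())")
  }
  groups <- as_tibble(groups)
  if (!"code" %in% names(groups)) groups$code <- groups$genome_id
  if (!"priority" %in% names(groups)) {
    groups <- groups |> group_by(.data$group) |>
      mutate(priority = row_number()) |> ungroup()
  }
  groups
}

group_members <- function(groups, code) {
  groups$genome_id[groups$group %in% code]
}

# focal genomes in priority order
focal_priority <- function(groups, focal) {
  g <- groups[groups$group == focal, , drop = FALSE]
  if (nrow(g) == 0) abort(paste0("focal group '", focal, "' is empty or absent"))
  g$genome_id[order(g$priority)]
}

# named vector genome_id -> one-letter focal code
focal_codes <- function(groups, focal) {
  g <- groups[groups$group == focal, , drop = FALSE]
  setNames(g$code[order(g$priority)], g$genome_id[order(g$priority)])
}

# partner (named, non-focal) group codes in table order
partner_groups <- function(groups, focal) {
  unique(groups$group[groups$group != focal])
}

# Accept either a named character vector (protein -> genome) or a
# data frame with columns protein_id, genome_id; return the named vector.
as_protein_map <- function(protein_to_genome) {
  if (is.data.frame(protein_to_genome)) {
    if (!all(c("protein_id", "genome_id") %in% names(protein_to_genome))) {
      abort("protein map data frame needs columns protein_id and genome_id")
    }
    return(setNames(as.character(protein_to_genome$genome_id),
                    protein_to_genome$protein_id))
  }
  if (is.null(names(protein_to_genome))) {
    abort("protein map must be a named vector or a data frame")
  }
  protein_to_genome
}

# whole-number percentage, round half up (printed tables use 67%, 62%, ...)
pct_half_up <- function(num, den) {
  ifelse(den > 0, floor(100 * num / den + 0.5), NA_real_)
}

#' Whole-number percentage, rounded half up
#'
#' The rounding used in every printed percentage of the package's summary
#' tables: `floor(100 * num / den + 0.5)`, `NA` when the denominator is 0.
#'
#' @param num,den Numerator and denominator (vectorised).
#' @return Numeric vector of whole-number percentages.
#' @examples
#' pct_round_half_up(154, 229)  # 67
#' @export
pct_round_half_up <- function(num, den) pct_half_up(num, den)

map_genomes <- function(proteins, pmap_vec, context = "protein") {
  g <- unname(pmap_vec[proteins])
  if (anyNA(g)) {
    abort(paste0("unmapped ", context, "(s): ",
                 paste(proteins[is.na(g)], collapse = ", ")))
  }
  g
}
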