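# Phyletic profiles: genome-level presence/absence per cluster, focal-subset
# and partner-pattern labels with exclusive (ø) / inclusive (*) semantics,
# and the ranked-hit clean/dirty classifier.

#' Build phyletic profiles from clusters
#'
#' Presence is computed at the genome level.  Each profile records the focal
#' subset (which focal genomes carry the cluster, as a string of their
#' one-letter codes, e.g. `"AHS"`), the named partner pattern (which of the
#' named non-focal groups are represented, e.g. `"ET"`), and whether any
#' genome outside focal-plus-named-groups is present (`has_other`).
#'
#' @param clusters Cluster tibble from [extract_clusters()].
#' @param protein_to_genome Named vector or data frame mapping every member
#'   protein to a genome; unmapped proteins raise an error naming them.
#' @param groups Group table from [group_def()]; all non-focal groups are the
#'   "named" partner groups.
#' @param focal Name of the focal group.
#' @return A tibble: `cluster_id`, `present_genomes` (list-column),
#'   `focal_subset`, `pattern`, `has_other`, `category` (see
#'   [partition_pattern()]).
#' @export
build_profiles <- function(clusters, protein_to_genome, groups, focal = "FOCAL") {
  groups <- as_group_tbl(groups)
  pmap_vec <- as_protein_map(protein_to_genome)
  fcodes <- focal_codes(groups, focal)
  partners <- partner_groups(groups, focal)
  gmap <- setNames(groups$group, groups$genome_id)

  rows <- map2(clusters$cluster_id, clusters$members, function(id, m) {
    g <- map_genomes(m, pmap_vec)
    present <- unique(g)
    fs <- names(fcodes) %in% present
    if (!any(fs)) abort(paste0("cluster ", id, " has no focal genome"))
    grp <- unname(gmap[present])
    named <- partners[partners %in% grp]
    has_other <- any(is.na(grp) | !(grp %in% c(focal, partners)))
    tibble(
      cluster_id = id, present_genomes = list(present),
      focal_subset = paste(fcodes[fs], collapse = ""),
      pattern = paste(named, collapse = ""),
      has_other = has_other
    )
  })
  pr <- list_rbind(rows)
  pr$category <- partition_pattern(pr)
  pr
}

#' Assign each profile to a mutually exclusive pattern category
#'
#' The category is the named partner pattern when at least one named group is
#' present (e.g. `"RET"`, `"ET"`, `"E"`), `"Other"` when only unnamed
#' lineages accompany the focal genomes, and `"FocalOnly"` when no non-focal
#' genome is present.  Categories are exhaustive and mutually exclusive.
#'
#' @param profiles Profile tibble from [build_profiles()] (needs columns
#'   `pattern` and `has_other`).
#' @return Character vector of categories, one per profile.
#' @export
partition_pattern <- function(profiles) {
  ifelse(nzchar(profiles$pattern), profiles$pattern,
         ifelse(profiles$has_other, "Other", "FocalOnly"))
}

#' Match profiles against an exclusive/inclusive pattern query
#'
#' A query names a subset of the named partner groups plus a marker:
#' `"ET-*"` (inclusive) is true when all named groups of the query are
#' present, regardless of other lineages; `"ET-ø"` (exclusive; ASCII alias
#' `"ET-o"`) additionally requires that no genome outside the focal group
#' and the queried groups is present (no other named group, no unnamed
#' lineage).
#'
#' @param profiles Profile tibble.
#' @param query Pattern string such as `"E-*"`, `"ET-ø"`, `"RET-*"`.
#' @param groups,focal Group table and focal group name (used to validate
#'   the queried letters); optional - when omitted, letters are taken at
#'   face value as single-character group codes.
#' @return Logical vector, one element per profile.
#' @export
match_pattern <- function(profiles, query, groups = NULL, focal = "FOCAL") {
  m <- regmatches(query, regexec("^([A-Za-z]+)-(ø|\\*|o)$", query))[[1]]
  if (length(m) != 3) {
    abort(paste0("malformed pattern query '", query,
                 "': expected e.g. \"ET-*\" or \"E-ø\""))
  }
  wanted <- strsplit(m[2], "")[[1]]
  if (!is.null(groups)) {
    groups <- as_group_tbl(groups)
    known <- partner_groups(groups, focal)
    bad <- setdiff(wanted, known)
    if (length(bad) > 0) {
      abort(paste0("query names unknown partner group(s): ",
                   paste(bad, collapse = ", ")))
    }
  }
  exclusive <- m[3] != "*"
  have <- strsplit(profiles$pattern, "")
  all_wanted <- map_lgl(have, function(h) all(wanted %in% h))
  if (!exclusive) return(all_wanted)
  no_extra <- map_lgl(have, function(h) length(setdiff(h, wanted)) == 0)
  all_wanted & no_extra & !profiles$has_other
}

#' Rank cluster members by similarity to a focal query and classify
#'
#' For each cluster, the query protein is taken from the highest-priority
#' focal genome present (ties broken lexicographically); it receives rank 1
#' and all other members are ranked by ascending e-value of the
#' query-to-subject hit (missing hit records rank last at e-value +Inf;
#' ties by descending bit score, then protein id).  With `k` other focal
#' proteins in the cluster, a *clean* profile has them at exactly ranks
#' `2..k+1`; any interleaving foreign protein makes it *dirty*.  Clusters
#' without non-focal members are *degenerate* and excluded from clean/dirty
#' summaries.
#'
#' @inheritParams build_profiles
#' @param hits Hit tibble with query-to-subject records.
#' @return A tibble: `cluster_id`, `query_protein`, `k`, `n_subjects`,
#'   `focal_ranks` (list-column), `classification` and `ranking`
#'   (list-column tibble of subject, evalue, rank).
#' @export
rank_and_classify <- function(clusters, hits, protein_to_genome, groups,
                              focal = "FOCAL") {
  groups <- as_group_tbl(groups)
  pmap_vec <- as_protein_map(protein_to_genome)
  prio <- focal_priority(groups, focal)
  hit_key <- paste(hits$query_id, hits$subject_id, sep = "\r")

  rows <- map2(clusters$cluster_id, clusters$members, function(id, m) {
    g <- map_genomes(m, pmap_vec)
    is_focal <- g %in% prio
    fp <- m[is_focal]
    pr <- match(g[is_focal], prio)
    query <- fp[order(pr, fp)][1]
    if (is.na(query)) abort(paste0("cluster ", id, " has no focal query protein"))
    subjects <- setdiff(m, query)
    k <- sum(is_focal) - 1L
    if (length(subjects) == 0) {
      return(tibble(
        cluster_id = id, query_protein = query, k = k, n_subjects = 0L,
        focal_ranks = list(integer(0)), classification = "degenerate",
        ranking = list(tibble(subject = character(0), evalue = double(0),
                              rank = integer(0)))
      ))
    }
    idx <- match(paste(query, subjects, sep = "\r"), hit_key)
    ev <- ifelse(is.na(idx), Inf, hits$evalue[idx])
    bs <- ifelse(is.na(idx), -Inf, hits$bitscore[idx])
    ord <- order(ev, -bs, subjects)
    ranked <- subjects[ord]
    ranks <- seq_along(ranked) + 1L
    focal_ranks <- ranks[ranked %in% fp]
    classification <- if (sum(!is_focal) == 0) {
      "degenerate"
    } else if (identical(as.integer(focal_ranks), seq_len(k) + 1L)) {
      "clean"
    } else {
      "dirty"
    }
    tibble(
      cluster_id = id, query_protein = query, k = k,
      n_subjects = length(subjects),
      focal_ranks = list(as.integer(focal_ranks)),
      classification = classification,
      ranking = list(tibble(subject = ranked, evalue = ev[ord], rank = ranks))
    )
  })
  list_rbind(rows)
}

#' Summarise clean/dirty classifications over profile categories
#'
#' Cross-tabulates profiles and their ranked classifications, reporting
#' counts and whole-number percentages (rounded half up, matching printed
#' tables).  Degenerate clusters are excluded from the clean/dirty
#' denominator.
#'
#' @param profiles Profile tibble from [build_profiles()].
#' @param classifications Tibble with `cluster_id` and `classification`
#'   (from [rank_and_classify()], or any aligned table).
#' @param by Grouping columns (default focal subset and category).
#' @return A tibble with per-group `n_total`, `n_clean`, `n_dirty`,
#'   `n_degenerate`, `pct_clean`, `pct_dirty`.
#' @export
profile_summary <- function(profiles, classifications,
                            by = c("focal_subset", "category")) {
  if (!all(profiles$cluster_id %in% classifications$cluster_id)) {
    miss <- setdiff(profiles$cluster_id, classifications$cluster_id)
    abort(paste0("no classification for cluster(s): ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  joined <- profiles |>
    left_join(classifications |> select("cluster_id", "classification"),
              by = "cluster_id")
  joined |>
    group_by(across(all_of(by))) |>
    summarise(
      n_total = n(),
      n_clean = sum(.data$classification == "clean"),
      n_dirty = sum(.data$classification == "dirty"),
      n_degenerate = sum(.data$classification == "degenerate"),
      .groups = "drop"
    ) |>
    mutate(
      pct_clean = pct_half_up(.data$n_clean, .data$n_total - .data$n_degenerate),
      pct_dirty = pct_half_up(.data$n_dirty, .data$n_total - .data$n_degenerate)
    )
}
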