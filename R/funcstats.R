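# Functional-category statistics: COG assignment with a four-step priority,
# the Variable Preference Index (VPI), and category-by-lineage affinities.

# GO evidence codes accepted as experimentally or computationally verified
GO_EVIDENCE <- c("IMP", "IGI", "IPI", "IDA", "IEP", "ISS", "IGC", "ICA")

# majority category, NA on tie or empty input
majority_or_na <- function(x) {
  x <- x[!is.na(x) & x != ""]
  if (length(x) == 0) return(NA_character_)
  tb <- sort(table(x), decreasing = TRUE)
  if (length(tb) > 1 && tb[1] == tb[2]) return(NA_character_)
  names(tb)[1]
}

#' Assign a functional category to each cluster
#'
#' Four-step priority: (1) direct mapping of member proteins through
#' `direct_map` (e.g. the focal reference genome's own COG table); (2)
#' majority vote over the COG annotations of all hit subjects at e-value at
#' most `e_max`; (3) majority vote over GO-derived COG categories of member
#' proteins, restricted to experimentally or computationally verified
#' evidence codes (IMP, IGI, IPI, IDA, IEP, ISS, IGC, ICA); (4) `unknown`.
#' Ties at any step fall through to the next, keeping the assignment
#' deterministic.
#'
#' @param clusters Cluster tibble from [extract_clusters()].
#' @param hits Hit tibble (queries are cluster members).
#' @param direct_map Tibble `protein_id`, `cog_category` for directly mapped
#'   proteins; may be `NULL`.
#' @param hit_annotations Tibble `protein_id`, `cog_category` annotating hit
#'   subjects; may be `NULL`.
#' @param go_annotations Tibble `protein_id`, `go_term`, `evidence`,
#'   `cog_category`; may be `NULL`.
#' @param e_max E-value ceiling for the majority vote (default `1e-15`).
#' @return Tibble `cluster_id`, `cog_category`, `source` where `source` is
#'   one of `direct_map`, `majority_vote`, `go_map`, `unassigned` (the last
#'   always paired with category `unknown`).
#' @export
assign_function <- function(clusters, hits, direct_map = NULL,
                            hit_annotations = NULL, go_annotations = NULL,
                            e_max = 1e-15) {
  check_ann <- function(tb, cols, what) {
    if (is.null(tb)) return(NULL)
    miss <- setdiff(cols, names(tb))
    if (length(miss) > 0) {
      abort(paste0(what, " table missing column(s): ", paste(miss, collapse = ", ")))
    }
    as_tibble(tb)
  }
  direct_map <- check_ann(direct_map, c("protein_id", "cog_category"), "direct-map")
  hit_annotations <- check_ann(hit_annotations, c("protein_id", "cog_category"),
                               "hit-annotation")
  go_annotations <- check_ann(go_annotations,
                              c("protein_id", "evidence", "cog_category"), "GO")
  dmap <- if (is.null(direct_map)) character(0) else
    setNames(direct_map$cog_category, direct_map$protein_id)
  amap <- if (is.null(hit_annotations)) character(0) else
    setNames(hit_annotations$cog_category, hit_annotations$protein_id)
  go <- if (is.null(go_annotations)) NULL else
    go_annotations[go_annotations$evidence %in% GO_EVIDENCE, , drop = FALSE]
  strong_hits <- hits[hits$evalue <= e_max, c("query_id", "subject_id")]
  subj_by_query <- split(strong_hits$subject_id, strong_hits$query_id)

  rows <- map2(clusters$cluster_id, clusters$members, function(id, m) {
    cat <- majority_or_na(unname(dmap[m[m %in% names(dmap)]]))
    if (!is.na(cat)) {
      return(tibble(cluster_id = id, cog_category = cat, source = "direct_map"))
    }
    subj <- unique(unlist(subj_by_query[m], use.names = FALSE))
    cat <- majority_or_na(unname(amap[subj[subj %in% names(amap)]]))
    if (!is.na(cat)) {
      return(tibble(cluster_id = id, cog_category = cat, source = "majority_vote"))
    }
    if (!is.null(go)) {
      cat <- majority_or_na(go$cog_category[go$protein_id %in% m])
      if (!is.na(cat)) {
        return(tibble(cluster_id = id, cog_category = cat, source = "go_map"))
      }
    }
    tibble(cluster_id = id, cog_category = "unknown", source = "unassigned")
  })
  list_rbind(rows)
}

#' Variable Preference Index for one partner group
#'
#' Given the pattern categories of the profiles of one functional category,
#' the VPI for partner group `g` is the number of non-ubiquitous profiles
#' containing `g` (every category that names `g` except the all-partner
#' category, e.g. `(E + RE + ET)` for `g = "E"` when the named groups are R,
#' E, T) divided by the number of profiles that are not focal-restricted
#' (every category except `FocalOnly`).  Ubiquitous (all-partner) profiles
#' therefore can only decrease the VPI.
#'
#' @param categories Character vector of partition categories (one per
#'   profile; see [partition_pattern()]).
#' @param group Single partner group letter, e.g. `"E"`.
#' @param all_groups The named partner groups (default `c("R","E","T")`);
#'   their concatenation is the ubiquitous category.
#' @return One-row tibble `group`, `numerator`, `denominator`, `vpi` (`NA`
#'   with a warning when the denominator is 0).
#' @export
compute_vpi <- function(categories, group, all_groups = c("R", "E", "T")) {
  if (length(group) != 1 || !(group %in% all_groups)) {
    abort(paste0("invalid group code '", paste(group, collapse = ","),
                 "': must be one of ", paste(all_groups, collapse = ", ")))
  }
  ubiquitous <- paste(all_groups, collapse = "")
  named <- !(categories %in% c("Other", "FocalOnly"))
  num <- sum(named & grepl(group, categories, fixed = TRUE) &
               categories != ubiquitous)
  den <- sum(categories != "FocalOnly")
  if (den == 0) {
    warn("VPI undefined: no non-focal-restricted profiles")
    return(tibble(group = group, numerator = num, denominator = 0L, vpi = NA_real_))
  }
  tibble(group = group, numerator = num, denominator = den, vpi = num / den)
}

#' VPI per functional category and partner group
#'
#' @param profiles Profile tibble with a `category` column (from
#'   [build_profiles()]).
#' @param functions Tibble `cluster_id`, `cog_category` (from
#'   [assign_function()]).
#' @param groups Partner group letters (default `c("R","E","T")`).
#' @return A tibble of class `clanprof_vpi`: one row per
#'   (cog_category, group) with `numerator`, `denominator`, `vpi`.
#' @export
vpi_by_category <- function(profiles, functions, groups = c("R", "E", "T")) {
  joined <- profiles |>
    inner_join(functions |> select("cluster_id", "cog_category"),
               by = "cluster_id")
  out <- joined |>
    group_by(.data$cog_category) |>
    summarise(res = {
      cats <- .data$category
      list(list_rbind(map(groups, function(g) {
        compute_vpi(cats, g, all_groups = groups)
      })))
    }, .groups = "drop") |>
    tidyr::unnest("res")
  class(out) <- c("clanprof_vpi", class(out))
  out
}

#' Category-by-lineage affinity matrix from supported tree pairings
#'
#' For each functional category, the fraction of its gene trees whose
#' supported pairing (see [pairing_support()]) includes each lineage.  A
#' tree can credit several lineages, so rows need not sum to 1.
#'
#' @param tree_tbl Tibble with columns `category` and `tree_set`
#'   (list-column of [gene_tree_set()] objects).
#' @param lineage_map Named vector or data frame mapping genomes to lineages.
#' @param groups,focal Group table and focal group name.
#' @param min_support Bootstrap support threshold (default 70).
#' @return A tibble of class `clanprof_affinity`: `category`, `lineage`,
#'   `n_trees`, `n_paired`, `prop`.
#' @export
affinity_matrix <- function(tree_tbl, lineage_map, groups, focal = "FOCAL",
                            min_support = 70) {
  if (is.data.frame(lineage_map)) {
    lineage_map <- setNames(as.character(lineage_map$lineage),
                            lineage_map$genome_id)
  }
  groups <- as_group_tbl(groups)
  fg <- group_members(groups, focal)
  lineages <- sort(unique(unname(lineage_map[setdiff(names(lineage_map), fg)])))
  pairings <- map(tree_tbl$tree_set, pairing_support, lineage_map = lineage_map,
                  groups = groups, focal = focal, min_support = min_support)
  cats <- unique(tree_tbl$category)
  out <- list_rbind(map(cats, function(cc) {
    px <- pairings[tree_tbl$category == cc]
    list_rbind(map(lineages, function(l) {
      tibble(category = cc, lineage = l, n_trees = length(px),
             n_paired = sum(map_lgl(px, function(p) l %in% p)))
    }))
  }))
  out$prop <- ifelse(out$n_trees > 0, out$n_paired / out$n_trees, NA_real_)
  out <- out[out$n_trees > 0, , drop = FALSE]
  class(out) <- c("clanprof_affinity", class(out))
  out
}
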