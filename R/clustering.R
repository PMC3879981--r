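# Homolog clustering seeded on focal-genome proteins: a strict reciprocal-hit
# graph over focal proteins defines connected components; each component then
# recruits every subject matched at the looser membership threshold.

#' Build the strict reciprocal-hit graph over focal proteins
#'
#' Nodes are all proteins of the focal genomes; an edge joins two focal
#' proteins when *bidirectional* hits with e-value at most `e_bidir` exist
#' (both directions present in `hits`).  Self-hits are ignored.
#'
#' @param hits Deduplicated hit tibble (see [read_similarity_table()]).
#' @param protein_to_genome Named vector or data frame mapping protein ids to
#'   genome ids.  Its focal entries define the node set.
#' @param groups Group table from [group_def()].
#' @param focal Name of the focal group in `groups`.
#' @param e_bidir Strict e-value threshold for graph edges (default `1e-10`).
#' @return An `igraph` undirected graph whose vertices are focal protein ids.
#' @export
build_focal_graph <- function(hits, protein_to_genome, groups,
                              focal = "FOCAL", e_bidir = 1e-10) {
  groups <- as_group_tbl(groups)
  fg <- group_members(groups, focal)
  if (length(fg) == 0) abort(paste0("focal group '", focal, "' has no genomes"))
  pmap_vec <- as_protein_map(protein_to_genome)
  focal_prot <- names(pmap_vec)[pmap_vec %in% fg]
  if (length(focal_prot) == 0) abort("no focal proteins in the protein map")

  h <- hits |>
    filter(.data$evalue <= e_bidir,
           .data$query_id %in% focal_prot,
           .data$subject_id %in% focal_prot,
           .data$query_id != .data$subject_id)
  # keep (p,q) only when (q,p) also present
  fwd <- paste(h$query_id, h$subject_id, sep = "\r")
  rev <- paste(h$subject_id, h$query_id, sep = "\r")
  h <- h[fwd %in% rev, , drop = FALSE]
  und <- unique(tibble(
    a = pmin(h$query_id, h$subject_id),
    b = pmax(h$query_id, h$subject_id)
  ))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(focal_prot), name = focal_prot)
  if (nrow(und) > 0) {
    g <- igraph::add_edges(g, rbind(und$a, und$b))
  }
  g
}

#' Extract homolog clusters from the focal graph
#'
#' One cluster per connected component of the strict graph (isolated focal
#' proteins give singleton-seeded clusters).  Members are the component's
#' focal proteins plus every subject any of them hits at e-value at most
#' `e_member`, deduplicated within the cluster.  The seed is the component
#' protein from the highest-priority focal genome present (priority = order
#' of the focal group in `groups`; ties broken lexicographically).
#'
#' @inheritParams build_focal_graph
#' @param graph Graph from [build_focal_graph()].
#' @param e_member Membership e-value threshold (default `1e-5`); must be at
#'   least the `e_bidir` the graph was built with.
#' @return A tibble with one row per cluster: `cluster_id`, `seed_protein`,
#'   `members` (list-column), `n_members`, per-focal-genome copy counts
#'   (list-column `focal_copies`) and `copy_class` (`single`/`multi`).
#' @export
extract_clusters <- function(graph, hits, protein_to_genome, groups,
                             focal = "FOCAL", e_member = 1e-5) {
  groups <- as_group_tbl(groups)
  pmap_vec <- as_protein_map(protein_to_genome)
  prio <- focal_priority(groups, focal)
  comp <- igraph::components(graph)
  membership <- comp$membership
  prot <- igraph::V(graph)$name

  # recruited subjects are non-focal: every focal protein already belongs to
  # exactly one component, so clusters partition the focal proteins while
  # non-focal subjects may be recruited by several clusters
  recruit <- hits |>
    filter(.data$evalue <= e_member, .data$query_id %in% prot,
           !(.data$subject_id %in% prot)) |>
    select("query_id", "subject_id")
  recruit_by_prot <- split(recruit$subject_id, recruit$query_id)

  comp_list <- split(prot, membership)
  rows <- map(comp_list, function(fp) {
    subjects <- unlist(recruit_by_prot[fp], use.names = FALSE)
    members <- unique(c(fp, subjects))
    g_of <- unname(pmap_vec[fp])
    pr <- match(g_of, prio)
    seed <- fp[order(pr, fp)][1]
    tibble(seed_protein = seed, members = list(members),
           focal_proteins = list(fp))
  })
  cl <- list_rbind(rows) |> arrange(.data$seed_protein)
  cl$cluster_id <- sprintf("C%05d", seq_len(nrow(cl)))
  cl$n_members <- map_int(cl$members, length)
  cl <- classify_copy_number(cl, pmap_vec, groups, focal = focal)
  cl |> select("cluster_id", "seed_protein", "members", "n_members",
               "focal_copies", "copy_class")
}

#' Classify clusters as single- or multi-copy in the focal genomes
#'
#' A cluster is `single`-copy when every focal genome represented in it has
#' exactly one member protein, and `multi` otherwise.
#'
#' @param clusters Cluster tibble with a `members` list-column.
#' @inheritParams build_focal_graph
#' @return `clusters` with `focal_copies` (list-column of named counts) and
#'   `copy_class` columns added/replaced.
#' @export
classify_copy_number <- function(clusters, protein_to_genome, groups,
                                 focal = "FOCAL") {
  groups <- as_group_tbl(groups)
  fg <- focal_priority(groups, focal)
  pmap_vec <- as_protein_map(protein_to_genome)
  counts <- map(clusters$members, function(m) {
    g <- unname(pmap_vec[m])
    fm <- g[!is.na(g) & g %in% fg]
    if (length(fm) == 0) {
      abort("cluster without any focal member: clusters must be focal-seeded")
    }
    table(factor(fm, levels = fg))
  })
  clusters$focal_copies <- map(counts, function(tb) setNames(as.integer(tb), names(tb)))
  clusters$copy_class <- map_chr(counts, function(tb) {
    if (max(tb) == 1L) "single" else "multi"
  })
  clusters
}

#' Long form of a cluster table
#'
#' @param clusters Cluster tibble from [extract_clusters()].
#' @return A tibble with one row per (cluster, member protein).
#' @export
cluster_members <- function(clusters) {
  tibble(
    cluster_id = rep(clusters$cluster_id, map_int(clusters$members, length)),
    protein_id = unlist(clusters$members, use.names = FALSE)
  )
}
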