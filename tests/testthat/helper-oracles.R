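# Independent brute-force oracles.  Each recomputes the quantity by a route
# that shares no code with the package implementation (edge-deletion
# components via igraph, direct sorting, direct set logic).

# all splits of a tree by deleting each edge in an igraph copy;
# returns a list of list(side1, side2 (tip labels), edge_row)
oracle_splits <- function(tree) {
  nt <- length(tree$tip.label)
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2, as.character),
                                   directed = FALSE)
  lapply(seq_len(nrow(tree$edge)), function(j) {
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(
      g, as.character(tree$edge[j, ])))
    cm <- igraph::components(g2)$membership
    ids <- as.integer(igraph::V(g)$name)
    side1 <- ids[cm == 1 & ids <= nt]
    side2 <- ids[cm == 2 & ids <= nt]
    list(side1 = sort(tree$tip.label[side1]),
         side2 = sort(tree$tip.label[side2]), edge_row = j)
  })
}

# clan detection by brute force: is `leaves` exactly one side of a split?
oracle_is_clan <- function(tree, leaves) {
  leaves <- sort(leaves)
  any(vapply(oracle_splits(tree), function(s) {
    identical(s$side1, leaves) || identical(s$side2, leaves)
  }, TRUE))
}

# clan-to-group distance by brute force: find the defining edge, then count
# internal edges on the igraph shortest path from its outer endpoint to each
# group leaf's parent
oracle_clan_distance <- function(tree, clan_leaves, group_leaves) {
  clan_leaves <- sort(clan_leaves)
  nt <- length(tree$tip.label)
  sp <- oracle_splits(tree)
  hit <- which(vapply(sp, function(s) {
    identical(s$side1, clan_leaves) || identical(s$side2, clan_leaves)
  }, TRUE))[1]
  if (is.na(hit)) stop("not a clan")
  j <- sp[[hit]]$edge_row
  ends <- tree$edge[j, ]
  # outer endpoint: the one from which clan leaves are unreachable without
  # crossing the deleted edge
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2, as.character),
                                   directed = FALSE)
  g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, as.character(ends)))
  cm <- igraph::components(g2)$membership
  clan_idx <- match(clan_leaves, tree$tip.label)
  clan_comp <- cm[as.character(clan_idx[1])]
  outer <- ends[cm[as.character(ends)] != clan_comp]
  targets <- setdiff(match(group_leaves, tree$tip.label), clan_idx)
  if (length(targets) == 0) return(Inf)
  parents <- vapply(targets, function(tp) tree$edge[tree$edge[, 2] == tp, 1], 0)
  d <- igraph::distances(g, v = as.character(outer),
                         to = as.character(unique(parents)))
  min(d)
}

# direct case analysis for pattern categories
oracle_partition <- function(pattern, has_other) {
  if (nzchar(pattern)) return(pattern)
  if (has_other) return("Other")
  "FocalOnly"
}

# set logic for pattern queries
oracle_match <- function(pattern, has_other, letters_wanted, exclusive) {
  have <- strsplit(pattern, "")[[1]]
  if (!all(letters_wanted %in% have)) return(FALSE)
  if (!exclusive) return(TRUE)
  length(setdiff(have, letters_wanted)) == 0 && !has_other
}

# direct recomputation of ranked clean/dirty via a data.frame sort
oracle_rank_classify <- function(members, genomes, hits, focal_order) {
  is_f <- genomes %in% focal_order
  fp <- members[is_f]
  query <- fp[order(match(genomes[is_f], focal_order), fp)][1]
  subjects <- setdiff(members, query)
  if (sum(!is_f) == 0) return("degenerate")
  df <- data.frame(s = subjects, stringsAsFactors = FALSE)
  key <- paste(hits$query_id, hits$subject_id)
  i <- match(paste(query, df$s), key)
  df$e <- ifelse(is.na(i), Inf, hits$evalue[i])
  df$b <- ifelse(is.na(i), -Inf, hits$bitscore[i])
  df <- df[order(df$e, -df$b, df$s), ]
  ranks <- which(df$s %in% fp) + 1L
  k <- length(fp) - 1L
  if (identical(as.integer(ranks), seq_len(k) + 1L)) "clean" else "dirty"
}

# direct VPI formula from a category count table
oracle_vpi <- function(categories, group, all_groups = c("R", "E", "T")) {
  ubiq <- paste(all_groups, collapse = "")
  named <- setdiff(unique(categories), c("Other", "FocalOnly"))
  num <- sum(categories %in% named[grepl(group, named, fixed = TRUE)] &
               categories != ubiq)
  den <- sum(categories != "FocalOnly")
  if (den == 0) NA_real_ else num / den
}
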