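# Unrooted-tree operations: homogeneous clans, clan-to-group distances,
# bootstrap balance of support, supported pairings, taxon reductions and
# supermatrix assembly.

# resolve tips belonging to a genome set; genome_of maps tip label -> genome
# (NULL means tip labels already are genome ids)
group_tips <- function(tree, genomes, genome_of = NULL) {
  labs <- tree$tip.label
  g <- if (is.null(genome_of)) labs else unname(genome_of[labs])
  which(g %in% genomes)
}

as_unrooted <- function(tree) {
  if (ape::is.rooted(tree)) normalize_gene_tree(tree) else tree
}

#' Find the homogeneous clan of a group in an unrooted tree
#'
#' A clan is the leaf set on one side of an edge.  The group forms a
#' homogeneous clan when some edge has exactly the group's leaves on one
#' side (no intruder, no group leaf left outside).  Rooted input trees are
#' treated as unrooted.
#'
#' @param tree A `phylo` tree.
#' @param group Character vector of genome ids (or tip labels when
#'   `genome_of` is `NULL`).
#' @param genome_of Optional named vector mapping tip labels to genome ids.
#' @return `NULL` when the group is not cohesive; otherwise a list of class
#'   `clan` with elements `tips` (leaf labels), `edge_child`, `clan_is_clade`,
#'   `outer_node` (the defining-edge endpoint on the far side), `support`
#'   (numeric or `NA`) and `tree` (the unrooted tree the node ids refer to).
#' @export
find_homogeneous_clan <- function(tree, group, genome_of = NULL) {
  tree <- as_unrooted(tree)
  gt <- group_tips(tree, group, genome_of)
  if (length(gt) == 0) {
    abort(paste0("group absent from tree: ", paste(group, collapse = ", ")))
  }
  nt <- length(tree$tip.label)
  if (length(gt) == nt) {
    abort("group covers every leaf; no outside leaf to define a clan")
  }
  ec <- edge_clades(tree)
  tr <- ec$tree
  supp <- edge_support_from_labels(tr, ec)
  gset <- sort(gt)
  all_tips <- seq_len(nt)
  for (j in seq_along(ec$below)) {
    side <- sort(ec$below[[j]])
    clan_is_clade <- identical(side, gset)
    comp_is_clan <- !clan_is_clade &&
      identical(sort(setdiff(all_tips, side)), gset)
    if (clan_is_clade || comp_is_clan) {
      return(structure(list(
        tips = tr$tip.label[gt],
        edge_child = ec$edge[j, 2],
        edge_parent = ec$edge[j, 1],
        clan_is_clade = clan_is_clade,
        outer_node = if (clan_is_clade) ec$edge[j, 1] else ec$edge[j, 2],
        support = supp[j],
        tree = tr
      ), class = "clan"))
    }
  }
  NULL
}

#' Is a group cohesive in a tree?
#'
#' `TRUE` when the group's leaves form a homogeneous clan; single-leaf
#' groups are cohesive by convention.
#'
#' @inheritParams find_homogeneous_clan
#' @return Logical scalar.
#' @export
is_cohesive <- function(tree, group, genome_of = NULL) {
  gt <- group_tips(tree, group, genome_of)
  if (length(gt) == 1) return(TRUE)
  !is.null(find_homogeneous_clan(tree, group, genome_of))
}

#' Internal-edge distance from a clan to the nearest leaf of a group
#'
#' Counts the internal edges strictly between the clan's defining edge and
#' the pendant edge of a group leaf, minimised over the group's leaves
#' outside the clan (0 when a group leaf attaches at the clan's outer
#' node).  Returns `Inf` when the group has no leaf outside the clan.
#'
#' @param clan A `clan` from [find_homogeneous_clan()] (carries its tree).
#' @param group Character vector of genome ids (or tip labels).
#' @param genome_of Optional named vector mapping tip labels to genomes.
#' @return Non-negative integer distance, or `Inf`.
#' @export
clan_distance <- function(clan, group, genome_of = NULL) {
  if (!inherits(clan, "clan")) abort("`clan` must come from find_homogeneous_clan()")
  tree <- clan$tree
  gt <- group_tips(tree, group, genome_of)
  gt <- setdiff(gt, match(clan$tips, tree$tip.label))
  if (length(gt) == 0) return(Inf)
  adj <- tree_adjacency(tree)
  d <- bfs_node_dist(adj, clan$outer_node)
  par <- tip_parents(tree)
  min(d[par[gt]])
}

#' Balance of bootstrap support between two candidate partner groups
#'
#' Over the bootstrap replicates, counts +1 for every replicate in which
#' group `x` is closer (fewer intervening internal edges) to the homogeneous
#' focal clan than group `y`, -1 when the reverse holds, and 0 for ties,
#' replicates missing either group, or replicates in which the focal
#' genomes are not cohesive.  The score therefore lies in
#' `[-n_replicates, +n_replicates]`, and swapping `x` and `y` flips its
#' sign.  The pair is flagged `strong` when `|score|` exceeds
#' `strong_frac * n_replicates`.
#'
#' @param tree_set A [gene_tree_set()].
#' @param x,y Group codes to compare (looked up in `groups`).
#' @param groups Group table from [group_def()].
#' @param focal Focal group name.
#' @param strong_frac Fraction of replicates that `|score|` must exceed to
#'   be flagged strong (default 0.70).
#' @return One-row tibble: `group_x`, `group_y`, `score`, `n_replicates`,
#'   `strong`.
#' @export
balance_of_support <- function(tree_set, x, y, groups, focal = "FOCAL",
                               strong_frac = 0.70) {
  groups <- as_group_tbl(groups)
  fg <- group_members(groups, focal)
  xg <- group_members(groups, x)
  yg <- group_members(groups, y)
  if (length(xg) == 0 || length(yg) == 0) {
    abort(paste0("unknown group code: ", if (length(xg) == 0) x else y))
  }
  genome_of <- tree_set$leaf_genome
  present_focal <- fg[fg %in% genome_of]
  if (length(present_focal) == 0) abort("focal group absent from the trees")
  score <- 0L
  for (rep_tree in tree_set$replicates) {
    cl <- find_homogeneous_clan(rep_tree, present_focal, genome_of)
    if (is.null(cl)) next
    dx <- clan_distance(cl, xg, genome_of)
    dy <- clan_distance(cl, yg, genome_of)
    if (is.infinite(dx) || is.infinite(dy)) next
    if (dx < dy) score <- score + 1L else if (dy < dx) score <- score - 1L
  }
  tibble(
    group_x = x, group_y = y, score = score,
    n_replicates = tree_set$n_replicates,
    strong = abs(score) > strong_frac * tree_set$n_replicates
  )
}

#' Lineages paired with the focal clan at a minimum bootstrap support
#'
#' In the ML tree, finds the smallest clan strictly containing the
#' homogeneous focal clan whose defining edge has support at least
#' `min_support`, and returns the lineages of its non-focal leaves (the
#' groups the tree confidently pairs with the focal clade).  Empty when the
#' focal genomes are not cohesive or no such supported clan exists.  The
#' result depends only on splits and supports, so it is invariant to
#' re-rooting.
#'
#' @param tree_set A [gene_tree_set()] whose ML tree carries supports.
#' @param lineage_map Named vector (or data frame `genome_id`, `lineage`)
#'   giving the lineage of every genome.
#' @param groups,focal Group table and focal group name.
#' @param min_support Support threshold on the defining edge (default 70).
#' @return Character vector of lineages (possibly empty).
#' @export
pairing_support <- function(tree_set, lineage_map, groups, focal = "FOCAL",
                            min_support = 70) {
  groups <- as_group_tbl(groups)
  if (is.data.frame(lineage_map)) {
    lineage_map <- setNames(as.character(lineage_map$lineage),
                            lineage_map$genome_id)
  }
  fg <- group_members(groups, focal)
  genome_of <- tree_set$leaf_genome
  present_focal <- fg[fg %in% genome_of]
  tree <- tree_set$ml
  cl <- if (length(present_focal) == 0) NULL else
    tryCatch(find_homogeneous_clan(tree, present_focal, genome_of),
             error = function(e) NULL)
  if (is.null(cl)) return(character(0))
  tr <- cl$tree
  nt <- length(tr$tip.label)
  focal_tips <- sort(match(cl$tips, tr$tip.label))
  ec <- edge_clades(tr)
  supp <- edge_support_from_labels(tr, ec)
  all_tips <- seq_len(nt)
  best <- NULL
  for (j in seq_along(ec$below)) {
    for (side in list(sort(ec$below[[j]]),
                      sort(setdiff(all_tips, ec$below[[j]])))) {
      if (length(side) <= length(focal_tips) || length(side) == nt) next
      if (!all(focal_tips %in% side)) next
      if (is.na(supp[j]) || supp[j] < min_support) next
      cand <- list(size = length(side), support = supp[j], side = side)
      if (is.null(best) || cand$size < best$size ||
          (cand$size == best$size && cand$support > best$support)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) return(character(0))
  partner_tips <- setdiff(best$side, focal_tips)
  lin <- unname(lineage_map[genome_of[tr$tip.label[partner_tips]]])
  sort(unique(lin[!is.na(lin)]))
}

#' Reduce over-represented genera on a guide tree
#'
#' Any genus with more than two leaves that forms a homogeneous clan in the
#' guide tree is reduced to two representatives, one sampled from each
#' descendant subtree of the clan's internal attachment node
#' (lexicographically smallest leaf id in each); genera with two or fewer
#' leaves, and non-cohesive genera, are left untouched.
#'
#' @param guide_tree A `phylo` guide tree (e.g. neighbour joining).
#' @param genus_map Named vector (or data frame `genome_id`/`leaf`, `genus`)
#'   mapping leaf labels to genera.
#' @return Character vector of retained leaf labels.
#' @export
genus_reduce <- function(guide_tree, genus_map) {
  if (is.data.frame(genus_map)) {
    keycol <- intersect(c("genome_id", "leaf", "protein_id"), names(genus_map))[1]
    genus_map <- setNames(as.character(genus_map$genus), genus_map[[keycol]])
  }
  tree <- as_unrooted(guide_tree)
  labs <- tree$tip.label
  genus <- unname(genus_map[labs])
  drop <- character(0)
  for (g in unique(genus[!is.na(genus)])) {
    gl <- labs[which(genus == g)]
    if (length(gl) <= 2) next
    cl <- find_homogeneous_clan(tree, g, setNames(genus, labs))
    if (is.null(cl)) next
    tr <- cl$tree
    adj <- tree_adjacency(tr)
    inner <- if (cl$clan_is_clade) cl$edge_child else cl$edge_parent
    outer <- cl$outer_node
    keep_reps <- character(0)
    for (nb in setdiff(adj[[inner]], outer)) {
      # leaves of the subtree hanging off `inner` through `nb`
      sub <- subtree_tips(adj, nb, inner, length(tr$tip.label))
      keep_reps <- c(keep_reps, sort(tr$tip.label[sub])[1])
    }
    drop <- c(drop, setdiff(gl, keep_reps))
  }
  setdiff(labs, drop)
}

# tips reachable from `start` without passing through `blocked`
subtree_tips <- function(adj, start, blocked, ntip) {
  seen <- c(blocked, start)
  frontier <- start
  tips <- integer(0)
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) {
      if (v <= ntip) tips <- c(tips, v)
      for (w in adj[[v]]) {
        if (!(w %in% seen)) {
          seen <- c(seen, w)
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  tips
}

#' Reduce in-paralogs to one representative per genome
#'
#' For every genome with multiple leaves in the tree, keeps the leaf with
#' the shortest terminal branch (ties broken lexicographically by label).
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param genome_of Named vector mapping leaf labels to genomes.
#' @return Character vector of retained leaf labels.
#' @export
reduce_inparalogs <- function(tree, genome_of = NULL) {
  labs <- tree$tip.label
  g <- if (is.null(genome_of)) labs else unname(genome_of[labs])
  if (anyNA(g)) {
    abort(paste0("leaves without a genome mapping: ",
                 paste(labs[is.na(g)], collapse = ", ")))
  }
  nt <- length(labs)
  e <- tree$edge
  tip_rows <- match(seq_len(nt), e[, 2])
  blen <- if (is.null(tree$edge.length)) rep(0, nt) else tree$edge.length[tip_rows]
  keep <- tapply(seq_len(nt), g, function(ix) {
    ix[order(blen[ix], labs[ix])][1]
  })
  sort(labs[unlist(keep)])
}

#' Prune a tree to a taxon set
#'
#' Induced subtree on the requested leaves; suppressed degree-2 nodes have
#' their branch lengths summed.
#'
#' @param tree A `phylo` tree.
#' @param taxa Leaf labels to retain.
#' @return The pruned `phylo` tree.
#' @export
prune_to_taxa <- function(tree, taxa) {
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing) > 0) {
    abort(paste0("taxa absent from tree: ", paste(missing, collapse = ", ")))
  }
  if (setequal(taxa, tree$tip.label)) return(tree)
  ape::keep.tip(tree, taxa)
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' Each alignment may contain at most one sequence per genome (reduce
#' in-paralogs first); genomes missing from a gene are padded with gaps.
#' The partition table records the column range of every gene.
#'
#' @param alignments Named list of [conf_alignment()] objects.
#' @param taxon_of Named vector (or data frame) mapping sequence/protein ids
#'   to genome ids; defaults to sequence names already being genome ids.
#' @return A list of class `supermatrix`: `alignment` (a `conf_alignment`
#'   over genomes) and `partitions` (tibble `gene`, `start`, `end`).
#' @export
build_supermatrix <- function(alignments, taxon_of = NULL) {
  if (is.null(names(alignments)) || any(names(alignments) == "")) {
    names(alignments) <- paste0("gene", seq_along(alignments))
  }
  if (!is.null(taxon_of)) taxon_of <- as_protein_map(taxon_of)
  per_gene <- imap(alignments, function(aln, gene) {
    ids <- names(aln$sequences)
    gen <- if (is.null(taxon_of)) ids else map_genomes(ids, taxon_of)
    dup <- unique(gen[duplicated(gen)])
    if (length(dup) > 0) {
      abort(paste0("gene ", gene, " has multiple sequences for genome(s) ",
                   paste(dup, collapse = ", "),
                   ": apply reduce_inparalogs() first"))
    }
    list(gene = gene, seqs = setNames(unname(aln$sequences), gen),
         conf = aln$column_confidence,
         width = length(aln$column_confidence))
  })
  genomes <- sort(unique(unlist(map(per_gene, function(g) names(g$seqs)))))
  widths <- unname(map_int(per_gene, function(g) as.integer(g$width)))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  blocks <- map(per_gene, function(g) {
    pad <- strrep("-", g$width)
    out <- setNames(rep(pad, length(genomes)), genomes)
    out[names(g$seqs)] <- g$seqs
    out
  })
  seqs <- setNames(do.call(paste0, blocks), genomes)
  conf <- unlist(map(per_gene, function(g) g$conf), use.names = FALSE)
  structure(list(
    alignment = conf_alignment(seqs, conf),
    partitions = tibble(gene = names(alignments), start = starts, end = ends)
  ), class = "supermatrix")
}

#' Write a supermatrix as FASTA, relaxed PHYLIP and a partition file
#'
#' @param x A `supermatrix` from [build_supermatrix()].
#' @param fasta_path,phylip_path,partition_path Output paths (any may be
#'   `NULL` to skip).
#' @return `x`, invisibly.
#' @export
write_supermatrix <- function(x, fasta_path = NULL, phylip_path = NULL,
                              partition_path = NULL) {
  aln <- x$alignment
  if (!is.null(fasta_path)) {
    write_conf_alignment(aln, fasta_path)
  }
  if (!is.null(phylip_path)) {
    hdr <- paste(length(aln$sequences), nchar(aln$sequences[[1]]))
    body <- paste(names(aln$sequences), aln$sequences)
    writeLines(c(hdr, body), phylip_path)
  }
  if (!is.null(partition_path)) {
    writeLines(sprintf("WAG, %s = %d-%d", x$partitions$gene,
                       x$partitions$start, x$partitions$end), partition_path)
  }
  invisible(x)
}
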