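# Low-level unrooted-tree machinery shared by the tree operations: per-edge
# leaf sets (clades viewed from the child side) and canonical split keys.
# A split key identifies the bipartition an edge induces independently of
# rooting or tip order, so supports and bootstrap counts can be matched
# across trees on the same leaf set.

# Per-edge tip-index sets via one postorder pass.
# Returns the postorder-reordered tree, its edge matrix, and for each edge
# row the tip indices (into tree$tip.label) below the child endpoint.
edge_clades <- function(tree) {
  nt <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", nt + tr$Nnode)
  for (i in seq_len(nt)) below[[i]] <- i
  e <- tr$edge
  for (j in seq_len(nrow(e))) {
    below[[e[j, 1]]] <- c(below[[e[j, 1]]], below[[e[j, 2]]])
  }
  list(tree = tr, edge = e, below = below[e[, 2]], ntip = nt)
}

# Canonical split keys for every edge.  label_index maps tip label -> integer
# position in a fixed ordering of the full leaf set (defaults to the sorted
# tip labels of this tree); bitmask arithmetic is exact up to 53 leaves,
# beyond that a sorted-index string is used.
split_keys <- function(tree, label_index = NULL) {
  labs <- tree$tip.label
  if (is.null(label_index)) {
    label_index <- setNames(seq_along(sort(labs)), sort(labs))
  }
  idx <- unname(label_index[labs])
  if (anyNA(idx)) {
    abort(paste0("tree leaves absent from label index: ",
                 paste(labs[is.na(idx)], collapse = ", ")))
  }
  ec <- edge_clades(tree)
  nt <- length(label_index)
  if (nt <= 53) {
    pw <- 2^(idx - 1)
    full <- sum(2^(seq_len(nt) - 1))
    m <- vapply(ec$below, function(tt) sum(pw[tt]), 0)
    key <- as.character(pmin(m, full - m))
  } else {
    key <- vapply(ec$below, function(tt) {
      s <- sort(idx[tt])
      comp <- setdiff(seq_len(nt), s)
      if (length(comp) < length(s) ||
          (length(comp) == length(s) && comp[1] < s[1])) s <- comp
      paste(s, collapse = ",")
    }, "")
  }
  c(ec, list(key = key))
}

# numeric per-edge support (from internal-node labels, child side); NA for
# pendant edges or unlabeled nodes.  Operates on the edge matrix of `ec`.
edge_support_from_labels <- function(tree, ec) {
  nt <- length(tree$tip.label)
  child <- ec$edge[, 2]
  supp <- rep(NA_real_, nrow(ec$edge))
  if (!is.null(tree$node.label)) {
    lab <- suppressWarnings(as.numeric(tree$node.label))
    int <- child > nt
    supp[int] <- lab[child[int] - nt]
  }
  supp
}

# Rescale node-label supports to [0,100] (0-1 dialect scaled up), validate
# range, then unroot while re-attaching each support to the edge that still
# carries the same split.  Trees without node labels are just unrooted.
normalize_gene_tree <- function(tree) {
  if (length(tree$tip.label) < 2) abort("tree must have at least 2 leaves")
  has_lab <- !is.null(tree$node.label) &&
    any(!is.na(suppressWarnings(as.numeric(tree$node.label))))
  if (has_lab) {
    supp <- suppressWarnings(as.numeric(tree$node.label))
    ok <- !is.na(supp)
    # 0-1 dialect: only when a value strictly between 0 and 1 occurs
    # (bare 0s and 1s are taken as percentages)
    if (all(supp[ok] >= 0 & supp[ok] <= 1) &&
        any(supp[ok] > 0 & supp[ok] < 1)) supp[ok] <- supp[ok] * 100
    if (any(supp[ok] < 0 | supp[ok] > 100)) {
      abort("edge supports must lie in [0, 100] (or [0, 1], scaled by 100)")
    }
    sk <- split_keys(tree)
    es <- rep(NA_real_, length(sk$key))
    int <- sk$edge[, 2] > sk$ntip
    es[int] <- supp[sk$edge[int, 2] - sk$ntip]
    smap <- tapply(es, sk$key, function(v) {
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    })
  }
  ut <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  if (has_lab) {
    sk2 <- split_keys(ut)
    nt <- sk2$ntip
    lab <- rep(NA_real_, ut$Nnode)
    int <- which(sk2$edge[, 2] > nt)
    lab[sk2$edge[int, 2] - nt] <- unname(smap[sk2$key[int]])
    ut <- sk2$tree  # postorder-reordered copy consistent with sk2
    ut$node.label <- ifelse(is.na(lab), "", as.character(lab))
  } else {
    ut$node.label <- NULL
  }
  ut
}

# adjacency list (node -> neighbouring nodes) for BFS walks
tree_adjacency <- function(tree) {
  nn <- length(tree$tip.label) + tree$Nnode
  adj <- vector("list", nn)
  e <- tree$edge
  for (j in seq_len(nrow(e))) {
    adj[[e[j, 1]]] <- c(adj[[e[j, 1]]], e[j, 2])
    adj[[e[j, 2]]] <- c(adj[[e[j, 2]]], e[j, 1])
  }
  adj
}

# edge counts from node `from` to every node (simple BFS; trees are small)
bfs_node_dist <- function(adj, from) {
  d <- rep(NA_integer_, length(adj))
  d[from] <- 0L
  frontier <- from
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.na(d[w])) {
          d[w] <- d[v] + 1L
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  d
}

# parent node of every tip
tip_parents <- function(tree) {
  nt <- length(tree$tip.label)
  e <- tree$edge
  p <- integer(nt)
  tip_rows <- e[, 2] <= nt
  p[e[tip_rows, 2]] <- e[tip_rows, 1]
  p
}
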