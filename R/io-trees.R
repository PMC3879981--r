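# Gene tree sets: an ML tree with edge supports plus bootstrap replicates,
# leaves resolvable to genomes.  All trees are handled as unrooted.

#' Construct a gene tree set
#'
#' Bundles a maximum-likelihood gene tree (with optional per-edge bootstrap
#' supports as internal node labels) and its bootstrap replicate trees.
#' Trees are unrooted on construction; supports given on a 0-1 scale are
#' rescaled to 0-100, and each support is re-attached to the edge carrying
#' the same bipartition so that unrooting cannot silently shift it.
#'
#' @param ml A `phylo` ML tree.
#' @param replicates A `multiPhylo` (or list of `phylo`) of bootstrap
#'   replicate topologies on the same leaf set.
#' @param leaf_to_genome Named character vector or data frame
#'   (`protein_id`/`leaf`, `genome_id`) resolving every leaf label to a
#'   genome.  Defaults to leaf labels being genome ids.
#' @return An object of class `gene_tree_set`: a list with elements `ml`,
#'   `replicates`, `leaf_genome`, `n_replicates`.
#' @export
gene_tree_set <- function(ml, replicates, leaf_to_genome = NULL) {
  if (!inherits(ml, "phylo")) abort("`ml` must be a phylo tree")
  if (inherits(replicates, "phylo")) replicates <- list(replicates)
  if (length(replicates) == 0) abort("replicate set is empty")
  leaves <- sort(ml$tip.label)
  for (i in seq_along(replicates)) {
    if (!identical(sort(replicates[[i]]$tip.label), leaves)) {
      off <- c(setdiff(replicates[[i]]$tip.label, leaves),
               setdiff(leaves, replicates[[i]]$tip.label))
      abort(paste0("replicate ", i, " leaf set differs from ML tree: ",
                   paste(off, collapse = ", ")))
    }
  }
  if (is.null(leaf_to_genome)) {
    lg <- setNames(ml$tip.label, ml$tip.label)
  } else {
    if (is.data.frame(leaf_to_genome)) {
      keycol <- intersect(c("protein_id", "leaf"), names(leaf_to_genome))[1]
      if (is.na(keycol) || !"genome_id" %in% names(leaf_to_genome)) {
        abort("leaf map data frame needs columns protein_id (or leaf) and genome_id")
      }
      leaf_to_genome <- setNames(as.character(leaf_to_genome$genome_id),
                                 leaf_to_genome[[keycol]])
    }
    missing <- setdiff(ml$tip.label, names(leaf_to_genome))
    if (length(missing) > 0) {
      abort(paste0("leaf label(s) not resolvable to a genome: ",
                   paste(missing, collapse = ", ")))
    }
    lg <- leaf_to_genome[ml$tip.label]
  }
  ml <- normalize_gene_tree(ml)
  replicates <- lapply(replicates, function(t) {
    t$node.label <- NULL
    if (ape::is.rooted(t)) ape::unroot(t) else t
  })
  class(replicates) <- "multiPhylo"
  structure(
    list(ml = ml, replicates = replicates, leaf_genome = lg,
         n_replicates = length(replicates)),
    class = "gene_tree_set"
  )
}

#' @export
print.gene_tree_set <- function(x, ...) {
  cat("<gene_tree_set> ", length(x$ml$tip.label), " leaves, ",
      x$n_replicates, " bootstrap replicates, ",
      length(unique(x$leaf_genome)), " genomes\n", sep = "")
  invisible(x)
}

#' Read a gene tree set from Newick files
#'
#' @param ml_path Newick file with the ML tree (supports as internal node
#'   labels, either 0-100 or 0-1).
#' @param bootstrap_path Newick file with one replicate tree per line.
#' @inheritParams gene_tree_set
#' @return A [gene_tree_set()].
#' @export
read_tree_set <- function(ml_path, bootstrap_path, leaf_to_genome = NULL) {
  ml <- ape::read.tree(ml_path)
  if (is.null(ml)) abort(paste0("could not parse ML tree from ", ml_path))
  reps <- ape::read.tree(bootstrap_path)
  if (is.null(reps)) abort(paste0("empty or unparsable replicate file: ", bootstrap_path))
  if (inherits(reps, "phylo")) reps <- list(reps)
  gene_tree_set(ml, reps, leaf_to_genome)
}

#' Write a gene tree set to Newick files
#'
#' @param x A `gene_tree_set`.
#' @param ml_path,bootstrap_path Output paths.
#' @return `ml_path`, invisibly.
#' @export
write_tree_set <- function(x, ml_path, bootstrap_path) {
  ape::write.tree(x$ml, ml_path)
  ape::write.tree(x$replicates, bootstrap_path)
  invisible(ml_path)
}
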