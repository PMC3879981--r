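# Ground-truth synthetic datasets: a three-genome focal clade ((A',H')S')
# inside a fixed backbone phylogeny with partner lineages R', E', T' and a
# pool of unaffiliated "other" genomes.  Families are species-tree prunings
# with optional planted single-leaf LGT regrafts; pairwise e-values derive
# from patristic distances, and bootstrap replicates are NNI perturbations
# of the true gene tree.

COG_LETTERS <- c("J", "K", "L", "D", "V", "T", "M", "N", "U", "O", "C",
                 "G", "E", "F", "H", "I", "P", "Q", "R", "S", "W")

#' Configuration for the synthetic-data generator
#'
#' Defaults describe a desk-scale analogue of a broad prokaryotic genome
#' panel: a 3-genome focal clade, partner lineages of 8 (R'), 6 (E') and 4
#' (T') genomes plus 10 unaffiliated genomes, family pattern frequencies
#' that mirror a core gene set dominated by widely shared (RET-like)
#' profiles, and 100 bootstrap replicates per family.
#'
#' @param seed Integer RNG seed; the whole dataset is deterministic given it.
#' @param group_sizes Named counts for `FOCAL`, `R`, `E`, `T`, `OTHER`
#'   (`FOCAL` must be 3).
#' @param n_families Number of gene families to simulate.
#' @param pattern_freqs Named probabilities over the pattern categories
#'   `RET, ET, RE, RT, R, E, T, Other, FocalOnly`; must sum to 1.
#' @param p_lgt Probability that a family carries one planted LGT event
#'   (a focal leaf regrafted into a donor lineage).
#' @param lgt_donor_weights Named sampling weights for the donor lineage.
#' @param evalue_intercept,evalue_slope,evalue_sd E-value model:
#'   `log10 e = intercept + slope * d + N(0, sd)` for patristic distance
#'   `d`, clipped to `[1e-180, 10]`.  The positive slope makes e-values
#'   increase with distance.
#' @param present_prob Inclusion probability per partner genome when its
#'   lineage is named in the sampled pattern (at least one is forced).
#' @param n_bootstrap Number of bootstrap replicate topologies per family.
#' @param bootstrap_perturb Per-internal-edge probability of an NNI move
#'   when generating each replicate (0 = identical topologies).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       group_sizes = c(FOCAL = 3L, R = 8L, E = 6L, T = 4L,
                                       OTHER = 10L),
                       n_families = 100L,
                       pattern_freqs = c(RET = 0.43, ET = 0.23, E = 0.07,
                                         T = 0.03, RE = 0.05, RT = 0.03,
                                         R = 0.04, Other = 0.10,
                                         FocalOnly = 0.02),
                       p_lgt = 0.1,
                       lgt_donor_weights = c(R = 1, E = 1, T = 1, OTHER = 1),
                       evalue_intercept = -130, evalue_slope = 55,
                       evalue_sd = 0.25,
                       present_prob = 0.6,
                       n_bootstrap = 100L, bootstrap_perturb = 0.05) {
  need <- c("FOCAL", "R", "E", "T", "OTHER")
  if (!all(need %in% names(group_sizes))) {
    abort(paste0("group_sizes needs entries ", paste(need, collapse = ", ")))
  }
  if (group_sizes[["FOCAL"]] != 3) abort("the focal clade has exactly 3 genomes")
  if (any(group_sizes[c("R", "E", "T", "OTHER")] < 1)) {
    abort("every partner lineage needs at least one genome")
  }
  if (abs(sum(pattern_freqs) - 1) > 1e-9) {
    abort("pattern_freqs must sum to 1")
  }
  if (any(pattern_freqs < 0) || p_lgt < 0 || p_lgt > 1 ||
      bootstrap_perturb < 0 || bootstrap_perturb > 1 ||
      present_prob <= 0 || present_prob > 1) {
    abort("probabilities must lie in [0, 1]")
  }
  bad <- setdiff(names(pattern_freqs),
                 c("RET", "RE", "RT", "ET", "R", "E", "T", "Other", "FocalOnly"))
  if (length(bad) > 0) {
    abort(paste0("unknown pattern categories: ", paste(bad, collapse = ", ")))
  }
  if (n_bootstrap < 1) abort("n_bootstrap must be >= 1")
  if (evalue_sd < 0) abort("evalue_sd must be >= 0")
  structure(list(
    seed = as.integer(seed), group_sizes = group_sizes,
    n_families = as.integer(n_families), pattern_freqs = pattern_freqs,
    p_lgt = p_lgt, lgt_donor_weights = lgt_donor_weights,
    evalue_intercept = evalue_intercept, evalue_slope = evalue_slope,
    evalue_sd = evalue_sd, present_prob = present_prob,
    n_bootstrap = as.integer(n_bootstrap),
    bootstrap_perturb = bootstrap_perturb
  ), class = "sim_config")
}

# newick fragment for a lineage block: a rake of leaves on a stem, or a
# single leaf with the stem folded into its pendant edge
rake_str <- function(labels, pendants, stem, inner = NULL) {
  parts <- sprintf("%s:%.4f", labels, pendants)
  if (!is.null(inner)) parts <- c(parts, inner)
  if (length(parts) == 1 && is.null(inner)) {
    return(sprintf("%s:%.4f", labels, pendants + stem))
  }
  sprintf("(%s):%.4f", paste(parts, collapse = ","), stem)
}

# The fixed reference (species) tree.  The sister lineage E' attaches its
# leaves directly at the focal clade's node so that its nearest-leaf
# internal-edge distance to the focal clan is strictly smaller than any
# other lineage's, for every pruned family.
build_species_tree <- function(genomes) {
  foc <- "((Aq:0.0800,Hb:0.0900):0.0600,Sh:0.1200):0.1500"
  e_parts <- sprintf("%s:%.4f", genomes$E, 0.40 + 0.01 * seq_along(genomes$E))
  o_blk <- rake_str(genomes$OTHER, 0.30 + 0.01 * seq_along(genomes$OTHER), 0.25)
  r_blk <- rake_str(genomes$R, 0.32 + 0.01 * seq_along(genomes$R), 0.25,
                    inner = o_blk)
  t_blk <- rake_str(genomes$T, 0.35 + 0.01 * seq_along(genomes$T), 0.25,
                    inner = r_blk)
  nwk <- sprintf("(%s,%s,%s);", foc, paste(e_parts, collapse = ","), t_blk)
  ape::read.tree(text = nwk)
}

sim_genomes <- function(group_sizes) {
  list(
    FOCAL = c("Aq", "Hb", "Sh"),
    R = sprintf("R%02d", seq_len(group_sizes[["R"]])),
    E = sprintf("E%02d", seq_len(group_sizes[["E"]])),
    T = sprintf("T%02d", seq_len(group_sizes[["T"]])),
    OTHER = sprintf("O%02d", seq_len(group_sizes[["OTHER"]]))
  )
}

sim_taxonomy <- function(genomes) {
  rows <- list(
    tibble(genome_id = genomes$FOCAL, domain = "Bacteria", phylum = "Aquificae",
           class_name = "Aquificae",
           genus = c("Aquifex", "Hydrogenobaculum", "Sulfurihydrogenibium"),
           temp_class = "hyperthermophile"),
    tibble(genome_id = genomes$R, domain = "Archaea", phylum = "Euryarchaeota",
           class_name = "Methanococci",
           genus = ifelse(seq_along(genomes$R) <= 3, "Methanogenus",
                          paste0("Rgenus", seq_along(genomes$R))),
           temp_class = "hyperthermophile"),
    tibble(genome_id = genomes$E, domain = "Bacteria", phylum = "Proteobacteria",
           class_name = "Epsilonproteobacteria",
           genus = paste0("Egenus", seq_along(genomes$E)),
           temp_class = rep_len(c("thermophile", "mesophile"), length(genomes$E))),
    tibble(genome_id = genomes$T, domain = "Bacteria", phylum = "Thermotogae",
           class_name = "Thermotogae",
           genus = paste0("Tgenus", seq_along(genomes$T)),
           temp_class = "thermophile"),
    tibble(genome_id = genomes$OTHER, domain = "Bacteria", phylum = "Firmicutes",
           class_name = "Clostridia",
           genus = paste0("Ogenus", seq_along(genomes$OTHER)),
           temp_class = "mesophile")
  )
  list_rbind(rows)
}

# sample a non-empty subset of a lineage's genomes
sample_present <- function(members, prob) {
  sel <- runif(length(members)) < prob
  if (!any(sel)) sel[sample.int(length(members), 1)] <- TRUE
  members[sel]
}

#' Simulate a ground-truth phylogenomic dataset
#'
#' Generates, per family: a pattern category, the present genomes, the true
#' gene tree (the reference tree pruned to the present genomes, with an
#' optional planted LGT regraft of one focal leaf into a donor lineage),
#' bootstrap replicate topologies, focal-query similarity hits derived from
#' patristic distances through the e-value model, and functional
#' annotations.  The truth table records what the analysis should recover.
#'
#' @param config A [sim_config()].
#' @return A list of class `clanprof_sim` with elements `taxonomy`,
#'   `groups` (focal + R/E/T group table), `lineages` (genome to lineage,
#'   including OTHER), `proteins` (protein to genome/family), `hits`,
#'   `families` (tibble with `tree_set` list-column), `annotations` (list of
#'   `direct_map`, `hit_annotations`, `go_annotations`), `truth`, `config`.
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) abort("`config` must come from sim_config()")
  set.seed(config$seed)
  genomes <- sim_genomes(config$group_sizes)
  taxonomy <- sim_taxonomy(genomes)
  species <- build_species_tree(genomes)
  groups <- group_def(
    FOCAL = c(A = "Aq", H = "Hb", S = "Sh"),
    R = genomes$R, E = genomes$E, T = genomes$T
  )
  lineages <- tibble(
    genome_id = unlist(genomes, use.names = FALSE),
    lineage = rep(names(genomes), lengths(genomes))
  )
  lineage_of <- setNames(lineages$lineage, lineages$genome_id)

  cats <- names(config$pattern_freqs)
  fam_ids <- sprintf("f%04d", seq_len(config$n_families))
  patterns <- sample(cats, config$n_families, replace = TRUE,
                     prob = config$pattern_freqs)

  fam_rows <- vector("list", config$n_families)
  hit_rows <- vector("list", config$n_families)
  prot_rows <- vector("list", config$n_families)
  truth_rows <- vector("list", config$n_families)
  dmap_rows <- list(); ann_rows <- list(); go_rows <- list()

  for (i in seq_len(config$n_families)) {
    fam <- fam_ids[i]
    pat <- patterns[i]
    present <- genomes$FOCAL
    if (pat == "Other") {
      present <- c(present, sample_present(genomes$OTHER, config$present_prob))
    } else if (pat != "FocalOnly") {
      for (g in strsplit(pat, "")[[1]]) {
        present <- c(present, sample_present(genomes[[g]], config$present_prob))
      }
    }
    tree <- prune_to_taxa(species, present)

    lgt_ev <- NULL
    if (config$p_lgt > 0 && runif(1) < config$p_lgt) {
      donor_lin <- intersect(names(config$lgt_donor_weights),
                             unique(lineage_of[setdiff(present, genomes$FOCAL)]))
      if (length(donor_lin) > 0) {
        w <- config$lgt_donor_weights[donor_lin]
        dl <- if (length(donor_lin) == 1) donor_lin else
          sample(donor_lin, 1, prob = w)
        cand <- intersect(present, genomes[[dl]])
        donor <- cand[sample.int(length(cand), 1)]
        recipient <- sample(genomes$FOCAL, 1)
        tree <- regraft_leaf(tree, recipient, donor)
        lgt_ev <- list(donor_lineage = dl, donor = donor, recipient = recipient)
      }
    }

    prot <- setNames(sprintf("%s_%s", present, fam), present)
    tree$tip.label <- unname(prot[tree$tip.label])
    leaf_genome <- setNames(names(prot), unname(prot))

    reps <- sim_replicates(tree, config$n_bootstrap, config$bootstrap_perturb)
    ml <- attach_supports(tree, reps, config$bootstrap_perturb)
    ts <- gene_tree_set(ml, reps, leaf_genome)

    hit_rows[[i]] <- sim_hits(ml, leaf_genome, genomes$FOCAL, config)
    prot_rows[[i]] <- tibble(protein_id = unname(prot),
                             genome_id = names(prot), family_id = fam)

    cog <- sample(COG_LETTERS, 1)
    focal_prot <- prot[genomes$FOCAL]
    if (runif(1) < 0.7) {
      dmap_rows[[length(dmap_rows) + 1]] <-
        tibble(protein_id = unname(focal_prot["Aq"]), cog_category = cog)
    }
    nonfocal <- setdiff(unname(prot), unname(focal_prot))
    if (length(nonfocal) > 0) {
      ann <- nonfocal[runif(length(nonfocal)) < 0.9]
      if (length(ann) > 0) {
        ann_rows[[length(ann_rows) + 1]] <-
          tibble(protein_id = ann, cog_category = cog)
      }
    }
    go_rows[[length(go_rows) + 1]] <- tibble(
      protein_id = unname(focal_prot), go_term = sprintf("GO:%07d", i),
      evidence = "IDA", cog_category = cog
    )

    fam_rows[[i]] <- tibble(
      family_id = fam, pattern = pat, n_genomes = length(present),
      cog_category = cog, tree_set = list(ts)
    )
    truth_rows[[i]] <- tibble(
      family_id = fam, pattern = pat,
      lgt = !is.null(lgt_ev),
      lgt_donor_lineage = if (is.null(lgt_ev)) NA_character_ else lgt_ev$donor_lineage,
      lgt_donor = if (is.null(lgt_ev)) NA_character_ else lgt_ev$donor,
      lgt_recipient = if (is.null(lgt_ev)) NA_character_ else lgt_ev$recipient,
      cog_category = cog,
      expected_class = if (pat == "FocalOnly") "degenerate" else
        if (is.null(lgt_ev)) "clean" else "dirty",
      expected_cohesive = if (pat == "FocalOnly") NA else is.null(lgt_ev)
    )
  }

  structure(list(
    taxonomy = taxonomy, groups = groups, lineages = lineages,
    proteins = list_rbind(prot_rows),
    hits = list_rbind(hit_rows),
    families = list_rbind(fam_rows),
    annotations = list(
      direct_map = if (length(dmap_rows)) list_rbind(dmap_rows) else
        tibble(protein_id = character(), cog_category = character()),
      hit_annotations = if (length(ann_rows)) list_rbind(ann_rows) else
        tibble(protein_id = character(), cog_category = character()),
      go_annotations = list_rbind(go_rows)
    ),
    truth = list_rbind(truth_rows),
    config = config
  ), class = "clanprof_sim")
}

#' @export
print.clanprof_sim <- function(x, ...) {
  cat("<clanprof_sim> ", nrow(x$families), " families over ",
      nrow(x$taxonomy), " genomes; ", sum(x$truth$lgt),
      " planted LGT events; seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

# regraft `recipient` as the cherry partner of `donor` (single-gene LGT)
regraft_leaf <- function(tree, recipient, donor) {
  tr <- ape::drop.tip(tree, recipient)
  at <- which(tr$tip.label == donor)
  pend <- tr$edge.length[match(at, tr$edge[, 2])]
  tr <- phytools::bind.tip(tr, recipient, edge.length = pend / 2,
                           where = at, position = pend / 2)
  if (ape::is.rooted(tr)) tr <- ape::unroot(tr)
  tr
}

sim_replicates <- function(tree, n_bootstrap, perturb) {
  if (perturb == 0) return(rep(list(tree), n_bootstrap))
  n_internal <- nrow(tree$edge) - length(tree$tip.label)
  base <- if (ape::is.binary(tree)) tree else ape::multi2di(tree)
  lapply(seq_len(n_bootstrap), function(i) {
    m <- rbinom(1, max(n_internal, 1), perturb)
    if (m == 0) tree else phangorn::rNNI(base, moves = m)
  })
}

# bootstrap supports for the ML tree's internal edges, as node labels
attach_supports <- function(ml, reps, perturb) {
  sk <- split_keys(ml)
  nt <- sk$ntip
  tr <- sk$tree
  int <- which(sk$edge[, 2] > nt)
  lab <- rep(NA_real_, tr$Nnode)
  if (perturb == 0) {
    lab[sk$edge[int, 2] - nt] <- 100
  } else {
    lidx <- setNames(seq_along(sort(tr$tip.label)), sort(tr$tip.label))
    counts <- setNames(numeric(length(int)), sk$key[int])
    for (r in reps) {
      rk <- split_keys(r, lidx)$key
      hit <- names(counts) %in% rk
      counts[hit] <- counts[hit] + 1
    }
    lab[sk$edge[int, 2] - nt] <- round(100 * counts / length(reps), 1)
  }
  tr$node.label <- ifelse(is.na(lab), "", as.character(lab))
  tr
}

# focal-query hit rows from patristic distances through the e-value model
sim_hits <- function(ml, leaf_genome, focal_genomes, config) {
  D <- ape::cophenetic.phylo(ml)
  labs <- rownames(D)
  queries <- labs[leaf_genome[labs] %in% focal_genomes]
  q <- rep(queries, each = length(labs))
  s <- rep(labs, times = length(queries))
  d <- as.vector(t(D[queries, , drop = FALSE]))
  log10e <- config$evalue_intercept + config$evalue_slope * d
  if (config$evalue_sd > 0) {
    log10e <- log10e + rnorm(length(log10e), 0, config$evalue_sd)
  }
  log10e <- pmin(pmax(log10e, -180), 1)
  tibble(
    query_id = q, subject_id = s,
    evalue = 10^log10e,
    bitscore = pmax(0, round(-2 * log10e, 1))
  )
}
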