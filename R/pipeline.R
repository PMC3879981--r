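# End-to-end orchestration: simulate (or load) -> cluster -> profile ->
# classify -> tree statistics -> VPI -> affinity, with a manifest.

#' Pipeline configuration
#'
#' Bundles every tunable threshold of the pipeline with its default:
#' `e_bidir` (strict reciprocal-hit threshold, 1e-10), `e_member` (cluster
#' membership, 1e-5), `e_func` (functional majority vote, 1e-15), `trim`
#' (alignment-column confidence, 0.80), `min_support` (bootstrap pairing
#' threshold, 70), `balance_strong` (strong balance-of-support fraction,
#' 0.70).
#'
#' @param sim A [sim_config()] describing the synthetic input, or `NULL`
#'   when `data` (a ready `clanprof_sim`-shaped list) is passed to
#'   [run_pipeline()] instead.
#' @param e_bidir,e_member,e_func,trim,min_support,balance_strong Thresholds
#'   (see description).
#' @param balance_pairs List of 2-vectors of group codes to score against
#'   each other.
#' @param out_dir Optional directory; when given, stage outputs and a
#'   manifest are written as TSV.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), e_bidir = 1e-10,
                            e_member = 1e-5, e_func = 1e-15, trim = 0.80,
                            min_support = 70, balance_strong = 0.70,
                            balance_pairs = list(c("E", "T"), c("E", "R"),
                                                 c("T", "R")),
                            out_dir = NULL) {
  stopifnot(e_bidir > 0, e_member >= e_bidir, e_func > 0,
            trim >= 0, trim <= 1, min_support >= 0, min_support <= 100,
            balance_strong >= 0, balance_strong <= 1)
  structure(list(sim = sim, e_bidir = e_bidir, e_member = e_member,
                 e_func = e_func, trim = trim, min_support = min_support,
                 balance_strong = balance_strong,
                 balance_pairs = balance_pairs, out_dir = out_dir),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full affinity pipeline
#'
#' Stages: simulate (unless `data` is supplied), cluster, profile, classify,
#' treestats (cohesion, balance of support, supported pairings), vpi,
#' affinity.  Deterministic given the simulation seed and configuration.
#'
#' @param config A [pipeline_config()].
#' @param data Optional pre-built input list with the elements of a
#'   `clanprof_sim` (taxonomy, groups, lineages, proteins, hits, families,
#'   annotations); overrides `config$sim`.
#' @return A list of class `clanprof_report`: `clusters`, `profiles`,
#'   `classifications`, `summary`, `treestats`, `balance`, `vpi`,
#'   `affinity`, `manifest`, plus the `data` used.
#' @export
run_pipeline <- function(config = pipeline_config(), data = NULL) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must come from pipeline_config()")
  }
  if (is.null(data)) {
    if (is.null(config$sim)) abort("either config$sim or `data` is required")
    data <- run_stage("simulate", simulate_dataset(config$sim))
  }
  pmap_vec <- setNames(data$proteins$genome_id, data$proteins$protein_id)

  graph <- run_stage("cluster",
    build_focal_graph(data$hits, pmap_vec, data$groups, e_bidir = config$e_bidir))
  clusters <- run_stage("cluster",
    extract_clusters(graph, data$hits, pmap_vec, data$groups,
                     e_member = config$e_member))
  profiles <- run_stage("profile",
    build_profiles(clusters, pmap_vec, data$groups))
  classifications <- run_stage("classify",
    rank_and_classify(clusters, data$hits, pmap_vec, data$groups))
  summary_tbl <- run_stage("classify",
    profile_summary(profiles, classifications))

  # clusters back to simulated families via their seed protein
  fam_of_cluster <- setNames(data$proteins$family_id, data$proteins$protein_id)
  lineage_map <- setNames(data$lineages$lineage, data$lineages$genome_id)
  functions <- run_stage("functions",
    assign_function(clusters, data$hits,
                    direct_map = data$annotations$direct_map,
                    hit_annotations = data$annotations$hit_annotations,
                    go_annotations = data$annotations$go_annotations,
                    e_max = config$e_func))

  tree_tbl <- run_stage("treestats", {
    cl_fam <- unname(fam_of_cluster[clusters$seed_protein])
    idx <- match(cl_fam, data$families$family_id)
    tibble(
      cluster_id = clusters$cluster_id,
      family_id = cl_fam,
      category = data$families$cog_category[idx],
      tree_set = data$families$tree_set[idx]
    )
  })
  treestats <- run_stage("treestats", {
    fg <- group_members(as_group_tbl(data$groups), "FOCAL")
    tree_tbl |>
      mutate(
        cohesive = map_lgl(.data$tree_set, function(ts) {
          genomes_in <- unique(unname(ts$leaf_genome))
          if (length(setdiff(genomes_in, fg)) == 0) return(NA)
          is_cohesive(ts$ml, fg, ts$leaf_genome)
        }),
        pairing = map(.data$tree_set, pairing_support,
                      lineage_map = lineage_map, groups = data$groups,
                      min_support = config$min_support)
      ) |>
      select("cluster_id", "family_id", "category", "cohesive", "pairing")
  })
  balance <- run_stage("treestats", {
    list_rbind(map(config$balance_pairs, function(p) {
      rows <- map2(tree_tbl$cluster_id, tree_tbl$tree_set, function(id, ts) {
        genomes_in <- unique(unname(ts$leaf_genome))
        gx <- group_members(as_group_tbl(data$groups), p[1])
        gy <- group_members(as_group_tbl(data$groups), p[2])
        if (!any(gx %in% genomes_in) && !any(gy %in% genomes_in)) return(NULL)
        b <- balance_of_support(ts, p[1], p[2], data$groups,
                                strong_frac = config$balance_strong)
        b$cluster_id <- id
        b
      })
      list_rbind(discard(rows, is.null))
    }))
  })
  vpi <- run_stage("vpi", vpi_by_category(profiles, functions))
  affin <- run_stage("affinity",
    affinity_matrix(tree_tbl, lineage_map, data$groups,
                    min_support = config$min_support))

  report <- structure(list(
    clusters = clusters, profiles = profiles,
    classifications = classifications, summary = summary_tbl,
    functions = functions, treestats = treestats, balance = balance,
    vpi = vpi, affinity = affin, data = data, config = config
  ), class = "clanprof_report")
  report$manifest <- write_report(report, config$out_dir)
  report
}

# write stage outputs as TSV and return the manifest (also written)
write_report <- function(report, out_dir) {
  flat <- list(
    clusters = report$clusters |>
      mutate(members = map_chr(.data$members, paste, collapse = ","),
             focal_copies = map_chr(.data$focal_copies, function(x)
               paste(names(x), x, sep = ":", collapse = ","))),
    profiles = report$profiles |>
      mutate(present_genomes = map_chr(.data$present_genomes, paste,
                                       collapse = ",")),
    classifications = report$classifications |>
      select("cluster_id", "query_protein", "k", "n_subjects",
             "classification"),
    summary = report$summary,
    functions = report$functions,
    treestats = report$treestats |>
      mutate(pairing = map_chr(.data$pairing, paste, collapse = ",")),
    balance = report$balance,
    vpi = as_tibble(report$vpi),
    affinity = as_tibble(report$affinity)
  )
  manifest <- tibble(
    stage = names(flat),
    rows = map_int(flat, nrow),
    file = NA_character_, md5 = NA_character_
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(flat)) {
      f <- file.path(out_dir, paste0(names(flat)[i], ".tsv"))
      readr::write_tsv(flat[[i]], f, progress = FALSE)
      manifest$file[i] <- f
      manifest$md5[i] <- unname(tools::md5sum(f))
    }
    readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"),
                     progress = FALSE)
  }
  manifest
}

#' @export
print.clanprof_report <- function(x, ...) {
  cat("<clanprof_report>\n")
  cat("  clusters:       ", nrow(x$clusters), "\n")
  cat("  profiles:       ", nrow(x$profiles), "\n")
  cs <- table(x$classifications$classification)
  cat("  classifications:", paste(names(cs), as.integer(cs), collapse = ", "),
      "\n")
  cat("  cohesive trees: ", sum(x$treestats$cohesive, na.rm = TRUE), "/",
      sum(!is.na(x$treestats$cohesive)), "\n")
  invisible(x)
}
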