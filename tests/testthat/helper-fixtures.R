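# Small builders shared across the test files.  Everything is generated in
# code; no fixture files.

rt <- function(txt) ape::read.tree(text = txt)

toy_groups <- function(nR = 3, nE = 3, nT = 2) {
  group_def(
    FOCAL = c(A = "Aq", H = "Hb", S = "Sh"),
    R = sprintf("R%02d", seq_len(nR)),
    E = sprintf("E%02d", seq_len(nE)),
    T = sprintf("T%02d", seq_len(nT))
  )
}

# hit tibble from a compact spec: list of c(query, subject, evalue[, bits])
make_hits <- function(...) {
  rows <- list(...)
  tibble::tibble(
    query_id = vapply(rows, `[[`, "", 1),
    subject_id = vapply(rows, `[[`, "", 2),
    evalue = as.numeric(vapply(rows, `[[`, "", 3)),
    bitscore = vapply(rows, function(r) {
      if (length(r) >= 4) as.numeric(r[[4]]) else 50
    }, 0)
  )
}

# protein map tibble
pmap_tbl <- function(...) {
  v <- c(...)
  tibble::tibble(protein_id = names(v), genome_id = unname(v))
}

# a random unrooted binary tree with branch lengths, n leaves labelled t1..tn
random_tree <- function(n, labels = sprintf("t%02d", seq_len(n))) {
  tr <- ape::rtree(n, tip.label = labels)
  ape::unroot(tr)
}

# random profile tibble over named patterns
random_profiles <- function(n) {
  pats <- c("RET", "RE", "RT", "ET", "R", "E", "T", "")
  tibble::tibble(
    cluster_id = sprintf("C%04d", seq_len(n)),
    pattern = sample(pats, n, replace = TRUE),
    has_other = sample(c(TRUE, FALSE), n, replace = TRUE)
  ) |>
    dplyr::mutate(category = partition_pattern(
      tibble::tibble(pattern = pattern, has_other = has_other)))
}

# clusters tibble from a list of member vectors
clusters_tbl <- function(member_list, seeds = NULL) {
  tibble::tibble(
    cluster_id = sprintf("C%04d", seq_along(member_list)),
    seed_protein = seeds %||% vapply(member_list, `[`, "", 1),
    members = member_list
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
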