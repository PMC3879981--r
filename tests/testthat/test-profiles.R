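grp <- toy_groups()
pm_all <- pmap_tbl(a1 = "Aq", h1 = "Hb", s1 = "Sh",
                   e1 = "E01", e2 = "E02", t1 = "T01", r1 = "R01",
                   o1 = "Zeta1", o2 = "Zeta2")

test_that("profiles record focal subset, named pattern and other-lineage flag", {
  cl <- clusters_tbl(list(c("a1", "h1", "s1", "e1", "t1"), c("a1")))
  pr <- build_profiles(cl, pm_all, grp)
  expect_equal(pr$focal_subset, c("AHS", "A"))
  expect_equal(pr$pattern, c("ET", ""))
  expect_equal(pr$has_other, c(FALSE, FALSE))
  expect_equal(pr$category, c("ET", "FocalOnly"))
  expect_true(match_pattern(pr[1, ], "ET-ø"))

  expect_error(build_profiles(clusters_tbl(list(c("a1", "nope"))), pm_all, grp),
               "nope")
})

test_that("profile fields equal a direct set-membership oracle on random clusters", {
  set.seed(12)
  genomes <- c("Aq", "Hb", "Sh", sprintf("R%02d", 1:3), sprintf("E%02d", 1:3),
               sprintf("T%02d", 1:2), sprintf("Z%02d", 1:5))
  prots <- sprintf("p%03d", seq_along(genomes))
  pm <- pmap_tbl(setNames(genomes, prots))
  for (i in 1:50) {
    mem <- sample(prots, sample(2:10, 1))
    if (!any(pm$genome_id[match(mem, pm$protein_id)] %in% c("Aq", "Hb", "Sh"))) {
      mem <- c(mem, "p001")
    }
    pr <- build_profiles(clusters_tbl(list(unique(mem))), pm, grp)
    gg <- unique(pm$genome_id[match(unique(mem), pm$protein_id)])
    expect_setequal(pr$present_genomes[[1]], gg)
    expect_equal(pr$pattern, paste(c("R", "E", "T")[
      c(any(grepl("^R", gg)), any(grepl("^E", gg)), any(grepl("^T", gg)))],
      collapse = ""))
    expect_equal(pr$has_other, any(grepl("^Z", gg)))
  }
})

test_that("pattern categories cover the full case analysis exactly once", {
  pats <- c("RET", "RE", "RT", "ET", "R", "E", "T", "")
  for (p in pats) for (other in c(TRUE, FALSE)) {
    got <- partition_pattern(tibble::tibble(pattern = p, has_other = other))
    expect_equal(got, oracle_partition(p, other))
  }
  # exclusive and exhaustive over a random profile set
  prs <- random_profiles(200)
  expect_equal(sum(table(prs$category)), 200)
})

test_that("ø and * queries agree with set logic and ø implies *", {
  pr_ret <- tibble::tibble(pattern = "RET", has_other = FALSE)
  expect_true(match_pattern(pr_ret, "E-*"))
  expect_false(match_pattern(pr_ret, "E-ø"))
  pr_et_other <- tibble::tibble(pattern = "ET", has_other = TRUE)
  expect_false(match_pattern(pr_et_other, "ET-ø"))
  expect_true(match_pattern(pr_et_other, "ET-*"))
  expect_error(match_pattern(pr_ret, "ET"), "malformed")
  expect_error(match_pattern(pr_ret, "X-*", groups = toy_groups()), "unknown")

  set.seed(3)
  prs <- random_profiles(1000)
  queries <- as.vector(outer(c("R", "E", "T", "RE", "RT", "ET", "RET"),
                             c("*", "ø"), paste, sep = "-"))
  for (q in queries) {
    got <- match_pattern(prs, q)
    parts <- strsplit(q, "-")[[1]]
    want <- mapply(oracle_match, prs$pattern, prs$has_other,
                   MoreArgs = list(letters_wanted = strsplit(parts[1], "")[[1]],
                                   exclusive = parts[2] == "ø"))
    expect_equal(unname(got), unname(want))
    # exclusivity implies inclusivity
    expect_true(all(!got | match_pattern(prs, paste0(parts[1], "-*"))))
  }
})

test_that("ranked profiles are clean when focal proteins hold the top ranks", {
  cl <- clusters_tbl(list(c("a1", "h1", "s1", "e1", "t1", "r1", "o1")))
  clean_hits <- make_hits(
    c("a1", "h1", "1e-80"), c("a1", "s1", "1e-70"), c("a1", "e1", "1e-50"),
    c("a1", "t1", "1e-40"), c("a1", "r1", "1e-30"), c("a1", "o1", "1e-20"))
  rc <- rank_and_classify(cl, clean_hits, pm_all, grp)
  expect_equal(rc$classification, "clean")
  expect_equal(rc$focal_ranks[[1]], c(2L, 3L))
  expect_equal(rc$query_protein, "a1")
  expect_equal(rc$k, 2)

  dirty_hits <- make_hits(
    c("a1", "h1", "1e-80"), c("a1", "r1", "1e-75"), c("a1", "s1", "1e-70"),
    c("a1", "e1", "1e-50"), c("a1", "t1", "1e-40"), c("a1", "o1", "1e-20"))
  rc2 <- rank_and_classify(cl, dirty_hits, pm_all, grp)
  expect_equal(rc2$classification, "dirty")
  expect_equal(rc2$focal_ranks[[1]], c(2L, 4L))

  # focal-only cluster is degenerate
  rc3 <- rank_and_classify(clusters_tbl(list(c("a1", "h1"))),
                           clean_hits, pm_all, grp)
  expect_equal(rc3$classification, "degenerate")
})

test_that("classification is invariant to duplicate hits and equal-e-value permutations", {
  cl <- clusters_tbl(list(c("a1", "h1", "e1", "e2", "t1")))
  base <- make_hits(
    c("a1", "h1", "1e-60"), c("a1", "e1", "1e-30", 100),
    c("a1", "e2", "1e-30", 100), c("a1", "t1", "1e-20"))
  r1 <- rank_and_classify(cl, base, pm_all, grp)
  dup <- dplyr::bind_rows(base, base[3:4, ]) |> dedup_hits()
  r2 <- rank_and_classify(cl, dup, pm_all, grp)
  perm <- base[c(4, 3, 2, 1), ]
  r3 <- rank_and_classify(cl, perm, pm_all, grp)
  expect_equal(r1$classification, r2$classification)
  expect_equal(r1$classification, r3$classification)
  expect_equal(r1$focal_ranks, r3$focal_ranks)
})

test_that("random clusters agree with the brute-force ranking oracle", {
  set.seed(8)
  genomes <- c("Aq", "Hb", "Sh", sprintf("X%02d", 1:6))
  prots <- sprintf("p%02d", seq_along(genomes))
  pm <- pmap_tbl(setNames(genomes, prots))
  grp2 <- group_def(FOCAL = c(A = "Aq", H = "Hb", S = "Sh"),
                    E = sprintf("X%02d", 1:6))
  for (i in 1:100) {
    mem <- unique(c("p01", sample(prots, sample(3:8, 1))))
    hits <- tibble::tibble(
      query_id = "p01", subject_id = sample(setdiff(mem, "p01")),
      evalue = 10^sample(seq(-60, -10, by = 5), length(mem) - 1, replace = TRUE),
      bitscore = round(runif(length(mem) - 1, 30, 200), 1)
    )
    # drop some records so missing hits rank last
    hits <- hits[runif(nrow(hits)) < 0.8, ]
    got <- rank_and_classify(clusters_tbl(list(mem)), hits, pm, grp2)
    want <- oracle_rank_classify(mem, pm$genome_id[match(mem, pm$protein_id)],
                                 hits, c("Aq", "Hb", "Sh"))
    expect_equal(got$classification, want)
  }
})

test_that("summary percentages equal direct division at whole-number precision", {
  set.seed(15)
  n <- 120
  profiles <- tibble::tibble(
    cluster_id = sprintf("C%04d", 1:n),
    focal_subset = "AHS",
    pattern = sample(c("RET", "ET", "E", ""), n, replace = TRUE),
    has_other = FALSE
  )
  profiles$category <- partition_pattern(profiles)
  cls <- tibble::tibble(
    cluster_id = profiles$cluster_id,
    classification = ifelse(profiles$category == "FocalOnly", "degenerate",
                            sample(c("clean", "dirty"), n, replace = TRUE))
  )
  sm <- profile_summary(profiles, cls)
  for (i in seq_len(nrow(sm))) {
    den <- sm$n_total[i] - sm$n_degenerate[i]
    if (den > 0) {
      expect_equal(sm$pct_clean[i], floor(100 * sm$n_clean[i] / den + 0.5))
    }
  }
  expect_equal(sum(sm$n_total), n)
  expect_error(profile_summary(profiles, cls[-1, ]), "classification")
})
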