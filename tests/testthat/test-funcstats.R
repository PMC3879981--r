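grp <- toy_groups()
pm <- pmap_tbl(a1 = "Aq", h1 = "Hb", s1 = "Sh", e1 = "E01", t1 = "T01",
               r1 = "R01", x1 = "Zeta")

test_that("function assignment follows the four-step priority with tie fall-through", {
  cl <- clusters_tbl(list(c("a1", "h1", "e1", "t1")))
  hits <- make_hits(c("a1", "e1", "1e-20"), c("a1", "t1", "1e-18"),
                    c("h1", "e1", "1e-25"))
  direct <- tibble::tibble(protein_id = "a1", cog_category = "J")
  ann <- tibble::tibble(protein_id = c("e1", "t1"), cog_category = c("K", "K"))
  out <- assign_function(cl, hits, direct_map = direct, hit_annotations = ann)
  expect_equal(out$cog_category, "J")
  expect_equal(out$source, "direct_map")

  # no direct map: majority vote J:0 K:2 -> K
  out2 <- assign_function(cl, hits, hit_annotations = ann)
  expect_equal(out2$cog_category, "K")
  expect_equal(out2$source, "majority_vote")

  # vote tie falls through to GO
  ann_tie <- tibble::tibble(protein_id = c("e1", "t1"), cog_category = c("K", "J"))
  go <- tibble::tibble(protein_id = "h1", go_term = "GO:1", evidence = "IDA",
                       cog_category = "M")
  out3 <- assign_function(cl, hits, hit_annotations = ann_tie,
                          go_annotations = go)
  expect_equal(out3$cog_category, "M")
  expect_equal(out3$source, "go_map")

  # unverified GO evidence is ignored -> unknown/unassigned
  go_bad <- tibble::tibble(protein_id = "h1", go_term = "GO:1",
                           evidence = "IEA", cog_category = "M")
  out4 <- assign_function(cl, hits, hit_annotations = ann_tie,
                          go_annotations = go_bad)
  expect_equal(out4$cog_category, "unknown")
  expect_equal(out4$source, "unassigned")

  # the e-value ceiling excludes weak matches from the vote
  weak <- make_hits(c("a1", "e1", "1e-10"))
  out5 <- assign_function(cl, weak, hit_annotations = ann)
  expect_equal(out5$source, "unassigned")
  expect_error(assign_function(cl, hits, direct_map = tibble::tibble(x = 1)),
               "missing column")
})

test_that("majority vote equals a count-and-argmax oracle on random tables", {
  set.seed(27)
  subs <- sprintf("s%02d", 1:12)
  for (i in 1:40) {
    cl <- clusters_tbl(list(c("a1", sample(subs, sample(3:8, 1)))))
    hits <- tibble::tibble(query_id = "a1", subject_id = cl$members[[1]][-1],
                           evalue = 1e-20, bitscore = 100)
    ann <- tibble::tibble(protein_id = subs,
                          cog_category = sample(c("J", "K", "L"), 12,
                                                replace = TRUE))
    out <- assign_function(cl, hits, hit_annotations = ann)
    votes <- ann$cog_category[match(cl$members[[1]][-1], ann$protein_id)]
    tb <- sort(table(votes), decreasing = TRUE)
    if (length(tb) > 1 && tb[1] == tb[2]) {
      expect_equal(out$source, "unassigned")
    } else {
      expect_equal(out$cog_category, names(tb)[1])
    }
  }
})

test_that("the VPI worked example and its limits hold", {
  cats <- c(rep("E", 2), "RE", "ET", rep("RET", 4), rep("Other", 2),
            rep("FocalOnly", 3))
  v <- compute_vpi(cats, "E")
  expect_equal(v$numerator, 4)
  expect_equal(v$denominator, 10)
  expect_equal(v$vpi, 0.40)
  # all-RET profiles: ubiquitous presence contributes nothing
  for (g in c("R", "E", "T")) {
    expect_equal(compute_vpi(rep("RET", 8), g)$vpi, 0)
  }
  expect_error(compute_vpi(cats, "Q"), "invalid group")
  expect_warning(v0 <- compute_vpi(rep("FocalOnly", 3), "E"), "undefined")
  expect_true(is.na(v0$vpi))
})

test_that("VPI matches the formula oracle with bounds on random tables", {
  set.seed(14)
  cats_pool <- c("RET", "RE", "RT", "ET", "R", "E", "T", "Other", "FocalOnly")
  for (i in 1:200) {
    cats <- sample(cats_pool, sample(1:40, 1), replace = TRUE)
    vs <- vapply(c("R", "E", "T"), function(g) {
      suppressWarnings(compute_vpi(cats, g)$vpi)
    }, 0)
    want <- vapply(c("R", "E", "T"), function(g) oracle_vpi(cats, g), 0)
    expect_equal(vs, want)
    ok <- !is.na(vs)
    expect_true(all(vs[ok] >= 0 & vs[ok] <= 1))
    if (all(ok)) expect_lte(sum(vs), 2)
  }
})

test_that("VPI ignores focal-only profiles and never rises when RET is added", {
  set.seed(16)
  cats <- sample(c("RE", "E", "T", "Other"), 30, replace = TRUE)
  base <- compute_vpi(cats, "E")$vpi
  with_focal <- compute_vpi(c(cats, rep("FocalOnly", 10)), "E")$vpi
  expect_equal(with_focal, base)
  prev <- base
  for (add in c(1, 5, 20)) {
    cur <- compute_vpi(c(cats, rep("RET", add)), "E")$vpi
    expect_lte(cur, prev + 1e-12)
    prev <- cur
  }
})

test_that("the affinity matrix reports per-category pairing proportions", {
  lg <- c(A1 = "Aq", A2 = "Hb", E1 = "gE1", E2 = "gE2", T1 = "gT1", R1 = "gR1")
  grp2 <- group_def(FOCAL = c("Aq", "Hb"))
  lin <- c(Aq = "FOCAL", Hb = "FOCAL", gE1 = "E", gE2 = "E", gT1 = "T",
           gR1 = "R")
  paired <- rt("(((A1:1,A2:1)95:1,(E1:1,E2:1)90:1)95:1,T1:1,R1:1);")
  unpaired <- rt("(((A1:1,A2:1)95:1,(E1:1,E2:1)90:1)50:1,T1:1,R1:1);")
  tt <- tibble::tibble(
    category = c("J", "J"),
    tree_set = list(gene_tree_set(paired, list(paired), lg),
                    gene_tree_set(unpaired, list(unpaired), lg))
  )
  am <- affinity_matrix(tt, lin, grp2)
  expect_equal(am$prop[am$lineage == "E"], 0.5)
  expect_true(all(am$prop >= 0 & am$prop <= 1))
  # unattainable threshold: nothing pairs
  am0 <- affinity_matrix(tt, lin, grp2, min_support = 101)
  expect_true(all(am0$prop == 0))
  # one tree can credit several lineages: cells may sum above 1
  multi <- rt("(((A1:1,A2:1)95:1,(E1:1,T1:1)90:1)95:1,E2:1,R1:1);")
  tt2 <- tibble::tibble(category = "K",
                        tree_set = list(gene_tree_set(multi, list(multi), lg)))
  am2 <- affinity_matrix(tt2, lin, grp2)
  expect_gte(sum(am2$prop), 2)
})
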