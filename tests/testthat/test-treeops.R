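test_that("homogeneous clans are found exactly when the group is one split side", {
  t1 <- rt("((a1:1,a2:1):1,(x:1,y:1):1);")
  cl <- find_homogeneous_clan(t1, c("a1", "a2"))
  expect_s3_class(cl, "clan")
  expect_setequal(cl$tips, c("a1", "a2"))
  expect_true(is_cohesive(t1, c("a1", "a2")))

  t2 <- rt("((a1:1,x:1):1,(a2:1,y:1):1);")
  expect_null(find_homogeneous_clan(t2, c("a1", "a2")))
  expect_false(is_cohesive(t2, c("a1", "a2")))
  # single-leaf groups are cohesive by convention
  expect_true(is_cohesive(t2, "a1"))
  expect_error(find_homogeneous_clan(t1, c("zz1", "zz2")), "absent")
})

test_that("clan detection agrees with an edge-deletion oracle on random trees", {
  set.seed(19)
  for (i in 1:120) {
    n <- sample(5:14, 1)
    tr <- random_tree(n)
    g <- sample(tr$tip.label, sample(2:(n - 1), 1))
    got <- !is.null(find_homogeneous_clan(tr, g))
    expect_equal(got, oracle_is_clan(tr, g), label = paste("tree", i))
  }
})

test_that("clan distance counts intervening internal edges to the nearest leaf", {
  # x adjacent to the focal clan across a single node
  t1 <- rt("((a1:1,a2:1):1,x:1,(y:1,z:1):1);")
  cl <- find_homogeneous_clan(t1, c("a1", "a2"))
  expect_equal(clan_distance(cl, "x"), 0)
  expect_equal(clan_distance(cl, c("y", "z")), 1)
  # two internal edges away
  t2 <- rt("((a1:1,a2:1):1,w:1,(q:1,(x:1,v:1):1):1);")
  cl2 <- find_homogeneous_clan(t2, c("a1", "a2"))
  expect_equal(clan_distance(cl2, "x"), 2)
  expect_equal(clan_distance(cl2, "missing_leaf"), Inf)
  expect_error(clan_distance(list(), "x"), "clan")
})

test_that("clan distance equals the BFS path-count oracle on random trees", {
  set.seed(23)
  done <- 0
  while (done < 60) {
    n <- sample(6:12, 1)
    tr <- random_tree(n)
    g <- sample(tr$tip.label, sample(2:(n - 2), 1))
    cl <- find_homogeneous_clan(tr, g)
    if (is.null(cl)) next
    others <- setdiff(tr$tip.label, g)
    target <- sample(others, sample(seq_along(others), 1))
    expect_equal(clan_distance(cl, target),
                 oracle_clan_distance(tr, g, target))
    done <- done + 1
  }
})

make_ts <- function(ml, reps, lg) gene_tree_set(ml, reps, lg)

test_that("balance of support counts replicates for the closer group", {
  lg <- c(A1 = "Aq", A2 = "Hb", X1 = "X1", Y1 = "Y1", Z1 = "Z1")
  grp <- group_def(FOCAL = c("Aq", "Hb"), X = "X1", Y = "Y1")
  # x adjacent, y far, in every replicate
  tr <- rt("((A1:1,A2:1):1,X1:1,(Z1:1,Y1:1):1);")
  ts <- make_ts(tr, rep(list(tr), 10), lg)
  b <- balance_of_support(ts, "X", "Y", grp)
  expect_equal(b$score, 10)
  expect_true(b$strong)
  # equidistant: zero
  tr2 <- rt("((A1:1,A2:1):1,X1:1,Y1:1,Z1:1);")
  ts2 <- make_ts(tr2, rep(list(tr2), 10), lg)
  expect_equal(balance_of_support(ts2, "X", "Y", grp)$score, 0)
  # noncohesive replicates contribute nothing
  tr3 <- rt("((A1:1,X1:1):1,A2:1,(Z1:1,Y1:1):1);")
  ts3 <- make_ts(tr3, rep(list(tr3), 10), lg)
  expect_equal(balance_of_support(ts3, "X", "Y", grp)$score, 0)
})

test_that("balance is antisymmetric and bounded on random tree sets", {
  set.seed(31)
  genomes <- c("Aq", "Hb", "Sh", "X1", "X2", "Y1", "Y2", "Z1")
  grp <- group_def(FOCAL = c("Aq", "Hb", "Sh"), X = c("X1", "X2"),
                   Y = c("Y1", "Y2"))
  lg <- setNames(genomes, genomes)
  for (i in 1:60) {
    reps <- lapply(1:6, function(j) random_tree(8, labels = genomes))
    ts <- make_ts(reps[[1]], reps, lg)
    bxy <- balance_of_support(ts, "X", "Y", grp)
    byx <- balance_of_support(ts, "Y", "X", grp)
    expect_equal(bxy$score, -byx$score)
    expect_lte(abs(bxy$score), ts$n_replicates)
  }
})

test_that("supported pairings pick the smallest supported containing clan", {
  lg <- c(A1 = "Aq", A2 = "Hb", E1 = "gE1", E2 = "gE2", T1 = "gT1", R1 = "gR1")
  grp <- group_def(FOCAL = c("Aq", "Hb"))
  lin <- c(Aq = "FOCAL", Hb = "FOCAL", gE1 = "E", gE2 = "E",
           gT1 = "T", gR1 = "R")
  tr <- rt("(((A1:1,A2:1)95:1,(E1:1,E2:1)90:1)95:1,T1:1,R1:1);")
  ts <- make_ts(tr, list(tr), lg)
  expect_equal(pairing_support(ts, lin, grp, min_support = 70), "E")
  # below threshold: no pairing (the E-clade edge must fail too, or its
  # complement would count as a supported clan containing the focal clan)
  tr2 <- rt("(((A1:1,A2:1)95:1,(E1:1,E2:1)60:1)60:1,T1:1,R1:1);")
  ts2 <- make_ts(tr2, list(tr2), lg)
  expect_equal(pairing_support(ts2, lin, grp, min_support = 70), character(0))
  # unattainable threshold
  expect_equal(pairing_support(ts, lin, grp, min_support = 101), character(0))
  # noncohesive focal: no pairing
  tr3 <- rt("((A1:1,E1:1)95:1,(A2:1,E2:1)95:1,(T1:1,R1:1)95:1);")
  ts3 <- make_ts(tr3, list(tr3), lg)
  expect_equal(pairing_support(ts3, lin, grp, min_support = 70), character(0))
})

test_that("pairing is invariant to rooting of the input ML tree", {
  lg <- c(A1 = "Aq", A2 = "Hb", E1 = "gE1", E2 = "gE2", T1 = "gT1", R1 = "gR1")
  grp <- group_def(FOCAL = c("Aq", "Hb"))
  lin <- c(Aq = "FOCAL", Hb = "FOCAL", gE1 = "E", gE2 = "E",
           gT1 = "T", gR1 = "R")
  base <- rt("(((A1:1,A2:1)95:1,(E1:1,E2:1)90:1)95:1,T1:1,R1:1);")
  p0 <- pairing_support(make_ts(base, list(base), lg), lin, grp)
  rootings <- c(
    "(T1:1,(R1:1,((A1:1,A2:1)95:1,(E1:1,E2:1)90:1)95:1):1);",
    "(R1:1,(T1:1,((A1:1,A2:1)95:1,(E1:1,E2:1)90:1)95:1):1);",
    "(((T1:1,R1:1)95:1,(E1:1,E2:1)90:1):1,(A1:1,A2:1)95:1);"
  )
  for (nwk in rootings) {
    rr <- rt(nwk)
    pr <- pairing_support(make_ts(rr, list(rr), lg), lin, grp)
    expect_equal(pr, p0, label = nwk)
  }
})

test_that("genus reduction keeps one leaf from each side of the genus split", {
  gm <- c(g1 = "Gen", g2 = "Gen", g3 = "Gen", g4 = "Gen",
          u1 = "U", u2 = "V", u3 = "W")
  tr <- rt("(((g1:1,g2:1):1,(g3:1,g4:1):1):1,u1:1,(u2:1,u3:1):1);")
  kept <- genus_reduce(tr, gm)
  expect_setequal(setdiff(tr$tip.label, kept), c("g2", "g4"))
  # genus with only two leaves untouched
  gm2 <- c(g1 = "Gen", g2 = "Gen", u1 = "U", u2 = "V")
  tr2 <- rt("((g1:1,g2:1):1,u1:1,u2:1);")
  expect_setequal(genus_reduce(tr2, gm2), tr2$tip.label)
  # non-cohesive genus untouched
  gm3 <- c(g1 = "Gen", g2 = "Gen", g3 = "Gen", u1 = "U", u2 = "V")
  tr3 <- rt("((g1:1,u1:1):1,g2:1,(g3:1,u2:1):1);")
  expect_setequal(genus_reduce(tr3, gm3), tr3$tip.label)
})

test_that("in-paralog reduction keeps the shortest terminal branch per genome", {
  lg <- c(p1 = "G1", p2 = "G1", q1 = "G2", r1 = "G3")
  tr <- rt("((p1:0.1,p2:0.3):1,q1:0.2,r1:0.5);")
  expect_setequal(reduce_inparalogs(tr, lg), c("p1", "q1", "r1"))
  # all single-copy: identity
  tr2 <- rt("((p1:0.1,q1:0.3):1,r1:0.2,s1:0.5);")
  lg2 <- c(p1 = "G1", q1 = "G2", r1 = "G3", s1 = "G4")
  expect_setequal(reduce_inparalogs(tr2, lg2), tr2$tip.label)
  # ties break lexicographically; oracle check on random trees
  set.seed(44)
  for (i in 1:20) {
    tr <- random_tree(8)
    lg3 <- setNames(sample(c("GA", "GB", "GC"), 8, replace = TRUE),
                    tr$tip.label)
    kept <- reduce_inparalogs(tr, lg3)
    pend <- tr$edge.length[match(seq_len(8), tr$edge[, 2])]
    for (g in unique(lg3)) {
      ix <- which(lg3[tr$tip.label] == g)
      want <- tr$tip.label[ix][order(pend[ix], tr$tip.label[ix])][1]
      expect_equal(intersect(kept, tr$tip.label[ix]), want)
    }
  }
})

test_that("pruning gives the induced subtree with summed branch lengths", {
  tr <- rt("((a:1,b:2):3,(c:4,d:5):6);")
  pr <- prune_to_taxa(tr, c("a", "c", "d"))
  expect_setequal(pr$tip.label, c("a", "c", "d"))
  expect_equal(unname(ape::cophenetic.phylo(pr)["a", "c"]),
               unname(ape::cophenetic.phylo(tr)["a", "c"]))
  expect_equal(prune_to_taxa(tr, tr$tip.label)$tip.label, tr$tip.label)
  expect_error(prune_to_taxa(tr, c("a", "nope")), "nope")
})

test_that("supermatrix concatenation pads missing genomes and tracks partitions", {
  a1 <- conf_alignment(c(p1 = "AAAAA", p2 = "CCCCC"), rep(1, 5))
  a2 <- conf_alignment(c(p1 = "DDDDDDD", p3 = "EEEEEEE"), rep(0.9, 7))
  tx <- c(p1 = "G1", p2 = "G2", p3 = "G3")
  sm <- build_supermatrix(list(geneA = a1, geneB = a2), tx)
  expect_equal(nchar(sm$alignment$sequences[["G1"]]), 12)
  expect_equal(sm$partitions$start, c(1L, 6L))
  expect_equal(sm$partitions$end, c(5L, 12L))
  expect_equal(substr(sm$alignment$sequences[["G2"]], 6, 12), "-------")
  expect_equal(substr(sm$alignment$sequences[["G3"]], 1, 5), "-----")
  # duplicate genome within a gene is rejected with advice
  bad <- conf_alignment(c(p1 = "AA", p1b = "CC"), rep(1, 2))
  expect_error(build_supermatrix(list(g = bad), c(p1 = "G1", p1b = "G1")),
               "reduce_inparalogs")
  # column bookkeeping on random gene widths
  set.seed(2)
  widths <- sample(3:9, 5, replace = TRUE)
  alns <- lapply(widths, function(w) {
    conf_alignment(setNames(strrep("A", w), paste0("G", sample(3, 1))), rep(1, w))
  })
  names(alns) <- paste0("g", 1:5)
  sm2 <- build_supermatrix(alns)
  expect_equal(sm2$partitions$end - sm2$partitions$start + 1L, widths)
  expect_equal(max(sm2$partitions$end),
               nchar(sm2$alignment$sequences[[1]]))
})
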