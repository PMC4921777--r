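test_that("p and poisson distances implement pairwise deletion", {
  rec <- seq_records(c("a", "b", "c"), c("a", "b", "c"),
                     c("ACDEFGHIKL", "ACDEFGHIKL", "ACDEFGHIKL"))
  D <- distance_matrix(msa(rec))
  expect_true(all(D == 0))

  # rows differing at 3 of 10 comparable columns
  rec <- seq_records(c("a", "b", "c"),  c("a", "b", "c"),
                     c("ACDEFGHIKL", "ACDEFGHIKV", "YYYEFGHIKL"))
  D <- distance_matrix(msa(rec), model = "p")
  expect_equal(D["a", "c"], 0.3)
  Dp <- distance_matrix(msa(rec), model = "poisson")
  expect_equal(Dp["a", "c"], -log(1 - 0.3))

  set.seed(51)
  x <- random_gap_msa(5, 200)
  D <- distance_matrix(x, model = "p")
  chars <- do.call(rbind, strsplit(x$residues, ""))
  for (i in 1:4) for (j in (i + 1):5) {
    ok <- chars[i, ] != "-" & chars[j, ] != "-"
    expect_equal(D[i, j], sum(chars[i, ok] != chars[j, ok]) / sum(ok))
  }

  bad <- seq_records(c("a", "b", "c"), c("a", "b", "c"),
                     c("AC---", "---DE", "ACDEF"), aligned = TRUE)
  expect_error(distance_matrix(msa(bad)), "no comparable columns for pair a / b")
})

test_that("neighbor joining inverts the hand-worked additive 4-taxon matrix", {
  taxa <- c("A", "B", "C", "D")
  D <- matrix(c(0, 3, 5, 3,
                3, 0, 6, 4,
                5, 6, 0, 4,
                3, 4, 4, 0), 4, 4, dimnames = list(taxa, taxa))
  tr <- neighbor_joining(D)
  # topology AB|CD
  ref <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:1);")
  expect_equal(rf_distance(tr, ref), 0L)
  # exact branch lengths: tip edges 1,2,3,1 and one internal edge of 1
  tip_edges <- setNames(
    tr$edge.length[match(seq_along(taxa), tr$edge[, 2])][match(taxa, tr$tip.label)],
    taxa)
  expect_equal(unname(tip_edges), c(1, 2, 3, 1))
  internal <- tr$edge.length[tr$edge[, 2] > length(taxa)]
  expect_equal(internal, 1)
})

test_that("3-taxon trees use the closed-form three-point lengths", {
  taxa <- c("a", "b", "c")
  D <- matrix(c(0, 2, 3,
                2, 0, 4,
                3, 4, 0), 3, 3, dimnames = list(taxa, taxa))
  tr <- neighbor_joining(D)
  len <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(len[taxa]), c(0.5, 1.5, 2.5))
})

test_that("NJ recovers simulated additive topologies exactly", {
  set.seed(52)
  for (k in 1:60) {
    tr <- simulate_tree(8)
    D <- tree_distances(tr)
    # verify additivity via a four-point-condition spot check
    q <- sample(rownames(D), 4)
    sums <- c(D[q[1], q[2]] + D[q[3], q[4]],
              D[q[1], q[3]] + D[q[2], q[4]],
              D[q[1], q[4]] + D[q[2], q[3]])
    expect_lt(sort(sums, decreasing = TRUE)[1] -
                sort(sums, decreasing = TRUE)[2], 1e-8)
    nj <- suppressMessages(neighbor_joining(D))
    expect_equal(rf_distance(nj, tr), 0L)
  }
})

test_that("midpoint rooting balances the two farthest leaves", {
  # symmetric quartet: root lands mid central edge
  tr <- ape::read.tree(text = "((A:1,B:1):0.5,(C:1,D:1):0.5);")
  r <- midpoint_root(ape::unroot(tr))
  d <- ape::node.depth.edgelength(r)
  expect_equal(max(d[1:4]) - min(d[1:4]), 0, tolerance = 1e-9)

  # caterpillar with distinct lengths: leaf-to-leaf paths are
  # AB 3, AC 8, AD 6, BC 9, BD 7, CD 10 -> diameter C-D, midpoint 5 from each
  cat_tree <- ape::read.tree(text = "(((A:1,B:2):1,C:6):1,D:3);")
  r <- midpoint_root(ape::unroot(cat_tree))
  d <- setNames(ape::node.depth.edgelength(r)[1:4], r$tip.label)
  expect_equal(unname(d["C"]), 5, tolerance = 1e-9)
  expect_equal(unname(d["D"]), 5, tolerance = 1e-9)

  # idempotence
  r2 <- midpoint_root(r)
  expect_equal(rf_distance(r, r2), 0L)
  expect_equal(sort(ape::node.depth.edgelength(r2)[1:4]),
               sort(ape::node.depth.edgelength(r)[1:4]), tolerance = 1e-9)

  zero <- ape::read.tree(text = "((A:0,B:0):0,C:0,D:0);")
  expect_error(midpoint_root(zero), "all branch lengths are zero")
})

test_that("bootstrap supports are reproducible and saturate on clean signal", {
  tr <- ape::read.tree(
    text = "((a:0.2,b:0.2):0.25,(c:0.2,d:0.2):0.25,(e:0.2,f:0.2):0.25);")
  set.seed(53)
  seqs <- evolve_family(ape::root(tr, outgroup = "a", resolve.root = TRUE),
                        400, rate = 1)
  rec <- seq_records(names(seqs), names(seqs), unname(seqs))
  bs <- bootstrap_support(msa(rec), replicates = 100, seed = 99)
  expect_true(all(bs$node.label >= 0 & bs$node.label <= 1))
  # non-trivial bipartitions of the generating tree
  nontrivial <- bs$node.label[-1]
  expect_true(all(nontrivial >= 0.9))
  expect_equal(rf_distance(bs, tr), 0L)

  bs2 <- bootstrap_support(msa(rec), replicates = 100, seed = 99)
  expect_identical(bs$node.label, bs2$node.label)

  bs1 <- bootstrap_support(msa(rec), replicates = 1, seed = 1)
  expect_true(all(bs1$node.label %in% c(0, 1)))
})

test_that("leaf sets survive rooting and bootstrap annotation", {
  set.seed(54)
  tr <- simulate_tree(10)
  seqs <- evolve_family(tr, 150, rate = 0.4)
  rec <- seq_records(names(seqs), names(seqs), unname(seqs))
  bs <- bootstrap_support(msa(rec), replicates = 5, seed = 3)
  expect_setequal(bs$tip.label, tr$tip.label)
  expect_setequal(midpoint_root(bs)$tip.label, tr$tip.label)
})

test_that("RF distance equals the brute-force bipartition count", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(rf_distance(t1, t1), 0L)
  expect_equal(rf_distance(t1, t2), 2L)
  expect_error(rf_distance(t1, ape::read.tree(text = "((A,B),(C,E));")),
               "different leaf sets")

  set.seed(55)
  for (k in 1:25) {
    a <- simulate_tree(8)
    b <- simulate_tree(8)
    b$tip.label <- sample(a$tip.label)
    expect_equal(rf_distance(a, b), rf_oracle(a, b), info = paste("pair", k))
  }
})
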