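test_that("molecular-characteristics distance is plain Euclidean", {
  props <- data.frame(peak_id = c("a", "b"),
                      C = c(6, 9), H = c(6, 6), N = 0, O = 0, S = 0, P = 0,
                      DBE = 4, AImod = 0.5, kdef = 0.1)
  d <- mcd_distance(props)
  expect_equal(d["a", "b"], 3)
  expect_equal(diag(d), c(a = 0, b = 0))

  u <- gen_formula_universe(12, seed = 51)
  pr <- compute_properties(u)
  d2 <- mcd_distance(pr)
  cols <- c("C", "H", "N", "O", "S", "P", "DBE", "AImod", "kdef")
  brute <- outer(seq_len(12), seq_len(12), Vectorize(function(i, j) {
    sqrt(sum((unlist(pr[i, cols]) - unlist(pr[j, cols]))^2))
  }))
  expect_equal(unname(d2), brute, tolerance = 1e-12)

  pr$DBE[3] <- NaN
  expect_error(mcd_distance(pr), pr$peak_id[3])
})

test_that("transformation distance is hop count standardised to [0, 1]", {
  db <- data.frame(name = "t", mass = 10)
  net <- match_transformations(c(A = 100, B = 110, C = 120), db,
                               "absolute", 1e-6)
  td <- td_distance(net)
  expect_equal(td["A", "B"], 0.5)
  expect_equal(td["A", "C"], 1.0)
  expect_equal(td["B", "C"], 0.5)

  # star: all leaf-leaf distances equal after standardisation
  star <- match_transformations(c(hub = 100, l1 = 110, l2 = 90, l3 = 85),
                                data.frame(name = c("t", "u"),
                                           mass = c(10, 15)),
                                "absolute", 1e-6)
  tds <- td_distance(star)
  leaves <- c("l1", "l2", "l3")
  offdiag <- tds[leaves, leaves][lower.tri(matrix(0, 3, 3))]
  expect_true(all(offdiag == 1))

  # two components: only the largest is kept
  two <- match_transformations(
    c(a = 100, b = 110, c = 120, d = 130, e = 140, x = 500, y = 510, z = 520),
    db, "absolute", 1e-6)
  td2 <- td_distance(two)
  expect_identical(sort(rownames(td2)), c("a", "b", "c", "d", "e"))
  expect_equal(max(td2), 1)
})

test_that("TWCD is the entrywise product and down-weights the MCD", {
  ids <- c("a", "b", "c")
  mcd <- matrix(c(0, 3, 6, 3, 0, 2, 6, 2, 0), 3,
                dimnames = list(ids, ids))
  td <- matrix(c(0, 0.5, 1, 0.5, 0, 1, 1, 1, 0), 3,
               dimnames = list(ids, ids))
  tw <- twcd_distance(mcd, td)
  expect_equal(tw["a", "b"], 1.5)
  expect_equal(diag(tw), c(a = 0, b = 0, c = 0))
  ones <- td; ones[] <- 1; diag(ones) <- 0
  expect_equal(twcd_distance(mcd, ones)[ids, ids], mcd * (1 - diag(3)))
  expect_true(all(tw <= mcd))
  expect_error(twcd_distance(mcd, td[1:2, 1:2]), "fewer than 3")
})

test_that("UPGMA reproduces the hand example and the textbook oracle", {
  tr <- upgma(t1_distance())
  cp <- cophenetic(tr)
  expect_equal(cp["A", "B"], 2)
  expect_equal(cp["A", "C"], 4)
  expect_equal(cp["B", "C"], 4)
  # node height of the A,B merge is half the merge distance
  expect_true(ape::is.ultrametric(tr))

  for (seed in c(61, 62, 63)) {
    d <- random_distance(6, seed)
    got <- cophenetic(upgma(d))
    want <- oracle_upgma_cophenetic(d)
    expect_equal(got[rownames(want), colnames(want)], want, tolerance = 1e-10)
  }

  bad <- t1_distance(); bad[1, 2] <- 99
  expect_error(upgma(bad), "symmetric")
})

test_that("UPGMA trees are ultrametric: top two triple distances tie", {
  d <- random_distance(10, 71)
  cp <- cophenetic(upgma(d))
  ids <- rownames(cp)
  for (tri in combn(ids, 3, simplify = FALSE)) {
    v <- sort(c(cp[tri[1], tri[2]], cp[tri[1], tri[3]], cp[tri[2], tri[3]]))
    expect_equal(v[2], v[3], tolerance = 1e-9)
  }
})

test_that("pruning preserves cophenetic distances among kept leaves", {
  tr <- upgma(t1_distance())
  pr <- prune_dendrogram(tr, c("A", "B"))
  expect_equal(cophenetic(pr)["A", "B"], 2)

  d <- random_distance(9, 81)
  tr2 <- upgma(d)
  keep <- rownames(d)[c(1, 3, 5, 8)]
  pr2 <- prune_dendrogram(tr2, keep)
  expect_equal(cophenetic(pr2)[keep, keep], cophenetic(tr2)[keep, keep],
               tolerance = 1e-10)
  # pruning to all leaves is the identity on cophenetic distances
  all_pr <- prune_dendrogram(tr2, rownames(d))
  expect_equal(cophenetic(all_pr)[rownames(d), rownames(d)],
               cophenetic(tr2)[rownames(d), rownames(d)], tolerance = 1e-12)

  expect_error(prune_dendrogram(tr, c("A", "Z")), "unknown")
  expect_error(prune_dendrogram(tr, "A"), "at least 2")
})

test_that("dendrograms round-trip through Newick", {
  d <- random_distance(7, 91)
  tr <- upgma(d)
  path <- tempfile(fileext = ".nwk")
  write_newick(tr, path)
  back <- read_newick(path)
  expect_setequal(back$tip.label, tr$tip.label)
  ids <- tr$tip.label
  expect_equal(cophenetic(back)[ids, ids], cophenetic(tr)[ids, ids],
               tolerance = 1e-6)
})
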