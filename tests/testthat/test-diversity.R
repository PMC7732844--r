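t1_setup <- function() {
  tr <- upgma(t1_distance())
  m <- rbind(s1 = c(A = 1, B = 1, C = 0),
             s2 = c(A = 0, B = 0, C = 1),
             s3 = c(A = 1, B = 1, C = 1),
             s4 = c(A = 1, B = 0, C = 0))
  list(tree = tr, m = m, d = cophenetic(tr))
}

test_that("richness is the per-sample detection count", {
  f <- t1_setup()
  expect_identical(unname(richness(f$m)), c(2, 1, 3, 1))
  expect_identical(unname(richness(rbind(a = c(0, 0, 0)))), 0)
})

test_that("dendrogram diversity sums the spanning subtree branch lengths", {
  f <- t1_setup()
  dd <- dendrogram_diversity(f$m, f$tree)
  # hand: leaves A and B (length 1 each) plus their stem (1) = 3
  expect_equal(unname(dd["s1"]), 3)
  # whole tree: 1 + 1 + 1 + 2 = 5
  expect_equal(unname(dd["s3"]), 5)
  # single leaf with root: its root path, 1 + 1 = 2
  expect_equal(unname(dd["s4"]), 2)
  # without the root path, {A, B} spans only the two leaf branches
  dd_nr <- dendrogram_diversity(f$m, f$tree, include_root = FALSE)
  expect_equal(unname(dd_nr["s1"]), 2)
})

test_that("dendrogram diversity matches an independent reference (picante)", {
  skip_if_not_installed("picante")
  d <- random_distance(12, 101)
  tr <- upgma(d)
  m <- random_assemblage(6, 12, seed = 102)
  colnames(m) <- rownames(d)
  got <- dendrogram_diversity(m, tr)
  want <- picante::pd(m, tr, include.root = TRUE)$PD
  expect_equal(unname(got), want, tolerance = 1e-10)
  got_nr <- dendrogram_diversity(m, tr, include_root = FALSE)
  want_nr <- picante::pd(m, tr, include.root = FALSE)$PD
  expect_equal(unname(got_nr), want_nr, tolerance = 1e-10)
  # and against the in-house root-path oracle
  for (k in seq_len(nrow(m))) {
    present <- colnames(m)[m[k, ] > 0]
    expect_equal(unname(got[k]), oracle_dd(tr, present), tolerance = 1e-10)
  }
})

test_that("MPD and MNTD agree with hand values and the brute-force oracle", {
  f <- t1_setup()
  expect_equal(unname(mpd(f$m, f$d)["s1"]), 2)            # single pair
  expect_equal(unname(mpd(f$m, f$d)["s3"]), (2 + 4 + 4) / 3, tolerance = 1e-3)
  expect_true(is.na(mpd(f$m, f$d)["s4"]))
  expect_equal(unname(mntd(f$m, f$d)["s3"]), (2 + 2 + 4) / 3, tolerance = 1e-3)

  d <- random_distance(10, 111)
  m <- random_assemblage(5, 10, seed = 112)
  colnames(m) <- rownames(d)
  got_mpd <- mpd(m, d); got_mntd <- mntd(m, d)
  for (k in seq_len(nrow(m))) {
    present <- colnames(m)[m[k, ] > 0]
    expect_equal(unname(got_mpd[k]), oracle_mpd(d, present), tolerance = 1e-10)
    expect_equal(unname(got_mntd[k]), oracle_mntd(d, present),
                 tolerance = 1e-10)
    expect_lte(got_mntd[k], got_mpd[k])
  }
})

test_that("Jaccard dissimilarity follows the set definition", {
  m <- rbind(s1 = c(1, 1, 1, 0), s2 = c(0, 1, 1, 1), s3 = c(1, 1, 1, 0),
             s4 = c(0, 0, 0, 1))
  j <- jaccard(m)
  expect_equal(j["s1", "s2"], 0.5)
  expect_equal(j["s1", "s3"], 0)
  expect_equal(j["s1", "s4"], 1)
  expect_equal(j, t(j))
})

test_that("unweighted UniFrac follows branch bookkeeping and matches picante", {
  f <- t1_setup()
  u <- unifrac_unweighted(f$m, f$tree)
  expect_equal(u["s1", "s1"], 0)
  # {A} vs {C}: no shared branch on this tree
  m2 <- rbind(x = c(A = 1, B = 0, C = 0), y = c(A = 0, B = 0, C = 1))
  u2 <- unifrac_unweighted(m2, f$tree)
  expect_equal(u2["x", "y"], 1)

  skip_if_not_installed("picante")
  d <- random_distance(15, 121)
  tr <- upgma(d)
  for (seed in c(122, 123)) {
    m <- random_assemblage(8, 15, seed = seed)
    colnames(m) <- rownames(d)
    got <- unifrac_unweighted(m, tr)
    want <- as.matrix(picante::unifrac(m, tr))
    expect_equal(got[rownames(want), colnames(want)], want, tolerance = 1e-10)
  }
})

test_that("on a star tree UniFrac of singletons is 1 and MPD = MNTD at S = 2", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1):0;")
  m <- rbind(x = c(A = 1, B = 0, C = 0, D = 0),
             y = c(A = 0, B = 1, C = 0, D = 0),
             z = c(A = 1, B = 1, C = 0, D = 0))
  expect_equal(unifrac_unweighted(m, star)["x", "y"], 1)
  d <- cophenetic(star)
  expect_equal(unname(mpd(m, d)["z"]), unname(mntd(m, d)["z"]))
})

test_that("diversity metrics are invariant to peak column order", {
  d <- random_distance(10, 131)
  tr <- upgma(d)
  m <- random_assemblage(4, 10, seed = 132)
  colnames(m) <- rownames(d)
  set.seed(133)
  perm <- sample(ncol(m))
  mp <- m[, perm]
  expect_equal(mpd(m, d), mpd(mp, d))
  expect_equal(mntd(m, d), mntd(mp, d))
  expect_equal(dendrogram_diversity(m, tr), dendrogram_diversity(mp, tr))
  expect_equal(jaccard(m), jaccard(mp))
  expect_equal(unifrac_unweighted(m, tr), unifrac_unweighted(mp, tr))
})

test_that("Spearman Mantel detects identity and monotone transforms", {
  d1 <- random_distance(8, 141)
  r <- mantel_spearman(d1, d1, n_perm = 99)
  expect_equal(r$statistic, 1)
  r2 <- mantel_spearman(d1, d1^2, n_perm = 99)  # monotone transform
  expect_equal(r2$statistic, 1)
  expect_lt(r2$p_value, 0.05)
  expect_error(mantel_spearman(d1[1:3, 1:3], d1[1:3, 1:3], 99), "at least 4")
})
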