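test_that("null_config validates draw counts", {
  expect_error(null_config(n_null_alpha = 10), "at least 99")
  cfg <- null_config(99, 199, 299, seed = 5)
  expect_identical(cfg$n_null_rc, 299L)
  expect_identical(cfg$shuffle_scheme, "tip_shuffle")
})

test_that("beta-MNTD matches hand evaluation and the picante reference", {
  d <- t1_distance()
  m <- rbind(s1 = c(A = 1, B = 1, C = 0), s2 = c(A = 0, B = 0, C = 1))
  b <- bmntd(m, d)
  # {A,B} vs {C}: nearest-between distances are all 4
  expect_equal(b["s1", "s2"], 4)
  expect_equal(diag(b), c(s1 = 0, s2 = 0))

  dm <- random_distance(12, 201)
  mm <- random_assemblage(6, 12, seed = 202)
  colnames(mm) <- rownames(dm)
  got <- bmntd(mm, dm)
  for (i in 1:5) for (j in (i + 1):6) {
    a <- colnames(mm)[mm[i, ] > 0]; b2 <- colnames(mm)[mm[j, ] > 0]
    expect_equal(got[i, j], oracle_bmntd(dm, a, b2), tolerance = 1e-10)
  }

  skip_if_not_installed("picante")
  tr <- upgma(dm)
  # on binary data, abundance.weighted = TRUE reduces to the two-direction
  # mean with weights 1/S, i.e. the definition implemented here
  want <- as.matrix(picante::comdistnt(mm, cophenetic(tr),
                                       abundance.weighted = TRUE))
  got_t <- bmntd(mm, tr)
  expect_equal(got_t[rownames(want), colnames(want)], want, tolerance = 1e-10)
})

test_that("NRI is degenerate when a sample holds every leaf and positive for
           the tightest pair", {
  d <- random_distance(10, 211)
  m_all <- matrix(1, 1, 10, dimnames = list("full", rownames(d)))
  res <- nri(m_all, d, null_config(99, seed = 1))
  expect_true(res$degenerate)
  expect_true(is.na(res$nri))

  # the two closest leaves: observed MPD below almost every null draw
  idx <- which(d == min(d[d > 0]), arr.ind = TRUE)[1, ]
  m_pair <- matrix(0, 1, 10, dimnames = list("tight", rownames(d)))
  m_pair[1, idx] <- 1
  res2 <- nri(m_pair, d, null_config(999, seed = 2))
  expect_gt(res2$nri, 0)
  res3 <- nti(m_pair, d, null_config(999, seed = 2))
  expect_gt(res3$nti, 0)
})

test_that("identical seeds give bit-identical null-model output", {
  d <- random_distance(15, 221)
  tr <- upgma(d)
  m <- random_assemblage(5, 15, seed = 222)
  colnames(m) <- rownames(d)
  cfg <- null_config(99, 99, 99, seed = 77)
  expect_identical(nri(m, d, cfg), nri(m, d, cfg))
  expect_identical(nti(m, d, cfg), nti(m, d, cfg))
  b1 <- bnti(m, tr, cfg); b2 <- bnti(m, tr, cfg)
  expect_identical(b1$z, b2$z)
  expect_identical(raup_crick(m, cfg), raup_crick(m, cfg))
})

test_that("beta-NTI of identical all-leaf samples is non-positive", {
  d <- random_distance(8, 231)
  tr <- upgma(d)
  m <- rbind(a = rep(1, 8), b = rep(1, 8))
  colnames(m) <- rownames(d)
  b <- bnti(m, tr, null_config(99, 99, 99, seed = 3))
  # observed beta-MNTD is 0 and no null can go below it
  expect_equal(b$observed["a", "b"], 0)
  expect_true(is.na(b$z["a", "b"]) || b$z["a", "b"] <= 0)
})

test_that("the printed sign convention negates the default", {
  d <- random_distance(10, 241)
  tr <- upgma(d)
  m <- random_assemblage(4, 10, seed = 242)
  colnames(m) <- rownames(d)
  cfg <- null_config(99, 99, 99, seed = 4)
  b1 <- bnti(m, tr, cfg)
  b2 <- bnti(m, tr, cfg, sign_convention = "negated")
  expect_equal(b1$z, -b2$z)
})

test_that("Raup-Crick stays in [-1, 1] and resolves forced limits", {
  # identical samples spanning the whole pool: every null equals observed
  m0 <- rbind(a = c(1, 1, 1), b = c(1, 1, 1))
  colnames(m0) <- c("p1", "p2", "p3")
  rc0 <- raup_crick(m0, null_config(99, 99, 199, seed = 5))
  expect_equal(rc0["a", "b"], 0)

  # identical small samples in a large diverse pool -> RC near -1
  set.seed(6)
  pool <- 60
  base <- sample(pool, 6)
  m1 <- matrix(0, 4, pool, dimnames = list(letters[1:4], paste0("p", 1:pool)))
  m1[1, base] <- 1; m1[2, base] <- 1
  m1[3, sample(pool, 20)] <- 1; m1[4, sample(pool, 20)] <- 1
  rc1 <- raup_crick(m1, null_config(99, 99, 999, seed = 7),
                    weighting = "uniform")
  expect_lt(rc1["a", "b"], -0.95)
  expect_true(all(rc1 >= -1 & rc1 <= 1))

  # two disjoint small samples in a large pool -> RC near +1
  m2 <- matrix(0, 2, pool, dimnames = list(c("x", "y"), paste0("p", 1:pool)))
  m2[1, 1:5] <- 1; m2[2, 6:10] <- 1
  rc2 <- raup_crick(m2, null_config(99, 99, 999, seed = 8),
                    weighting = "uniform")
  expect_gt(rc2["x", "y"], 0.9)
})

test_that("process classification reproduces the decision thresholds", {
  grid <- expand.grid(z = c(-3, -2.1, -0.5, 0.3, 2.1, 2.5),
                      rc = c(-0.99, -0.5, 0.2, 0.96))
  ns <- nrow(grid)
  # build matrices pair-by-pair: samples 2k-1, 2k carry grid row k
  zmat <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  for (k in seq_len(ns)) {
    zmat[1, 2] <- zmat[2, 1] <- grid$z[k]
    rcmat <- zmat; rcmat[1, 2] <- rcmat[2, 1] <- grid$rc[k]
    cls <- classify_processes(zmat, rcmat)
    want <- if (grid$z[k] > 2) "variable_selection"
      else if (grid$z[k] < -2) "homogeneous_selection"
      else if (grid$rc[k] > 0.95) "dispersal_limitation"
      else if (grid$rc[k] < -0.95) "homogenizing_dispersal"
      else "undominated"
    expect_identical(as.character(cls$process), want)
  }
  # missing RC under |z| < 2 is unresolved, not silently undominated
  zmat[1, 2] <- zmat[2, 1] <- 0.5
  cls_na <- classify_processes(zmat, NULL)
  expect_identical(as.character(cls_na$process), "undominated_unresolved")
})

test_that("process summaries report percentages that sum to 100 per block", {
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  z[1, 2] <- z[2, 1] <- 3; z[3, 4] <- z[4, 3] <- -3
  rc <- z * 0
  cls <- classify_processes(z, rc)
  s <- process_summary(cls)
  expect_equal(sum(s$percent), 100)
  groups <- c(a = "g1", b = "g1", c = "g2", d = "g2")
  s2 <- process_summary(cls, groups)
  for (b in unique(s2$block)) {
    expect_equal(sum(s2$percent[s2$block == b]), 100)
  }
})
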