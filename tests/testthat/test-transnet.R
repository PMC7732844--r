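test_that("builtin database is well-formed and anchored to published masses", {
  db <- transformation_database()
  expect_gte(nrow(db), 60)
  expect_false(anyDuplicated(db$name) > 0)
  expect_false(anyDuplicated(round(db$mass, 4)) > 0)
  expect_true(all(db$mass > 0))
  # masses recomputed from element counts agree with the stored column
  expect_equal(db$mass, monoisotopic_mass(db), tolerance = 1e-12)
  expect_lt(abs(db$mass[db$name == "NH4"] - 18.0343), 1e-4)
  expect_lt(abs(db$mass[db$name == "cysteine (C3H5NOS)"] - 103.0092), 1e-4)
  expect_equal(db$mass[db$name == "CH2"],
               monoisotopic_mass(C = 1, H = 2), tolerance = 1e-12)
})

test_that("mass differences match database entries within tolerance", {
  db <- transformation_database()
  # NH4 gap at absolute tolerance
  net <- match_transformations(c(a = 200.0000, b = 218.0343), db,
                               tol_mode = "absolute", tol_value = 1e-4)
  expect_identical(net$edges$transformation, "NH4")
  # a 100 Da gap matches nothing in the builtin database at 1 ppm
  net2 <- match_transformations(c(a = 200.0000, b = 300.0000), db)
  expect_identical(nrow(net2$edges), 0L)
  # cysteine + NH4 chain forms one component of size 3
  m3 <- c(a = 200.0000, b = 303.0092, c = 218.0343)
  net3 <- match_transformations(m3, db, tol_mode = "absolute",
                                tol_value = 1e-4)
  expect_setequal(net3$edges$transformation, c("cysteine (C3H5NOS)", "NH4"))
  expect_identical(length(unique(net3$membership)), 1L)
})

test_that("matching is order-invariant and monotone in tolerance", {
  u <- gen_formula_universe(40, seed = 31)
  masses <- setNames(u$mass, u$peak_id)
  db <- transformation_database()
  n1 <- match_transformations(masses, db, "absolute", 1e-4)
  set.seed(1)
  n2 <- match_transformations(sample(masses), db, "absolute", 1e-4)
  expect_identical(n1$edges, n2$edges)

  loose <- match_transformations(masses, db, "absolute", 1e-3)
  key <- function(e) paste(e$peak_1, e$peak_2, e$transformation)
  expect_true(all(key(n1$edges) %in% key(loose$edges)))
})

test_that("edge sets equal an exhaustive triple-loop oracle", {
  for (seed in c(41, 42)) {
    u <- gen_formula_universe(30, seed = seed)
    db <- transformation_database()
    for (mode in c("ppm", "absolute")) {
      tol <- if (mode == "ppm") 1 else 1e-4
      net <- match_transformations(setNames(u$mass, u$peak_id), db, mode, tol)
      oracle <- oracle_edge_set(u$peak_id, u$mass, db, mode, tol)
      got <- net$edges[c("peak_1", "peak_2", "transformation")]
      rownames(got) <- NULL
      expect_identical(got, oracle)
    }
  }
})

test_that("transformation counts are annotation-weighted degrees", {
  db <- data.frame(name = c("t1", "t2"), mass = c(10, 20))
  class(db) <- c("transformation_database", "data.frame")
  # path A - B - C via two different transformations
  net <- match_transformations(c(A = 100, B = 110, C = 130), db,
                               "absolute", 1e-6)
  counts <- transformation_counts(net)
  expect_identical(counts[c("A", "B", "C")], c(A = 1L, B = 2L, C = 1L))
  counts2 <- transformation_counts(net, universe = c("A", "B", "C", "D"))
  expect_identical(counts2[["D"]], 0L)
  expect_error(transformation_counts(net, universe = c("A", "B")),
               "universe")
})

test_that("activity partition applies the >40 / 0 thresholds", {
  part <- partition_by_activity(c(A = 0L, B = 41L, C = 12L))
  expect_identical(part$active, "B")
  expect_identical(part$inactive, "A")
  expect_identical(part$threshold_hi, 40)
  none <- partition_by_activity(c(A = 0L, B = 0L))
  expect_identical(none$active, character(0))
  # boundary: exactly 40 is not active
  edge <- partition_by_activity(c(A = 40L))
  expect_identical(edge$active, character(0))
})

test_that("user database CSV overrides and validates", {
  path <- write_peak_csv(data.frame(Name = c("x", "y"), Mass = c(1.5, 2.5)))
  db <- read_transformation_database(path)
  expect_identical(db$name, c("x", "y"))
  bad <- write_peak_csv(data.frame(Name = c("x", "x"), Mass = c(1.5, 2.5)))
  expect_error(read_transformation_database(bad), "duplicate")
})
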