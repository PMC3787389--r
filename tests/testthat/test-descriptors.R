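test_that("normalization yields exact z-scores and drops flat descriptors", {
  x <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(2, 0, 4))
  rownames(x) <- c("c1", "c2", "c3")
  expect_message(out <- normalize_descriptors(x), "zero-variance.*b")
  expect_identical(colnames(out), c("a", "c"))
  expect_equal(out[, "a"], c(c1 = -1, c2 = 0, c3 = 1))
  ns <- attr(out, "norm_stats")
  expect_equal(ns$mean[ns$descriptor == "a"], 2)
  expect_equal(ns$sd[ns$descriptor == "a"], 1)

  expect_error(normalize_descriptors(x[1, , drop = FALSE]), "at least 2")
  flat <- matrix(1, 3, 2, dimnames = list(letters[1:3], c("u", "v")))
  expect_error(quiet(normalize_descriptors(flat)), "zero variance")
})

test_that("every retained column is standardized, verified by recomputation", {
  x <- rand_descriptors(20, 50, seed = 11)
  out <- normalize_descriptors(x)
  expect_true(all(abs(colMeans(out)) <= 1e-9))
  expect_true(all(abs(apply(out, 2, sd) - 1) <= 1e-9))
  # direct per-cell recomputation from the stored statistics
  ns <- attr(out, "norm_stats")
  manual <- sweep(sweep(x[, ns$descriptor], 2, ns$mean, "-"), 2, ns$sd, "/")
  expect_equal(unclass(out), manual, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("library projection uses training statistics only", {
  x <- rand_descriptors(15, 8, seed = 2)
  trained <- normalize_descriptors(x)
  # projecting the training table through its own stats is the identity
  expect_equal(unclass(project_library(x, trained)), unclass(trained),
               tolerance = 1e-12, ignore_attr = TRUE)

  # a library column equal to the training mean maps to zero
  lib <- rand_descriptors(6, 8, seed = 3)
  lib[, 2] <- mean(x[, 2])
  proj <- project_library(lib, trained)
  expect_true(all(abs(proj[, 2]) < 1e-12))

  # brute-force per-cell oracle
  ns <- attr(trained, "norm_stats")
  for (i in rownames(lib)) for (k in ns$descriptor) {
    expect_equal(proj[i, k], (lib[i, k] - ns$mean[ns$descriptor == k]) /
                   ns$sd[ns$descriptor == k], tolerance = 1e-12)
  }

  expect_error(project_library(lib[, -2], trained), "d02")
})

test_that("weighted distances obey column-duplication semantics", {
  x <- normalize_descriptors(rand_descriptors(10, 5, seed = 4))
  d <- pairwise_distance(x, c("d01", "d01", "d03"))
  dup <- cbind(x[, "d01", drop = FALSE], `d01b` = x[, "d01"],
               x[, "d03", drop = FALSE])
  expect_equal(unclass(d), unclass(as.matrix(dist(dup))),
               tolerance = 1e-12, ignore_attr = TRUE)

  # single descriptor: absolute coordinate difference
  d1 <- pairwise_distance(x, "d02")
  expect_equal(d1["c01", "c05"], abs(x["c01", "d02"] - x["c05", "d02"]))
  expect_true(all(diag(pairwise_distance(x)) == 0))
  expect_error(pairwise_distance(x, character(0)), "empty")
  expect_error(pairwise_distance(x, "nope"), "unknown descriptor")
})

test_that("distance properties: triangle inequality, permutation, weight scaling", {
  x <- normalize_descriptors(rand_descriptors(12, 6, seed = 5))
  w <- c("d01", "d02", "d02", "d05")
  d <- pairwise_distance(x, w)
  set.seed(9)
  for (rep in 1:25) {
    ijk <- sample(rownames(x), 3)
    expect_lte(d[ijk[1], ijk[3]], d[ijk[1], ijk[2]] + d[ijk[2], ijk[3]] + 1e-12)
  }
  perm <- sample(rownames(x))
  expect_equal(unclass(pairwise_distance(x[perm, ], w)), unclass(d[perm, perm]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unclass(pairwise_distance(x, rep(w, 2))), unclass(sqrt(2) * d),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("activity distances are absolute response differences", {
  act <- activity_of(c(0, 100, 250), odor_ids = c("o1", "o2", "o3"))
  d <- activity_distance(act, "OrA")
  expect_equal(d["o1", "o2"], 100)
  expect_equal(d["o1", "o3"], 250)
  expect_equal(d["o2", "o3"], 150)

  same <- activity_of(rep(42, 4))
  expect_true(all(activity_distance(same, "OrA") == 0))

  set.seed(6)
  a <- rnorm(9) * 100
  act <- activity_of(a)
  d <- activity_distance(act, "OrA")
  for (i in seq_along(a)) for (j in seq_along(a)) {
    expect_identical(d[i, j], abs(a[i] - a[j]))
  }
  expect_error(activity_distance(act, "OrB"), "unknown receptor")
})

test_that("descriptor multisets serialize losslessly to JSON", {
  m <- descriptor_multiset(c("d3", "d1", "d3"), receptor = "Or9")
  f <- withr::local_tempfile(fileext = ".json")
  write_multiset(m, f)
  back <- read_multiset(f)
  expect_identical(as.character(back), c("d3", "d1", "d3"))
  expect_identical(attr(back, "receptor"), "Or9")
  expect_identical(multiplicity(m), c(d1 = 1L, d3 = 2L))
})
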