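test_that("objective is 1 when a descriptor reproduces activity exactly", {
  set.seed(31)
  n <- 10
  a <- c(260, 230, 210, runif(n - 3, 0, 40))
  x <- rand_descriptors(n, 4, seed = 32)
  x[, "d01"] <- a  # one descriptor carries the activity verbatim
  act <- activity_of(a, odor_ids = rownames(x))
  actives <- classify_actives(act, "OrA")
  cbca <- activity_distance(act, "OrA")
  expect_equal(objective_correlation(x, "d01", cbca, actives), 1.0,
               tolerance = 1e-12)
})

test_that("degenerate activity yields the -Inf sentinel", {
  x <- rand_descriptors(6, 3, seed = 33)
  cbca <- matrix(0, 6, 6, dimnames = list(rownames(x), rownames(x)))
  expect_identical(objective_correlation(x, "d01", cbca, rownames(x)[1:3]), -Inf)
})

test_that("objective matches a literal brute-force implementation", {
  set.seed(34)
  x <- normalize_descriptors(rand_descriptors(8, 5, seed = 35))
  a <- setNames(runif(8, 0, 250), rownames(x))
  act <- activity_of(a, odor_ids = names(a))
  cbca <- activity_distance(act, "OrA")
  actives <- names(sort(a, decreasing = TRUE))[1:3]
  for (ms in list("d01", c("d02", "d04"), c("d01", "d01", "d05"))) {
    expect_equal(objective_correlation(x, ms, cbca, actives),
                 oracle_objective(x, ms, a, actives), tolerance = 1e-12)
  }
})

test_that("a descriptor that encodes activity is selected first and halts the search", {
  set.seed(36)
  n <- 12
  a <- c(240, 200, 180, runif(n - 3, 0, 30))
  x <- rand_descriptors(n, 3, seed = 37)
  colnames(x) <- c("d1", "d2", "d3")
  x[, "d3"] <- a  # activity distance is exactly the d3 distance
  act <- activity_of(a, odor_ids = rownames(x))
  tr <- sfs_select(x, act, "OrA")
  expect_identical(as.character(tr$multiset), "d3")
  expect_equal(tr$objective, 1.0, tolerance = 1e-12)
})

test_that("a single-descriptor pool is selected once, then halts", {
  set.seed(38)
  x <- rand_descriptors(8, 1, seed = 39)
  a <- c(200, 190, runif(6, 0, 30))
  act <- activity_of(a, odor_ids = rownames(x))
  tr <- sfs_select(x, act, "OrA")
  expect_identical(as.character(tr$multiset), "d01")
  expect_identical(nrow(tr$iterations), 1L)
})

test_that("greedy selection matches an exhaustive per-step oracle", {
  set.seed(40)
  x <- normalize_descriptors(rand_descriptors(12, 6, seed = 41))
  a <- setNames(c(250, 210, 190, runif(9, 0, 40)), rownames(x))
  act <- activity_of(a, odor_ids = names(a))
  actives <- classify_actives(act, "OrA")

  tr <- sfs_select(x, act, "OrA", actives = actives, max_iter = 3)
  oracle <- oracle_sfs(x, a, actives$members, steps = 3)
  expect_identical(as.character(tr$multiset), oracle$sel)
  expect_equal(tr$iterations$objective, oracle$objs, tolerance = 1e-12)
})

test_that("objective sequence strictly increases and selection is column-order invariant", {
  cfg <- synthetic_config(n_train = 40, n_library = 0, n_descriptors = 30,
                          seed = 5,
                          receptors = list(list(id = "OrX", s_star = 1:3,
                                                anchor = 1L, tau = 2.2,
                                                a_max = 51, sigma = 0)))
  panel <- generate_panel(cfg)
  x <- normalize_descriptors(panel$descriptors)
  tr <- sfs_select(x, panel$activity, "OrX")
  expect_true(all(diff(tr$iterations$objective) > 0))
  expect_equal(tr$objective, tr$iterations$objective[nrow(tr$iterations)])

  perm <- sample(ncol(x))
  tr2 <- sfs_select(x[, perm], panel$activity, "OrX")
  expect_identical(as.character(tr2$multiset), as.character(tr$multiset))
})

test_that("planted descriptor subspaces are recovered at zero noise", {
  cfg <- synthetic_config(n_train = 100, n_library = 0, n_descriptors = 200,
                          seed = 2,
                          receptors = list(list(id = "OrX", s_star = 1:3,
                                                anchor = 1L, tau = 2.2,
                                                a_max = 51, sigma = 0)))
  panel <- generate_panel(cfg)
  fit <- or_fit(panel$activity, panel$descriptors, "OrX")
  expect_true(all(as.character(fit$multiset) %in% c("d001", "d002", "d003")))
})

test_that("SFS traces serialize to JSON", {
  x <- normalize_descriptors(rand_descriptors(8, 3, seed = 43))
  a <- c(220, 210, runif(6, 0, 30))
  act <- activity_of(a, odor_ids = rownames(x))
  tr <- sfs_select(x, act, "OrA", max_iter = 2)
  f <- withr::local_tempfile(fileext = ".json")
  write_sfs_trace(tr, f)
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_identical(obj$receptor_id, "OrA")
  expect_equal(obj$final_objective, tr$objective, tolerance = 1e-12)
})
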