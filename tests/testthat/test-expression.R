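test_that("read_expression parses matrix and groups and validates them", {
  paths <- write_tiny_study(withr::local_tempdir())
  ds <- read_expression(paths$matrix, paths$groups, "D1")
  expect_s3_class(ds, "ExpressionDataset")
  expect_equal(dim(ds$values), c(3L, 4L))
  expect_equal(rownames(ds$values), c("GA", "GB", "GC"))
  expect_equal(unname(ds$groups), c("case", "case", "control", "control"))
})

test_that("rows with an empty gene identifier are deleted at read time", {
  paths <- write_tiny_study(
    withr::local_tempdir(),
    matrix_lines = c("gene_id\ts1\ts2\ts3\ts4",
                     "GA\t5\t6\t1\t2",
                     "\t9\t9\t9\t9",
                     "GC\t8\t9\t4\t5"))
  ds <- suppressMessages(read_expression(paths$matrix, paths$groups, "D1"))
  expect_equal(rownames(ds$values), c("GA", "GC"))
})

test_that("read_expression errors name the offending sample or cell", {
  dir <- withr::local_tempdir()
  paths <- write_tiny_study(dir, group_lines = c("s1\tcase", "s2\tcase",
                                                 "s3\tcontrol"))
  expect_error(read_expression(paths$matrix, paths$groups, "D1"), "s4")

  paths2 <- write_tiny_study(
    file.path(dir, "bad"),
    matrix_lines = c("gene_id\ts1\ts2\ts3\ts4",
                     "GA\t5\toops\t1\t2",
                     "GC\t8\t9\t4\t5"))
  expect_error(read_expression(paths2$matrix, paths2$groups, "D1"), "oops")
  expect_error(read_expression(paths2$matrix, paths2$groups, "D1"), "s2")
})

test_that("fewer than two samples in either group is rejected", {
  vals <- matrix(1:6, 2, 3,
                 dimnames = list(c("GA", "GB"), c("s1", "s2", "s3")))
  groups <- c(s1 = "case", s2 = "control", s3 = "control")
  expect_error(expression_dataset(vals, groups, "D1"), "at least 2")
})

test_that("collapse_probes keeps the probe with the largest group-mean gap", {
  vals <- matrix(c(5, 5, 4.5, 4.5,    # |dmean| = 0.5
                   7, 7, 5, 5,        # |dmean| = 2.0
                   1, 1, 3, 3),       # maps to another gene
                 nrow = 3L, byrow = TRUE,
                 dimnames = list(c("p1", "p2", "p3"),
                                 c("s1", "s2", "s3", "s4")))
  ds <- tiny_dataset(vals)
  map <- c(p1 = "GENEA", p2 = "GENEA", p3 = "GENEB")
  out <- collapse_probes(ds, map, rule = "max_abs_logfc")
  expect_equal(sort(rownames(out$values)), c("GENEA", "GENEB"))
  expect_equal(unname(out$values["GENEA", ]), c(7, 7, 5, 5))
})

test_that("probes mapping to distinct genes leave the row count unchanged", {
  ds <- tiny_dataset()
  map <- c(GA = "X1", GB = "X2", GC = "X3")
  out <- collapse_probes(ds, map)
  expect_equal(nrow(out$values), 3L)
  expect_false(anyDuplicated(rownames(out$values)) > 0L)
})

test_that("equal collapse scores break ties to the smallest probe id", {
  vals <- matrix(c(6, 6, 4, 4,
                   7, 7, 5, 5),   # same |dmean| = 2 for both probes
                 nrow = 2L, byrow = TRUE,
                 dimnames = list(c("p2", "p1"), c("s1", "s2", "s3", "s4")))
  ds <- tiny_dataset(vals)
  out <- collapse_probes(ds, c(p1 = "G", p2 = "G"))
  # p1 wins the tie, carrying its own values
  expect_equal(unname(out$values["G", ]), c(7, 7, 5, 5))
})

test_that("unmapped probes are dropped and an empty result errors", {
  ds <- tiny_dataset()
  out <- suppressMessages(collapse_probes(ds, c(GA = "X", GB = "", GC = "Y")))
  expect_equal(sort(rownames(out$values)), c("X", "Y"))
  expect_error(suppressMessages(collapse_probes(ds, c(GA = ""))),
               "no probes")
})

test_that("log2 transform follows the policy and the auto-detection rule", {
  vals <- matrix(c(1, 3, 7, 100, 200, 400), nrow = 2L, byrow = TRUE,
                 dimnames = list(c("GA", "GB"), c("s1", "s2", "s3")))
  vals <- rbind(vals, GC = c(50, 60, 80), GD = c(9, 9, 10))
  groups <- stats::setNames(c("case", "case", "control"), colnames(vals))
  groups <- c(groups, s4 = "control")
  vals <- cbind(vals, s4 = c(2, 150, 70, 9.5))
  ds <- expression_dataset(vals, groups, "D1")

  out <- maybe_log2(ds, policy = "always", pseudocount = 1)
  expect_equal(unname(out$values["GA", 1:3]), c(1, 2, 3))
  expect_true(attr(out, "log2_applied"))

  expect_identical(maybe_log2(ds, policy = "never")$values, ds$values)

  # values within the usual log-intensity range: auto leaves them alone
  logged <- tiny_dataset()  # all values in [1, 9]
  out2 <- maybe_log2(logged, policy = "auto")
  expect_identical(out2$values, logged$values)
  expect_false(attr(out2, "log2_applied"))

  # raw-intensity scale: auto applies the transform
  out3 <- maybe_log2(ds, policy = "auto")
  expect_true(attr(out3, "log2_applied"))

  # negatives mean the data are already logged, even under "always"
  neg <- tiny_dataset(matrix(c(-1, 2, 0, 1, 5, 4, 3, 2),
                             nrow = 2L, byrow = TRUE,
                             dimnames = list(c("GA", "GB"),
                                             c("s1", "s2", "s3", "s4"))))
  out4 <- suppressMessages(maybe_log2(neg, policy = "always"))
  expect_identical(out4$values, neg$values)
})

test_that("applying the never policy twice is the identity", {
  ds <- tiny_dataset()
  expect_identical(maybe_log2(maybe_log2(ds, "never"), "never")$values,
                   ds$values)
})

test_that("z-scoring standardises rows exactly as defined", {
  ds <- tiny_dataset()
  z <- zscore_rows(ds, ddof = 1)
  expect_equal(unname(rowMeans(z$values)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(z$values, 1, stats::sd)), rep(1, 3),
               tolerance = 1e-12)

  # hand-checked three-point case: [1, 2, 3] -> [-1, 0, 1] with sample sd
  v3 <- matrix(c(1, 2, 3), nrow = 1L,
               dimnames = list("GA", c("s1", "s2", "s3")))
  ds3 <- structure(list(disease_id = "D1", values = v3,
                        groups = stats::setNames(
                          c("case", "case", "control"), colnames(v3))),
                   class = "ExpressionDataset")
  expect_equal(unname(zscore_rows(ds3, ddof = 1)$values["GA", ]),
               c(-1, 0, 1))
})

test_that("z-scored rows have mean 0 and sd 1 across random matrices", {
  set.seed(42)
  for (rep in seq_len(100L)) {
    vals <- matrix(stats::rnorm(80, sd = stats::runif(1, 0.5, 3)), 10L, 8L,
                   dimnames = list(sprintf("G%02d", 1:10),
                                   sprintf("s%d", 1:8)))
    ds <- expression_dataset(
      vals, stats::setNames(rep(c("case", "control"), each = 4L),
                            colnames(vals)), "D1")
    z <- zscore_rows(ds, ddof = 1)
    expect_lt(max(abs(rowMeans(z$values))), 1e-9)
    expect_lt(max(abs(apply(z$values, 1, stats::sd) - 1)), 1e-9)
  }
})

test_that("z-scoring is idempotent and drops constant rows", {
  ds <- tiny_dataset()
  z1 <- zscore_rows(ds)
  z2 <- zscore_rows(z1)
  expect_equal(z1$values, z2$values, tolerance = 1e-9)

  const <- tiny_dataset(matrix(c(5, 5, 5, 5, 1, 2, 3, 4),
                               nrow = 2L, byrow = TRUE,
                               dimnames = list(c("GA", "GB"),
                                               c("s1", "s2", "s3", "s4"))))
  expect_warning(z <- zscore_rows(const), "zero-variance")
  expect_equal(rownames(z$values), "GB")

  # ddof = 0 uses the population sd
  z0 <- zscore_rows(ds, ddof = 0)
  n <- ncol(ds$values)
  expect_equal(unname(apply(z0$values, 1, stats::sd)),
               rep(sqrt(n / (n - 1)), 3), tolerance = 1e-12)
})
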