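# Reading, preprocessing, and partition file handling.

test_that("square matrices parse with delimiter auto-detection", {
  for (txt in list(c("0 0.5", "0.5 0"), c("0,0.5", "0.5,0"),
                   c("0\t0.5", "0.5\t0"))) {
    f <- withr::local_tempfile(lines = txt)
    cm <- read_connectivity_matrix(f)
    expect_equal(cm$values, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  }
})

test_that("non-square and non-numeric inputs are rejected with located errors", {
  f <- withr::local_tempfile(lines = c("0 0.5 1", "0.5 0 1"))
  expect_error(read_connectivity_matrix(f), "shape error")
  f2 <- withr::local_tempfile(lines = c("0 x", "0.5 0"))
  expect_error(read_connectivity_matrix(f2), "parse error at row 1, column 2")
  f3 <- withr::local_tempfile(lines = c("0 Inf", "0.5 0"))
  expect_error(read_connectivity_matrix(f3), "non-finite")
})

test_that("header row and label column round-trip through write/read", {
  labels <- paste0("ROI", 1:3)
  cm <- connectivity_matrix(matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3), labels)
  f <- withr::local_tempfile()
  write_connectivity_matrix(cm, f)
  back <- read_connectivity_matrix(f)
  expect_equal(back$labels, labels)
  expect_equal(back$values, cm$values)
})

test_that("reverse z-transform matches its closed form and inverts artanh", {
  expect_identical(reverse_z_transform(matrix(0, 1, 1))[1], 0)
  expect_equal(reverse_z_transform(matrix(1, 1, 1))[1],
               (exp(2) - 1) / (exp(2) + 1), tolerance = 1e-12)
  x <- seq(-0.998, 0.998, length.out = 201)
  back <- reverse_z_transform(matrix(atanh(x), ncol = 1))
  expect_equal(as.vector(back), x, tolerance = 1e-12)
})

test_that("clamping and thresholding behave entrywise and are idempotent", {
  m <- matrix(c(-0.3, 0.4, 0.15, 0.2), 2, 2)
  expect_equal(clamp_negative(m), matrix(c(0, 0.4, 0.15, 0.2), 2, 2))
  expect_equal(clamp_negative(matrix(-1, 2, 2)), matrix(0, 2, 2))
  th <- threshold_edges(m, 0.2)
  expect_equal(th[1, 2], 0)       # 0.15 < theta removed
  expect_equal(th[2, 2], 0.2)     # boundary kept: strict inequality
  nonneg <- clamp_negative(m)
  expect_equal(threshold_edges(nonneg, 0), nonneg)
  expect_equal(threshold_edges(th, 0.2), th)
  expect_equal(clamp_negative(clamp_negative(m)), clamp_negative(m))
})

test_that("preprocessing produces a valid weighted graph for messy input", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    raw <- matrix(rnorm(n * n), n, n)
    raw <- (raw + t(raw)) / 2 + matrix(rnorm(n * n, sd = 1e-8), n, n)
    g <- tryCatch(preprocess_cm(raw, theta = 0.1), error = function(e) e)
    if (inherits(g, "error")) {
      expect_match(conditionMessage(g), "empty graph")
      next
    }
    a <- g$adjacency
    expect_lte(max(abs(a - t(a))), 1e-9)
    expect_true(all(a >= 0))
    expect_identical(unname(diag(a)), rep(0, n))
    expect_equal(g$degrees, rowSums(a))
    expect_equal(g$total_weight, sum(a) / 2)
  }
})

test_that("preprocessing is the identity on an already clean matrix", {
  b <- planted_benchmark(c(4, 4), seed = 8, theta = 0)
  g <- preprocess_cm(b$graph$adjacency, theta = 0)
  expect_equal(g$adjacency, b$graph$adjacency)
})

test_that("preprocessing rejects strongly asymmetric input and empty results", {
  m <- matrix(c(0, 0.5, 0.1, 0), 2, 2)
  expect_error(preprocess_cm(m), "asymmetric")
  expect_error(preprocess_cm(matrix(0.1, 3, 3), theta = 0.2), "empty graph")
})

test_that("partition files round-trip and enforce vertex coverage", {
  p <- partition(c(0L, 0L, 1L, 1L))
  f <- withr::local_tempfile()
  write_partition(p, f)
  back <- read_partition(f)
  expect_identical(back$labels, p$labels)
  expect_identical(back$K, p$K)

  f2 <- withr::local_tempfile(lines = c("0\t0", "0\t1", "2\t1"))
  expect_error(read_partition(f2), "duplicate vertex")
  f3 <- withr::local_tempfile(lines = c("0\t0", "2\t1", "3\t1"))
  expect_error(read_partition(f3), "missing vertex")
  f4 <- withr::local_tempfile(lines = c("0\t-1", "1\t0"))
  expect_error(read_partition(f4), "negative community")
})

test_that("non-contiguous community ids are canonicalized with a warning", {
  f <- withr::local_tempfile(lines = c("0\t5", "1\t5", "2\t7"))
  expect_warning(p <- read_partition(f), "relabelled")
  expect_identical(p$labels, c(0L, 0L, 1L))
})

test_that("edge lists round-trip through the adjacency matrix", {
  g <- two_triangles_graph()
  f <- withr::local_tempfile()
  write_edge_list(g, f)
  back <- read_edge_list(f)
  expect_equal(back$adjacency, g$adjacency)
})

test_that("weighted_graph enforces its invariants", {
  expect_error(weighted_graph(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  expect_error(weighted_graph(matrix(c(0, -1, -1, 0), 2, 2)), "nonnegative")
  expect_error(weighted_graph(matrix(c(1, 0, 0, 0), 2, 2)), "diagonal")
})
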