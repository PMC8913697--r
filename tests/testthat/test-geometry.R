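test_that("read_swc parses standard records and rejects malformed input", {
  f <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# comment", "1 1 0 0 0 1 -1", "2 3 10 0 0 1 1",
               "3 3 20 0 0 1 2"), f)
  sk <- read_swc(f)
  expect_s3_class(sk, "skeleton")
  expect_equal(nrow(sk$nodes), 3L)
  expect_equal(skeleton_root(sk), 1L)
  expect_equal(skeleton_leaves(sk), 3L)
  expect_equal(sk$nodes$radius, rep(1, 3))

  writeLines("# header only", f)
  expect_error(read_swc(f), "no data records")

  writeLines(c("1 1 0 0 0 1 -1", "2 3 10 0 0 1"), f)
  expect_error(read_swc(f), "line 2")

  writeLines(c("1 1 0 0 0 1 -1", "2 3 10 0 0 1 -1"), f)
  expect_error(read_swc(f), "exactly one root")
})

test_that("write_swc / read_swc round-trips a random tree exactly", {
  set.seed(42)
  n <- 10L
  parent <- c(-1L, vapply(2:n, function(i) sample(seq_len(i - 1L), 1L), 1L))
  nd <- data.frame(id = 1:n, type = 3L,
                   x = cumsum(runif(n, 1, 5)), y = rnorm(n, sd = 3),
                   radius = runif(n, 0.5, 2), parent = parent)
  sk <- skeleton(nd)
  f <- withr::local_tempfile(fileext = ".swc")
  write_swc(sk, f)
  sk2 <- read_swc(f)
  expect_identical(sk2$nodes$id, sk$nodes$id)
  expect_identical(sk2$nodes$parent, sk$nodes$parent)
  expect_equal(sk2$nodes$x, sk$nodes$x, tolerance = 1e-9)
  expect_equal(sk2$nodes$y, sk$nodes$y, tolerance = 1e-9)
  expect_equal(sk2$nodes$radius, sk$nodes$radius, tolerance = 1e-9)
})

test_that("clean_skeleton merges duplicates, is idempotent, never grows", {
  nd <- data.frame(id = 1:4, type = 3L,
                   x = c(0, 10, 10 + 1e-9, 20), y = 0,
                   radius = 1, parent = c(-1L, 1L, 2L, 3L))
  sk <- structure(list(nodes = nd), class = "skeleton")  # skip ctor checks
  cl <- clean_skeleton(sk, tol = 1e-6)
  expect_equal(nrow(cl$nodes), 3L)
  expect_equal(length(skeleton_leaves(cl)), 1L)
  cl2 <- clean_skeleton(cl, tol = 1e-6)
  expect_identical(cl2$nodes, cl$nodes)

  ## short-edge collapse agrees with an exhaustive pairwise-distance scan
  set.seed(7)
  nd2 <- data.frame(id = 1:6, type = 3L,
                    x = c(0, 5, 5 + 5e-7, 11, 16, 22), y = 0,
                    radius = 1, parent = c(-1L, 1:5))
  sk2 <- structure(list(nodes = nd2), class = "skeleton")
  tol <- 1e-6
  d <- as.matrix(dist(nd2[, c("x", "y")])); diag(d) <- Inf
  n_expected <- nrow(nd2) - sum(d[upper.tri(d)] <= tol)
  cl3 <- clean_skeleton(sk2, tol = tol)
  expect_equal(nrow(cl3$nodes), n_expected)
  expect_equal(length(skeleton_leaves(cl3)), 1L)
})

test_that("synthetic pipe, swollen pipe and bifurcation match their specs", {
  sk <- make_synthetic_skeleton(geometry_spec("pipe", length = 80,
                                              base_radius = 2, spacing = 10))
  expect_equal(nrow(sk$nodes), 9L)
  expect_true(all(sk$nodes$radius == 2))

  spec <- swollen_spec()
  expect_equal(radius_profile(40, spec), 4)           # amplified center
  expect_equal(radius_profile(c(0, 29.9, 50.1, 80), spec), rep(2, 4))

  skb <- make_synthetic_skeleton(
    geometry_spec("bifurcation", length = 40, base_radius = 2, spacing = 5,
                  branch_length = 30, branch_angle = pi / 6))
  nd <- skb$nodes
  key <- paste(round(nd$x, 12), round(-nd$y, 12))
  expect_true(all(key %in% paste(round(nd$x, 12), round(nd$y, 12))))
})

test_that("swelling bump is C1 at the window boundary", {
  spec <- swollen_spec()
  edge <- 30                      # s0 - L2/2
  jump <- function(h) {
    sl_out <- (radius_profile(edge, spec) -
                 radius_profile(edge - h, spec)) / h
    sl_in <- (radius_profile(edge + h, spec) -
                radius_profile(edge, spec)) / h
    abs(sl_in - sl_out)
  }
  interior_slope <- abs(radius_profile(35 + 1e-6, spec) -
                          radius_profile(35 - 1e-6, spec)) / 2e-6
  ## one-sided slope jumps vanish linearly in the step (C1 contact)
  expect_lt(jump(1e-4), 1e-4 * interior_slope)
  expect_lt(jump(1e-4), 0.15 * jump(1e-3))
})
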