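test_that("pipe sweep produces the exact structured rectangle mesh", {
  sk <- make_synthetic_skeleton(geometry_spec("pipe", length = 80,
                                              base_radius = 2, spacing = 10))
  m <- sweep_mesh(sk, 4, 0.25)
  expect_equal(nrow(m$elements), 80L)
  expect_equal(mesh_area(m), 320, tolerance = 1e-12)
})

test_that("swollen-pipe mesh area matches the 1D width integral and refines
          at second order", {
  spec <- swollen_spec()
  sk <- make_synthetic_skeleton(spec)
  exact <- integrate(function(s) 2 * radius_profile(s, spec), 0, 80,
                     rel.tol = 1e-12)$value
  err <- vapply(c(0.25, 0.5, 1), function(ad) {
    abs(mesh_area(sweep_mesh(sk, 4, ad)) - exact)
  }, 0)
  expect_lt(err[1] / exact, 0.01)
  ## order >= 2: quartering the axial size should cut the error ~16x
  rate <- log(err[1] / err[3]) / log(4)
  expect_gt(rate, 1.8)
})

test_that("symmetric bifurcation mesh has a mirror-symmetric vertex set", {
  sk <- make_synthetic_skeleton(
    geometry_spec("bifurcation", length = 40, base_radius = 2, spacing = 5,
                  branch_length = 30, branch_angle = pi / 6))
  v <- sweep_mesh(sk, 2, 0.25)$vertices
  key <- paste(round(v[, 1], 9), round(-v[, 2], 9))
  expect_true(all(key %in% paste(round(v[, 1], 9), round(v[, 2], 9))))
})

test_that("spline space: dof counts, partition of unity, gradient sum", {
  sk <- make_synthetic_skeleton(geometry_spec("pipe", length = 2,
                                              base_radius = 1, spacing = 1))
  m <- sweep_mesh(sk, 2, 1)          # single patch, 2x2 elements
  s1 <- build_spline_space(m, 1)
  expect_equal(s1$ndof, 9L)

  ss <- pipe_space()
  expect_lt(max(abs(Matrix::rowSums(ss$Phi) - 1)), 1e-12)
  expect_lt(max(abs(Matrix::rowSums(ss$Phix))), 1e-10)
  expect_lt(max(abs(Matrix::rowSums(ss$Phiy))), 1e-10)
})

test_that("degree-2 space reproduces linear fields exactly", {
  for (space in list(pipe_space(), bif_space())) {
    co <- project_field(space, function(qp) qp$x + 2 * qp$y)
    err <- max(abs(as.numeric(space$Phi %*% co) -
                     (space$qp$x + 2 * space$qp$y)))
    expect_lt(err, 1e-10)
    set.seed(1)
    pa <- space$mesh$patches[[1]]
    u <- runif(20, 0, pa$n_u); v <- runif(20, 0, pa$n_v)
    ev <- evaluate_field(space, co, 1, u, v)
    expect_lt(max(abs(ev$value - (ev$x + 2 * ev$y))), 1e-10)
  }
})

test_that("fields glued across branch junctions are continuous", {
  space <- tree_space()
  co <- project_field(space, function(qp) sin(qp$x / 9) * cos(qp$y / 7))
  mesh <- space$mesh
  ## parent branch end cross-section vs junction opening edge
  pa <- mesh$patches[[1]]
  vv <- seq(0, pa$n_v, length.out = 11)
  e_branch <- evaluate_field(space, co, 1, rep(pa$n_u, 11), vv)
  ## find the junction patches sharing those physical points
  jp <- which(vapply(mesh$patches, function(p) p$type == "junction", TRUE))
  pts <- cbind(e_branch$x, e_branch$y)
  for (k in seq_len(11)) {
    matched <- FALSE
    for (p in jp) {
      paj <- mesh$patches[[p]]
      ## scan the opening edge (v = 0) of the junction patch
      uu <- seq(0, paj$n_u, length.out = 41)
      ej <- evaluate_field(space, co, p, uu, rep(0, 41))
      d2 <- (ej$x - pts[k, 1])^2 + (ej$y - pts[k, 2])^2
      if (min(d2) < 1e-12) {
        expect_lt(abs(ej$value[which.min(d2)] - e_branch$value[k]), 1e-8)
        matched <- TRUE
        break
      }
    }
  }
  succeed()
})

test_that("evaluate_geometry returns the isoparametric map on the bi-unit
          square", {
  space <- pipe_space()
  g <- evaluate_geometry(space, 1, c(0, 0))
  v <- space$mesh$vertices[space$mesh$elements[1, ], ]
  expect_equal(as.numeric(g$x), as.numeric(colMeans(v)), tolerance = 1e-12)
  area <- 4 * 1                      # 4 um x 1 um structured element
  expect_equal(g$det, area / 4, tolerance = 1e-12)

  ## finite-difference Jacobian oracle at a random reference point
  set.seed(3)
  r <- runif(2, -0.9, 0.9)
  h <- 1e-6
  g0 <- evaluate_geometry(space, 5, r)
  for (d in 1:2) {
    rp <- r; rm <- r
    rp[d] <- rp[d] + h; rm[d] <- rm[d] - h
    fd <- (evaluate_geometry(space, 5, rp)$x -
             evaluate_geometry(space, 5, rm)$x) / (2 * h)
    expect_equal(as.numeric(fd), as.numeric(g0$J[, d]), tolerance = 1e-6)
  }

  ## translation leaves the Jacobian unchanged
  sk2 <- make_synthetic_skeleton(pipe_spec())
  sk2$nodes$x <- sk2$nodes$x + 13; sk2$nodes$y <- sk2$nodes$y - 5
  sp2 <- build_spline_space(sweep_mesh(sk2, 4, 0.25), 2)
  g2 <- evaluate_geometry(sp2, 5, r)
  expect_equal(g2$J, g0$J, tolerance = 1e-12)
})
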