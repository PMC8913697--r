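test_that("GMRES solves a sparse system to the requested tolerance", {
  set.seed(21)
  n <- 120
  A <- Matrix::sparseMatrix(i = 1:n, j = 1:n, x = runif(n, 2, 4)) +
    0.2 * Matrix::rsparsematrix(n, n, density = 0.05)
  b <- rnorm(n)
  ## diagonal preconditioner
  d <- Matrix::diag(A)
  sol <- gmres_solve(function(v) as.numeric(A %*% v), b,
                     prec = function(v) v / d, restart = 60, maxit = 400,
                     tol = 1e-10)
  expect_true(sol$converged)
  ref <- as.numeric(Matrix::solve(A, b))
  expect_equal(sol$x, ref, tolerance = 1e-7)
})

test_that("assembled Lagrangian gradient matches central differences", {
  space <- pipe_space()
  ps <- parameter_set()
  mt <- make_mt_density(space, "uniform", ps)
  tgt <- pipe_target()
  worst <- finite_difference_gradient_check(space, ps, mt, tgt,
                                            epsilon = 1e-6)
  expect_lt(worst, 1e-5)
})

test_that("gradient check is exact for the quadratic sub-problem and shows
          second-order step dependence", {
  space <- pipe_space()
  ps <- parameter_set()
  mt <- make_mt_density(space, "uniform", ps)
  tgt <- pipe_target()
  N <- space$ndof
  ## zero adjoint: the Lagrangian reduces to the quadratic objective
  quad_iter <- list(state = zero_state(space), control = zero_control(space),
                    adjoint = stats::setNames(rep(list(numeric(N)), 4),
                                              c("n0", "np", "vx", "vy")))
  expect_lt(finite_difference_gradient_check(space, ps, mt, tgt,
                                             iterate = quad_iter,
                                             epsilon = 1e-5), 1e-7)
  ## The Lagrangian is quadratic in (state, control) at fixed adjoint, so
  ## the central-difference truncation term only appears for joint
  ## (primal, adjoint) perturbations; along those the error grows as eps^2
  ## (Richardson slope ~ 2).
  gfn <- function(f) getFromNamespace(f, "neurotransport")
  ctx <- gfn("make_transport_ctx")(space, ps, mt, tgt)
  lay <- gfn("kkt_layout")(ctx)
  ini <- gfn("initial_fields")(ctx)
  st <- ini$state; ct <- ini$control
  smooth <- project_field(space, 2 * sin(space$qp$x / 7) *
                            cos(space$qp$y / 3))
  adj <- stats::setNames(rep(list(smooth), 4), c("n0", "np", "vx", "vy"))
  g <- gfn("kkt_gradient")(ctx, lay, st, ct, adj)
  y0 <- gfn("pack_y")(ctx, lay, st, ct)
  p0 <- gfn("pack_p")(ctx, lay, adj)
  dstate <- list(n0 = project_field(space, 0.3 * sin(space$qp$x / 9)),
                 np = project_field(space, cos(space$qp$x / 8)),
                 vx = project_field(space, 0.5 * sin(space$qp$x / 6 + 1)),
                 vy = project_field(space, 0.4 * cos(space$qp$x / 7)))
  dctrl <- list(fx = project_field(space, 0.3 * sin(space$qp$x / 11)),
                fy = numeric(space$ndof))
  dadj <- stats::setNames(rep(list(project_field(
    space, cos(space$qp$x / 5))), 4), c("n0", "np", "vx", "vy"))
  d <- c(gfn("pack_y")(ctx, lay, dstate, dctrl), gfn("pack_p")(ctx, lay, dadj))
  d <- d / sqrt(sum(d^2))
  Lfun <- function(yv, pv) {
    z <- gfn("unpack_y")(ctx, lay, yv, st, ct)
    pa <- gfn("unpack_p")(ctx, lay, pv, adj)
    val <- evaluate_objective(space, ps, z$state, z$control, tgt)$total
    R <- gfn("residual_blocks")(ctx, z$state, z$control)
    for (eq in lay$p_blocks)
      val <- val + sum(pa[[eq]][ctx$free[[eq]]] * R[[eq]][ctx$free[[eq]]])
    val
  }
  an <- sum(c(g$gy, g$gp) * d)
  eps <- c(1e-3, 3e-3, 1e-2)
  errs <- vapply(eps, function(e)
    abs((Lfun(y0 + e * d[seq_len(lay$ny)],
              p0 + e * d[lay$ny + seq_len(lay$np)]) -
           Lfun(y0 - e * d[seq_len(lay$ny)],
                p0 - e * d[lay$ny + seq_len(lay$np)])) / (2 * e) - an), 0)
  slope <- coef(lm(log(errs) ~ log(eps)))[2]
  expect_gt(slope, 1.5)
  expect_lt(slope, 2.5)
})

test_that("KKT system is symmetric and stationary where it should be", {
  space <- pipe_space()
  ps <- parameter_set(n_in = 0, n_out = 0)
  mt <- make_mt_density(space, "uniform", ps)
  tgt <- solve_predefined_velocity(space, 0, ps)
  ## zero data: the zero fields are exactly KKT-stationary
  it0 <- list(state = zero_state(space), control = zero_control(space),
              adjoint = NULL)
  ks <- assemble_kkt(space, ps, mt, it0, tgt)
  expect_lt(max(abs(ks$rhs)), 1e-8)
  ## saddle-point symmetry (exact Hessian => symmetric Newton matrix)
  asym <- Matrix::norm(ks$A - Matrix::t(ks$A), "F") / Matrix::norm(ks$A, "F")
  expect_lt(asym, 1e-10)

  ## symmetry also holds at a generic iterate with nonzero adjoint
  ps1 <- parameter_set()
  mt1 <- make_mt_density(space, "uniform", ps1)
  tgt1 <- pipe_target()
  set.seed(23)
  N <- space$ndof
  st <- zero_state(space)
  st$np <- rnorm(N, 2, 0.1); st$vx <- tgt1$vx; st$vy <- tgt1$vy
  adj <- stats::setNames(lapply(1:4, function(i) 0.1 * rnorm(N)),
                         c("n0", "np", "vx", "vy"))
  ks1 <- assemble_kkt(space, ps1, mt1,
                      list(state = st, control = zero_control(space),
                           adjoint = adj), tgt1)
  asym1 <- Matrix::norm(ks1$A - Matrix::t(ks1$A), "F") /
    Matrix::norm(ks1$A, "F")
  expect_lt(asym1, 1e-10)
})

test_that("KKT matrix blocks match finite differences of the gradient", {
  space <- pipe_space()
  ps <- parameter_set()
  mt <- make_mt_density(space, "uniform", ps)
  tgt <- pipe_target()
  N <- space$ndof
  set.seed(29)
  st <- zero_state(space)
  st$n0 <- rnorm(N, 0.3, 0.02); st$np <- rnorm(N, 2, 0.1)
  st$vx <- tgt$vx + 0.05 * rnorm(N); st$vy <- 0.05 * rnorm(N)
  ct <- zero_control(space); ct$fx <- 0.1 * rnorm(N)
  adj <- stats::setNames(lapply(1:4, function(i) 0.1 * rnorm(N)),
                         c("n0", "np", "vx", "vy"))
  it <- list(state = st, control = ct, adjoint = adj)
  ks <- assemble_kkt(space, ps, mt, it, tgt)
  st <- neurotransport:::impose_dirichlet(ks$ctx, st)  # A is built here
  h <- 1e-6
  nfull <- nrow(ks$A)
  set.seed(31)
  d <- rnorm(nfull); d <- d / sqrt(sum(d^2))
  Ad <- as.numeric(ks$A %*% d)
  ## directional FD of the full KKT residual (rhs = -residual)
  lay <- ks$layout
  perturb <- function(sgn) {
    z <- sgn * h * d
    ctx <- ks$ctx
    cand <- neurotransport:::unpack_y(ctx, lay, neurotransport:::pack_y(
      ctx, lay, st, ct) + z[seq_len(lay$ny)], st, ct)
    padj <- neurotransport:::unpack_p(ctx, lay, neurotransport:::pack_p(
      ctx, lay, adj) + z[lay$ny + seq_len(lay$np)], adj)
    g <- neurotransport:::kkt_gradient(ctx, lay, cand$state, cand$control,
                                       padj)
    c(g$gy, g$gp)
  }
  fd <- (perturb(1) - perturb(-1)) / (2 * h)
  expect_lt(max(abs(fd - Ad)) / max(abs(Ad)), 1e-5)
})

test_that("all-at-once solve converges on the normal pipe and is
          deterministic", {
  space <- pipe_space()
  ps <- parameter_set()
  mt <- make_mt_density(space, "uniform", ps)
  tgt <- pipe_target()
  s1 <- solve_pdeco(space, ps, mt, tgt)
  expect_true(s1$converged)
  expect_lte(s1$kkt_residual, 1e-7)
  s2 <- solve_pdeco(space, ps, mt, tgt)
  expect_identical(s1$history, s2$history)
  expect_identical(s1$state$np, s2$state$np)
  ## objective settles once the iterate is near-feasible
  h <- s1$history
  near <- which(h$kkt_residual < 1e-4)
  if (length(near) > 1) {
    J <- h$objective[near]
    expect_lt(max(diff(J)) / abs(J[1]), 1e-3)
  }
})

test_that("unknown-group contract: 4 unidirectional, 7 bidirectional", {
  expect_equal(n_unknown_groups(parameter_set()), 4L)
  expect_equal(n_unknown_groups(parameter_set(mode = "bidirectional")), 7L)
  ## the discrete fields mirror the contract
  space <- pipe_space()
  ps <- parameter_set(mode = "bidirectional")
  mt <- make_mt_density(space, "uniform", ps)
  tgt <- solve_predefined_velocity(space, 1.0, ps)
  st <- zero_state(space, ps); ct <- zero_control(space, ps)
  expect_equal(length(st) - 2L + length(ct) - 2L, 7L)  # field groups
  R <- assemble_constraint_residual(space, ps, mt, st, ct, tgt)
  expect_setequal(names(R), c("n0", "np", "nm", "vx", "vy", "wx", "wy"))
})

test_that("large-beta solutions recover the uncontrolled forward dynamics", {
  space <- pipe_space()
  ps <- parameter_set(beta = 1e6, n_time_steps = 8, T_horizon = 4)
  mt <- make_mt_density(space, "uniform", ps)
  tgt <- solve_predefined_velocity(space, 1.0, ps)
  solb <- solve_pdeco(space, ps, mt, tgt)
  expect_true(solb$converged)
  fwd <- forward_transport_solve(space, ps, mt, tgt, tol = 1e-11)
  expect_true(fwd$converged)
  for (b in names(fwd$state)) {
    denom <- max(sqrt(sum(fwd$state[[b]]^2)), 1e-8)
    expect_lt(sqrt(sum((solb$state[[b]] - fwd$state[[b]])^2)) / denom, 1e-3)
  }
  fn <- sqrt(sum(space$w * as.numeric(space$Phi %*% solb$control$fx)^2) +
               sum(space$w * as.numeric(space$Phi %*% solb$control$fy)^2))
  Vn <- sqrt(sum(space$w * as.numeric(space$Phi %*% tgt$vx)^2) +
               sum(space$w * as.numeric(space$Phi %*% tgt$vy)^2))
  expect_lt(fn / Vn, 1e-3)
})

test_that("objective differences contract under mesh refinement and the
          gradient integral falls with alpha", {
  ## The converged objective still drifts at desk resolutions because the
  ## inlet reaction layer (width ~ D/v ~ 0.1 um) stays unresolved; what must
  ## hold is that successive refinement changes shrink.
  ps <- parameter_set()
  mt_of <- function(space) make_mt_density(space, "uniform", ps)
  res <- lapply(c(0.25, 0.5, 1), function(ad) {
    space <- pipe_space(ad)
    tgt <- solve_predefined_velocity(space, 1.0, ps)
    solve_pdeco(space, ps, mt_of(space), tgt)
  })
  expect_true(all(vapply(res, function(s) s$converged, TRUE)))
  J <- vapply(res, function(s) s$objective$total, 0)
  expect_lt(abs(J[3] - J[2]), abs(J[2] - J[1]))

  space <- pipe_space()
  tgt <- pipe_target()
  grads <- vapply(c(1, 10, 100), function(a) {
    psa <- parameter_set(alpha = a)
    sol <- solve_pdeco(space, psa, make_mt_density(space, "uniform", psa),
                       tgt)
    sol$objective$gradient_term / a      # raw integral of |grad n|^2
  }, 0)
  expect_true(all(diff(grads) < 0))
})
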