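test_that("uniform attach/detach balance annihilates the steady residual", {
  space <- pipe_space()
  ps <- parameter_set()
  mt <- make_mt_density(space, "uniform", ps)
  tgt <- pipe_target()
  N <- space$ndof
  ## n+ = (k+ / (k'+ l+)) n0 = 10 n0 with the default parameters
  st <- list(n0 = rep(1, N), np = rep(10, N),
             vx = numeric(N), vy = numeric(N))
  R <- assemble_constraint_residual(space, ps, mt, st,
                                    zero_control(space), tgt)
  expect_lt(max(vapply(R, function(r) max(abs(r)), 0)), 1e-10)
})

test_that("zero state, control and boundary data give a zero residual", {
  space <- pipe_space()
  ps <- parameter_set(n_in = 0, n_out = 0)
  mt <- make_mt_density(space, "uniform", ps)
  tgt <- solve_predefined_velocity(space, 0, ps)
  R <- assemble_constraint_residual(space, ps, mt, zero_state(space),
                                    zero_control(space), tgt)
  expect_equal(max(vapply(R, function(r) max(abs(r)), 0)), 0)
})

test_that("pure advection residual matches an independent quadrature
          oracle", {
  space <- pipe_space()
  ps <- parameter_set(D_plus = 0, k_plus = 0, kprime_plus = 0,
                      stabilize = FALSE)
  mt <- make_mt_density(space, "uniform", ps)
  tgt <- pipe_target()
  N <- space$ndof
  cvel <- 0.7
  np <- project_field(space, function(qp) 0.5 + 0.03 * qp$x)  # linear in x
  st <- list(n0 = numeric(N), np = np,
             vx = rep(cvel, N), vy = numeric(N))
  R <- assemble_constraint_residual(space, ps, mt, st, zero_control(space),
                                    tgt, restricted = FALSE)
  ## oracle: residual_i = integral of phi_i * (v . grad n) with v, grad n
  ## constant; integral of each basis function by composite Simpson
  expected <- cvel * 0.03
  for (i in sample(seq_len(N), 8)) {
    e_i <- numeric(N); e_i[i] <- 1
    int_phi <- simpson_integral_pipe(space, e_i)
    expect_equal(R$np[i], expected * int_phi, tolerance = 1e-8)
  }
})

test_that("objective breakdown matches closed forms and scales linearly in
          the penalties", {
  space <- pipe_space()
  ps <- parameter_set()
  tgt <- pipe_target()
  N <- space$ndof
  st <- zero_state(space); ct <- zero_control(space)
  ## perfect tracking, constant concentration, zero control
  st$vx <- tgt$vx; st$vy <- tgt$vy; st$np <- rep(1.3, N)
  ob <- evaluate_objective(space, ps, st, ct, tgt)
  expect_equal(ob$total, 0, tolerance = 1e-12)

  ## v - V = 1 in x, f_x = 1 on the 320 um^2 pipe: 1/2 * area each
  st$vx <- tgt$vx + 1
  ct$fx <- rep(1, N)
  ob <- evaluate_objective(space, ps, st, ct, tgt)
  expect_equal(ob$tracking_term, 160, tolerance = 1e-9)
  expect_equal(ob$control_term, 160, tolerance = 1e-9)
  expect_equal(ob$gradient_term, 0, tolerance = 1e-12)
  expect_equal(ob$total,
               ob$tracking_term + ob$gradient_term + ob$control_term)

  ## doubling alpha doubles the gradient term, beta the control term
  set.seed(11)
  st$np <- project_field(space, function(qp) sin(qp$x / 10) + 0.1 * qp$y)
  ob1 <- evaluate_objective(space, ps, st, ct, tgt)
  ps2 <- parameter_set(alpha = 2, beta = 2)
  ob2 <- evaluate_objective(space, ps2, st, ct, tgt)
  expect_equal(ob2$gradient_term, 2 * ob1$gradient_term, tolerance = 1e-12)
  expect_equal(ob2$control_term, 2 * ob1$control_term, tolerance = 1e-12)
})

test_that("objective integrals agree with an independent Simpson
          quadrature", {
  space <- pipe_space()
  ps <- parameter_set()
  tgt <- pipe_target()
  set.seed(13)
  st <- zero_state(space); ct <- zero_control(space)
  st$vx <- project_field(space, function(qp) 0.3 * sin(qp$x / 11) + 0.4)
  st$np <- project_field(space, function(qp) cos(qp$x / 17) + 0.05 * qp$y)
  ct$fx <- project_field(space, function(qp) 0.2 * sin(qp$x / 23))
  ob <- evaluate_objective(space, ps, st, ct, tgt)
  ## oracle via pointwise Simpson integration of the squared fields
  track2 <- simpson_integral_pipe(space, st$vx - tgt$vx, n = 121)
  ## squared integrands need evaluation of squares, not of coefficients;
  ## integrate on a fine grid directly
  pa <- space$mesh$patches[[1]]
  n <- 161
  u <- seq(0, pa$n_u, length.out = n); v <- seq(0, pa$n_v, length.out = n)
  cell <- (mesh_area(space$mesh) / (pa$n_u * pa$n_v)) *
    (u[2] - u[1]) * (v[2] - v[1])
  acc_track <- 0; acc_ctrl <- 0
  for (j in seq_len(n)) {
    dv <- evaluate_field(space, st$vx - tgt$vx, 1, u, rep(v[j], n))$value
    df <- evaluate_field(space, ct$fx, 1, u, rep(v[j], n))$value
    wj <- if (j == 1 || j == n) 0.5 else 1
    wu <- rep(1, n); wu[c(1, n)] <- 0.5
    acc_track <- acc_track + wj * sum(wu * dv^2)
    acc_ctrl <- acc_ctrl + wj * sum(wu * df^2)
  }
  expect_equal(ob$tracking_term, acc_track * cell / 2, tolerance = 5e-3)
  expect_equal(ob$control_term, acc_ctrl * cell / 2, tolerance = 5e-3)
})

test_that("objective is invariant under rigid translation of the
          geometry", {
  sk <- make_synthetic_skeleton(pipe_spec())
  sk$nodes$x <- sk$nodes$x + 31; sk$nodes$y <- sk$nodes$y - 12
  sp2 <- build_spline_space(sweep_mesh(sk, 4, 0.25), 2)
  ps <- parameter_set()
  t1 <- pipe_target()
  t2 <- solve_predefined_velocity(sp2, 1.0, ps)
  space <- pipe_space()
  set.seed(17)
  co <- rnorm(space$ndof)
  st1 <- zero_state(space); st1$np <- co; st1$vx <- t1$vx + 0.3
  st2 <- zero_state(sp2); st2$np <- co; st2$vx <- t2$vx + 0.3
  ct1 <- zero_control(space); ct1$fx <- 0.5 * co
  ob1 <- evaluate_objective(space, ps, st1, ct1, t1)
  ob2 <- evaluate_objective(sp2, ps, st2, ct1, t2)
  expect_equal(ob2$total, ob1$total, tolerance = 1e-9)
})

test_that("steady bound-cargo transport balances its boundary fluxes", {
  ## converged normal solution: advective + diffusive outflow of m+ through
  ## inlet/outlets balances the net reactive exchange with the free pool
  space <- pipe_space()
  ps <- parameter_set()
  mt <- make_mt_density(space, "uniform", ps)
  tgt <- pipe_target()
  sol <- solve_pdeco(space, ps, mt, tgt)
  expect_true(sol$converged)
  lq <- as.numeric(space$Phi %*% mt$lp_coef)
  n0q <- as.numeric(space$Phi %*% sol$state$n0)
  npq <- as.numeric(space$Phi %*% sol$state$np)
  mpq <- lq * npq
  mpxq <- lq * as.numeric(space$Phix %*% sol$state$np) +
    npq * as.numeric(space$Phix %*% mt$lp_coef)
  mpyq <- lq * as.numeric(space$Phiy %*% sol$state$np) +
    npq * as.numeric(space$Phiy %*% mt$lp_coef)
  react <- sum(space$w * (ps$k_plus * lq * n0q - ps$kprime_plus * mpq))
  ## the advective form v . grad m is not in divergence form: the traffic
  ## velocity is compressible, so the budget carries a m div(v) volume term
  divv <- as.numeric(space$Phix %*% sol$state$vx) +
    as.numeric(space$Phiy %*% sol$state$vy)
  compress <- sum(space$w * mpq * divv)
  bflux <- 0
  for (tg in c("inlet", "wall",
               grep("^outlet:", names(space$bnd), value = TRUE))) {
    b <- space$bnd[[tg]]
    vxb <- as.numeric(b$Phib %*% sol$state$vx)
    vyb <- as.numeric(b$Phib %*% sol$state$vy)
    lb <- as.numeric(b$Phib %*% mt$lp_coef)
    npb <- as.numeric(b$Phib %*% sol$state$np)
    adv <- (lb * npb) * (vxb * b$nx + vyb * b$ny)
    diff_fl <- 0
    if (tg != "wall") {
      ## diffusive flux is zero on walls by construction of the weak form
      mxb <- lb * as.numeric(b$Phibx %*% sol$state$np) +
        npb * as.numeric(b$Phibx %*% mt$lp_coef)
      myb <- lb * as.numeric(b$Phiby %*% sol$state$np) +
        npb * as.numeric(b$Phiby %*% mt$lp_coef)
      diff_fl <- -ps$D_plus * (mxb * b$nx + myb * b$ny)
    }
    bflux <- bflux + sum(b$w * (adv + diff_fl))
  }
  ## the discrete identity: summing all rows of the bound-cargo residual
  ## (the constant test function; SUPG drops out) equals the strong-form
  ## budget, and at the converged solution the free rows vanish, so the
  ## whole imbalance sits in the strongly-imposed inlet rows
  Rfull <- assemble_constraint_residual(space, ps, mt, sol$state,
                                        sol$control, tgt,
                                        restricted = FALSE)
  budget <- bflux - compress - react
  scale <- max(abs(react), abs(bflux), abs(compress))
  ## at the converged solution every free residual row vanishes: the entire
  ## weak-form defect is carried by the strongly-imposed inlet rows, and the
  ## strong-form budget closes up to the quadrature error of the sextic
  ## integrands (the remaining few percent)
  inlet_dofs <- space$bnd$inlet$dofs
  free_sum <- sum(Rfull$np[-inlet_dofs])
  expect_lt(abs(free_sum) / scale, 1e-6)
  expect_lt(abs(budget - sum(Rfull$np)) / scale, 0.05)
  expect_lt(abs(budget) / scale, 0.08)
})
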