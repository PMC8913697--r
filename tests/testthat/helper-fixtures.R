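## Shared fixtures, built once per test run.  All geometries are synthetic
## and small: an 80 um straight pipe, a symmetric bifurcation, the 5-outlet
## study tree, and the swollen pipe used by the swirl scenario.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

pipe_spec <- function() geometry_spec("pipe", length = 80, base_radius = 2,
                                      spacing = 4)

swollen_spec <- function() geometry_spec(
  "swollen_pipe", length = 80, base_radius = 2, spacing = 2,
  swelling = list(s0 = 40, L2 = 20, amplification = 2))

pipe_space <- function(axial_density = 0.25)
  fixture(paste0("pipe_space_", axial_density), function() {
    sk <- make_synthetic_skeleton(pipe_spec())
    build_spline_space(sweep_mesh(sk, 4, axial_density), 2)
  })

pipe_target <- function()
  fixture("pipe_target", function()
    solve_predefined_velocity(pipe_space(), 1.0, parameter_set()))

bif_space <- function()
  fixture("bif_space", function() {
    sk <- make_synthetic_skeleton(
      geometry_spec("bifurcation", length = 40, base_radius = 2,
                    spacing = 5, branch_length = 30,
                    branch_angle = pi / 6))
    build_spline_space(sweep_mesh(sk, 4, 0.25), 2)
  })

tree_space <- function()
  fixture("tree_space", function() {
    sk <- make_synthetic_skeleton(tree_spec_5outlet())
    build_spline_space(sweep_mesh(sk, 2, 0.25), 2)
  })

zero_state <- function(space, params = parameter_set()) {
  sn <- if (params$mode == "bidirectional")
    c("n0", "np", "nm", "vx", "vy", "wx", "wy")
  else c("n0", "np", "vx", "vy")
  stats::setNames(rep(list(numeric(space$ndof)), length(sn)), sn)
}

zero_control <- function(space, params = parameter_set()) {
  cn <- if (params$mode == "bidirectional") c("fx", "fy", "gx", "gy")
  else c("fx", "fy")
  stats::setNames(rep(list(numeric(space$ndof)), length(cn)), cn)
}

## independent Simpson-rule integral of a spline coefficient field over one
## patch of a rectangular (pipe) mesh, used as a quadrature oracle
simpson_integral_pipe <- function(space, coef, n = 81) {
  pa <- space$mesh$patches[[1]]
  u <- seq(0, pa$n_u, length.out = n)
  v <- seq(0, pa$n_v, length.out = n)
  wts <- function(k) {
    w <- rep(c(4, 2), length.out = k - 2)
    c(1, w[-length(w)], 4, 1) / 3
  }
  wu <- wts(n) * (u[2] - u[1]); wv <- wts(n) * (v[2] - v[1])
  tot <- 0
  for (j in seq_len(n)) {
    ev <- evaluate_field(space, coef, 1, u, rep(v[j], n))
    tot <- tot + sum(wu * ev$value) * wv[j]
  }
  ## param-to-physical area scale of the uniform rectangular patch
  area <- mesh_area(space$mesh)
  tot * area / (pa$n_u * pa$n_v)
}
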