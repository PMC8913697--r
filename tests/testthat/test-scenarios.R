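## Scenario-level behaviour.  The full ordering contracts (parameter sweeps,
## swirl peaks, rerouting) live in test-acceptance.R; here we cover the
## configuration surface, the normal-transport baseline and the profile and
## export plumbing.

test_that("scenario configuration validates its inputs", {
  expect_error(scenario_config("swirl", params = parameter_set()),
               "bidirectional")
  expect_error(scenario_config("reduced_mt", depth = 1.2), "depth")
  expect_error(scenario_config("swirl",
                               geometry = pipe_spec(),
                               params = parameter_set(mode = "bidirectional")),
               "swollen")
  cfg <- scenario_config("normal")
  expect_s3_class(cfg, "scenario_config")
  expect_equal(cfg$params$n_time_steps, 8L)
})

test_that("normal pipe scenario: profile between boundary values, endpoints
          carry the Dirichlet data", {
  res <- fixture("normal_scenario", function()
    run_scenario(scenario_config("normal")))
  expect_true(res$solution$converged)
  pr <- res$diagnostics$profiles[[1]]
  expect_true(all(diff(pr$s) > 0))
  ## inlet: n0 + n+ = n_in + lambda_in n_in = 3
  expect_equal(pr$value[1], 3, tolerance = 1e-8)
  ## outlet: n0 pinned to n_out = 0, profile end is bound cargo only
  n0_end <- evaluate_field(res$space, res$solution$state$n0, 1,
                           res$space$mesh$patches[[1]]$n_u, 2)$value
  expect_equal(n0_end, 0, tolerance = 1e-9)
  ## no interior peak above the boundary values (healthy transport)
  expect_lt(max(pr$value), 3 * 1.05)
})

test_that("centerline profile integral agrees with an independent fine
          quadrature of the same line", {
  res <- fixture("normal_scenario", function()
    run_scenario(scenario_config("normal")))
  pr <- res$diagnostics$profiles[[1]]
  line_int <- sum(diff(pr$s) * (head(pr$value, -1) + tail(pr$value, -1)) / 2)
  ## oracle: composite Simpson on an independent, much finer sampling
  space <- res$space
  conc <- res$solution$state$n0 + res$solution$state$np
  pa <- space$mesh$patches[[1]]
  n <- 641
  u <- seq(0, pa$n_u, length.out = n)
  vals <- evaluate_field(space, conc, 1, u, rep(pa$n_v / 2, n))$value
  w <- rep(c(4, 2), length.out = n - 2); w <- c(1, w[-length(w)], 4, 1) / 3
  ds <- diff(pa$s_range) / pa$n_u * (u[2] - u[1])
  oracle <- sum(w * vals) * ds
  expect_equal(line_int, oracle, tolerance = 0.02)
})

test_that("vortex diagnostics recover a manufactured rigid rotation and
          reject unidirectional input", {
  space <- pipe_space()
  omega <- 0.35
  ctr <- c(40, 0)
  vx <- project_field(space, function(qp) -omega * (qp$y - ctr[2]))
  vy <- project_field(space, function(qp) omega * (qp$x - ctr[1]))
  N <- space$ndof
  fake <- list(space = space, region = NULL,
               solution = list(state = list(
                 n0 = numeric(N), np = numeric(N), nm = numeric(N),
                 vx = vx, vy = vy, wx = numeric(N), wy = numeric(N))))
  vd <- vortex_diagnostics(fake)
  expect_lt(max(abs(vd$curl - 2 * omega)), 1e-8)

  fake_uni <- fake
  fake_uni$solution$state$wx <- NULL
  expect_error(vortex_diagnostics(fake_uni), "bidirectional")
})

test_that("exports round-trip: VTK point data, profile CSV, manifest
          re-run", {
  res <- fixture("normal_scenario", function()
    run_scenario(scenario_config("normal")))
  out <- withr::local_tempdir()
  files <- export_result(res, path = out)
  expect_true(all(file.exists(files)))
  pd <- read_vtk_point_data(file.path(out, "normal.vtk"))
  orig <- neurotransport:::vertex_values(res$space, res$solution$state$np)
  expect_lt(max(abs(pd$np - orig)), 1e-7)
  prfile <- grep("profile_outlet", files, value = TRUE)[1]
  pr_csv <- read.csv(prfile)
  pr <- res$diagnostics$profiles[[1]]
  expect_equal(nrow(pr_csv), nrow(pr))
  res2 <- rerun_manifest(file.path(out, "normal_manifest.json"))
  expect_identical(res2$solution$history, res$solution$history)
})

test_that("scenario configs load from YAML and JSON", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("scenario: reduced_mt",
               "depth: 0.6",
               "region:", "  branch: 1", "  s: [25, 45]",
               "params:", "  alpha: 0.1", "  n_time_steps: 4",
               "  T_horizon: 8",
               "geometry:", "  kind: pipe", "  length: 60",
               "  base_radius: 2", "  spacing: 4"), f)
  cfg <- read_scenario_config(f)
  expect_equal(cfg$depth, 0.6)
  expect_equal(cfg$params$alpha, 0.1)
  expect_equal(cfg$geometry$length, 60)
  expect_equal(cfg$region$s, c(25, 45))
  fj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(scenario = "normal",
                            geometry = list(kind = "pipe", length = 40,
                                            base_radius = 2, spacing = 4)),
                       fj, auto_unbox = TRUE)
  cfg2 <- read_scenario_config(fj)
  expect_equal(cfg2$scenario, "normal")
  expect_equal(cfg2$geometry$length, 40)
})
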