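## Named experiment configurations: normal transport, microtubule-reduction
## traffic jams, and microtubule swirls with local swelling, plus the
## standard parameter sweeps.  A scenario bundles geometry, mesh resolution,
## microtubule field, solver options and the transient study horizon.

#' Synthetic study trees
#'
#' Fixed branched morphologies used as study stand-ins for real reconstructed
#' neuron trees: a 5-outlet and a 10-outlet planar binary tree.
#'
#' @return a \code{\link{geometry_spec}} of kind \code{"tree"}
#' @export
tree_spec_5outlet <- function() {
  geometry_spec("tree", base_radius = 1.5, spacing = 4,
                branches = data.frame(
                  parent = c(0, 1, 1, 2, 2, 3, 3, 4, 4),
                  length = c(40, 36, 36, 30, 30, 30, 30, 24, 24),
                  angle = c(0, 0.55, -0.55, 0.5, -0.35, 0.35, -0.5,
                            0.45, -0.3)))
}

#' @rdname tree_spec_5outlet
#' @export
tree_spec_10outlet <- function() {
  geometry_spec("tree", base_radius = 1.5, spacing = 4,
                branches = data.frame(
                  parent = c(0, 1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 6, 6, 7, 7,
                             8, 8, 9, 9),
                  length = c(36, 32, 32, 28, 28, 28, 28, 24, 24, 24, 24,
                             24, 24, 22, 22, 20, 20, 20, 20),
                  angle = c(0, 0.6, -0.6, 0.5, -0.35, 0.35, -0.5,
                            0.45, -0.3, 0.4, -0.35, 0.35, -0.45,
                            0.4, -0.3, 0.35, -0.3, 0.3, -0.35)))
}

#' Configure a transport scenario
#'
#' @param scenario \code{"normal"} (uniform microtubule density),
#'   \code{"reduced_mt"} (local density dip causing a traffic jam) or
#'   \code{"swirl"} (bidirectional microtubule swirl with local swelling)
#' @param geometry a \code{\link{geometry_spec}} or a \code{\link{skeleton}};
#'   defaults to the standard study geometry of the scenario: an 80 um pipe
#'   (normal/reduced_mt) or the same pipe with a mid-length swelling (swirl)
#' @param region jam/swirl region as \code{list(branch =, s = c(s1, s2))};
#'   chosen automatically when omitted (mid-pipe, adjacent to the first
#'   junction on trees, or the swelling extent)
#' @param depth,amplification,asymmetry,transition microtubule-field
#'   parameters, see \code{\link{make_mt_density}}
#' @param params a \code{\link{parameter_set}}; when omitted, the scenario's
#'   study configuration is used (transient backward-Euler horizon 16 s in 8
#'   steps on pipes, 96 s in 12 steps on trees; bidirectional for swirl)
#' @param n_transverse,axial_density,degree mesh and basis resolution
#' @param inflow_speed peak inlet speed of the predefined velocity, um/s
#' @param options a \code{\link{solver_options}}
#' @param seed integer seed forwarded to the solver
#' @return an object of class \code{"scenario_config"}
#' @export
scenario_config <- function(scenario = c("normal", "reduced_mt", "swirl"),
                            geometry = NULL, region = NULL, depth = 0.8,
                            amplification = 2, asymmetry = 0.5,
                            transition = NULL, params = NULL,
                            n_transverse = 4, axial_density = 0.25,
                            degree = 2, inflow_speed = 1.0,
                            options = solver_options(), seed = 1L) {
  scenario <- match.arg(scenario)
  if (is.null(geometry)) {
    geometry <- if (scenario == "swirl")
      geometry_spec("swollen_pipe", length = 80, base_radius = 2,
                    spacing = 2,
                    swelling = list(s0 = 40, L2 = 20, amplification = 2))
    else geometry_spec("pipe", length = 80, base_radius = 2, spacing = 4)
  }
  is_tree <- inherits(geometry, "geometry_spec") &&
    geometry$kind %in% c("tree", "bifurcation", "from_swc") ||
    inherits(geometry, "skeleton")
  if (is.null(params)) {
    params <- if (scenario == "swirl")
      parameter_set(mode = "bidirectional", n_time_steps = 8, T_horizon = 16)
    else if (is_tree)
      parameter_set(n_time_steps = 12, T_horizon = 96)
    else
      parameter_set(n_time_steps = 8, T_horizon = 16)
  }
  if (scenario == "swirl") {
    if (params$mode != "bidirectional")
      stop("configuration error: swirl scenarios require bidirectional mode")
    sw <- if (inherits(geometry, "geometry_spec")) geometry$swelling else NULL
    if (is.null(sw))
      stop("configuration error: swirl scenarios require a swollen geometry")
  }
  if (scenario == "reduced_mt" && (depth <= 0 || depth >= 1))
    stop("configuration error: reduced_mt depth must be in (0, 1)")
  structure(list(scenario = scenario, geometry = geometry, region = region,
                 depth = depth, amplification = amplification,
                 asymmetry = asymmetry, transition = transition,
                 params = params, n_transverse = n_transverse,
                 axial_density = axial_density, degree = degree,
                 inflow_speed = inflow_speed, options = options,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  gk <- if (inherits(x$geometry, "skeleton")) "skeleton" else x$geometry$kind
  cat("<scenario_config>", x$scenario, "on", gk, "geometry,",
      x$params$mode, "mode\n")
  invisible(x)
}

## default jam/swirl region for a meshed geometry
default_region <- function(config, mesh) {
  if (config$scenario == "swirl") {
    sw <- config$geometry$swelling
    return(list(branch = 1L, s = c(sw$s0 - sw$L2 / 2, sw$s0 + sw$L2 / 2)))
  }
  branches <- mesh$branches
  if (length(branches) == 1L) {
    b <- branches[[1]]
    mid <- b$s_start + b$length / 2
    return(list(branch = 1L, s = c(mid - 10, mid + 10)))
  }
  ## trees: the jam sits on the first child branch, directly downstream of
  ## the first junction (where it also perturbs the junction flux split)
  b <- branches[[2]]
  s0 <- b$s_start + 4
  list(branch = b$id, s = c(s0, s0 + 20))
}

#' Run a configured transport scenario
#'
#' Executes the full pipeline: geometry synthesis or import, skeleton-based
#' sweeping into a quadrilateral mesh, spline space construction, the
#' predefined-velocity flow solve, microtubule-density construction, the
#' all-at-once optimal-control solve, and standard diagnostics.
#'
#' @param config a \code{\link{scenario_config}}
#' @return an object of class \code{"scenario_result"} bundling the mesh,
#'   space, fields, \code{\link{solve_pdeco}} solution and diagnostics
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("scenario stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }
  skel <- stage("geometry",
                if (inherits(config$geometry, "skeleton")) config$geometry
                else make_synthetic_skeleton(config$geometry))
  mesh <- stage("meshing", sweep_mesh(skel, config$n_transverse,
                                      config$axial_density))
  space <- stage("spline", build_spline_space(mesh, config$degree))
  params <- config$params
  target <- stage("velocity",
                  solve_predefined_velocity(space, config$inflow_speed,
                                            params))
  region <- if (is.null(config$region)) default_region(config, mesh)
  else config$region
  mt <- stage("mt_density", switch(config$scenario,
    normal = make_mt_density(space, "uniform", params),
    reduced_mt = make_mt_density(space, "reduced", params, region = region,
                                 depth = config$depth,
                                 transition = config$transition),
    swirl = make_mt_density(space, "swirl", params, region = region,
                            amplification = config$amplification,
                            asymmetry = config$asymmetry,
                            transition = config$transition)))
  opts <- config$options
  opts$random_seed <- config$seed
  sol <- stage("optimize", solve_pdeco(space, params, mt, target,
                                       options = opts))
  res <- structure(list(config = config, skeleton = skel, mesh = mesh,
                        space = space, target = target, mt = mt,
                        region = region, solution = sol),
                   class = "scenario_result")
  res$diagnostics <- stage("diagnostics", scenario_diagnostics(res))
  res
}

## standard diagnostics: per-outlet centerline profiles + peak statistics
scenario_diagnostics <- function(res) {
  space <- res$space
  outlets <- grep("^outlet:", names(space$bnd), value = TRUE)
  outlet_ids <- as.integer(sub("^outlet:", "", outlets))
  profiles <- lapply(outlet_ids, function(oid)
    centerline_profile(res, oid))
  names(profiles) <- as.character(outlet_ids)
  p1 <- profiles[[1]]
  list(profiles = profiles,
       peak_concentration = max(p1$value),
       peak_s = p1$s[which.max(p1$value)],
       outlet_ids = outlet_ids)
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result>", x$config$scenario, "scenario -",
      if (x$solution$converged) "converged" else "NOT converged", "\n")
  cat(sprintf("  centerline peak %.4g mol/um^2 at s = %.3g um\n",
              x$diagnostics$peak_concentration, x$diagnostics$peak_s))
  print(x$solution$objective)
  invisible(x)
}

#' @export
summary.scenario_result <- function(object, ...) {
  print(object)
  summary(object$solution)
  invisible(object)
}

#' Plot centerline concentration profiles of a scenario result
#'
#' @param x a \code{scenario_result}
#' @param ... passed to \code{matplot}
#' @export
plot.scenario_result <- function(x, ...) {
  pr <- x$diagnostics$profiles
  graphics::matplot(pr[[1]]$s, sapply(pr, function(p)
    stats::approx(p$s, p$value, xout = pr[[1]]$s)$y),
    type = "l", lty = 1, xlab = "arc length s (um)",
    ylab = "concentration n0 + n+ (mol/um^2)",
    main = paste(x$config$scenario, "centerline profiles"), ...)
  invisible(x)
}

#' Parameter sweep over scenario configurations
#'
#' Re-runs a base scenario over a named grid of parameter values (for
#' example \code{list(alpha = c(1, 0.1, 0.01))}); mesh, spline space and
#' predefined velocity are built once and shared, so runs differ only in the
#' parameter set.  The default grid sweeps the gradient penalty alpha, the
#' control penalty beta and the attachment/detachment ratio k/k' (k fixed at
#' 1/s).
#'
#' @param base a \code{\link{scenario_config}}
#' @param grid named list of value vectors; names must be
#'   \code{parameter_set} fields or \code{"k_ratio"} (sweeps
#'   \code{kprime = k / value} with \code{k = 1})
#' @return a data.frame of class \code{"sweep_table"}: one row per grid
#'   point with the centerline peak concentration and location, objective
#'   terms and convergence flag
#' @export
parameter_sweep <- function(base,
                            grid = list(alpha = c(1, 0.1, 0.01),
                                        beta = c(1, 0.1, 0.01),
                                        k_ratio = c(1, 10, 100))) {
  stopifnot(inherits(base, "scenario_config"))
  for (nm in names(grid))
    if (!nm %in% c(names(parameter_set()), "k_ratio"))
      stop("unknown sweep parameter: ", nm)
  skel <- if (inherits(base$geometry, "skeleton")) base$geometry
  else make_synthetic_skeleton(base$geometry)
  mesh <- sweep_mesh(skel, base$n_transverse, base$axial_density)
  space <- build_spline_space(mesh, base$degree)
  target <- solve_predefined_velocity(space, base$inflow_speed, base$params)
  region <- if (is.null(base$region)) default_region(base, mesh)
  else base$region
  rows <- list()
  for (nm in names(grid)) for (val in grid[[nm]]) {
    params <- base$params
    if (nm == "k_ratio") {
      params$k_plus <- 1.0; params$kprime_plus <- 1.0 / val
      params$k_minus <- 1.0; params$kprime_minus <- 1.0 / val
    } else params[[nm]] <- val
    mt <- switch(base$scenario,
      normal = make_mt_density(space, "uniform", params),
      reduced_mt = make_mt_density(space, "reduced", params,
                                   region = region, depth = base$depth,
                                   transition = base$transition),
      swirl = make_mt_density(space, "swirl", params, region = region,
                              amplification = base$amplification,
                              asymmetry = base$asymmetry,
                              transition = base$transition))
    opts <- base$options
    opts$random_seed <- base$seed
    sol <- solve_pdeco(space, params, mt, target, options = opts)
    res <- structure(list(config = base, mesh = mesh, space = space,
                          target = target, mt = mt, region = region,
                          solution = sol), class = "scenario_result")
    first_outlet <- as.integer(sub("^outlet:", "",
                                   grep("^outlet:", names(space$bnd),
                                        value = TRUE)[1]))
    pr <- centerline_profile(res, first_outlet)
    rows[[length(rows) + 1L]] <-
      data.frame(parameter = nm, value = val,
                 peak_concentration = max(pr$value),
                 peak_s = pr$s[which.max(pr$value)],
                 tracking = sol$objective$tracking_term,
                 gradient = sol$objective$gradient_term,
                 control = sol$objective$control_term,
                 total = sol$objective$total,
                 converged = sol$converged)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_table", class(out))
  out
}
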