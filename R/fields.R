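## Prescribed fields: microtubule density distributions, the predefined
## velocity target from a steady incompressible flow solve, and the
## Stokes-Einstein diffusivity utility.

#' Stokes-Einstein diffusivity of a sphere
#'
#' D = kB T / (6 pi eta r), returned in um^2/s.  A 1 um sphere in water at
#' room temperature gives about 0.4 um^2/s, the reference value from which
#' the default cargo diffusivity (0.1 um^2/s, reduced for the crowded
#' cytoplasm) is derived.
#'
#' @param diameter particle diameter, um
#' @param temperature absolute temperature, K
#' @param dynamic_viscosity dynamic viscosity, Pa s
#' @return diffusivity in um^2/s
#' @export
stokes_einstein_diffusivity <- function(diameter, temperature = 298,
                                        dynamic_viscosity = 1.0e-3) {
  if (any(c(diameter, temperature, dynamic_viscosity) <= 0))
    stop("domain error: all Stokes-Einstein arguments must be positive")
  kB <- 1.380649e-23                      # J/K
  r_m <- diameter / 2 * 1e-6              # um -> m
  D_m2s <- kB * temperature / (6 * pi * dynamic_viscosity * r_m)
  D_m2s * 1e12                            # m^2/s -> um^2/s
}

#' Construct a microtubule density field
#'
#' The dimensionless densities \code{l+} and \code{l-} scale the transported
#' (bound) concentrations.  Three kinds are supported:
#' \itemize{
#'   \item \code{uniform}: \code{l+ = 1} everywhere (and \code{l- = 1} in
#'     bidirectional mode).
#'   \item \code{reduced}: \code{l+} dips smoothly (cubic smoothstep
#'     transitions) to \code{1 - depth} inside an axial region of one branch,
#'     modelling a local loss of microtubules.
#'   \item \code{swirl}: inside the region both densities are raised to
#'     \code{amplification} on the centerline with opposite transverse biases
#'     (\code{l+} larger towards the bottom wall \code{t = -1}, \code{l-}
#'     towards the top wall), modelling a counter-clockwise microtubule
#'     swirl; outside the region the densities relax to the uniform baseline.
#' }
#'
#' @param space a \code{spline_space}
#' @param kind \code{"uniform"}, \code{"reduced"} or \code{"swirl"}
#' @param params a \code{parameter_set} (supplies the transport mode)
#' @param region list with \code{branch} (branch id) and \code{s} (length-2
#'   arc-length interval, um from the inlet); required for reduced/swirl
#' @param depth dip depth in (0, 1) for \code{reduced}
#' @param amplification centerline density amplification (>= 1) for
#'   \code{swirl}
#' @param asymmetry transverse bias in [0, 1] for \code{swirl}
#' @param transition axial transition width, um (default a quarter of the
#'   region length)
#' @param minus_floor small positive floor on \code{l-} outside the swirl
#'   region (keeps the minus-direction equations non-degenerate where
#'   minus-directed microtubules are absent)
#' @return an object of class \code{"mt_density"} with evaluators
#'   \code{l_plus(qp)}/\code{l_minus(qp)} (taking a data.frame with columns
#'   \code{branch}, \code{s}, \code{t}) and cached spline projections used by
#'   the discretisation
#' @export
make_mt_density <- function(space, kind = c("uniform", "reduced", "swirl"),
                            params = parameter_set(), region = NULL,
                            depth = 0.8, amplification = 2, asymmetry = 0.5,
                            transition = NULL, minus_floor = 0.05) {
  kind <- match.arg(kind)
  bidir <- params$mode == "bidirectional"
  if (kind == "swirl" && !bidir)
    stop("configuration error: swirl densities require bidirectional mode")
  if (kind != "uniform") {
    if (is.null(region) || is.null(region$branch) || length(region$s) != 2)
      stop("configuration error: ", kind, " requires region$branch and region$s")
    if (kind == "reduced" && (depth <= 0 || depth >= 1))
      stop("configuration error: depth must be in (0, 1)")
    if (kind == "swirl" && (amplification < 1 || asymmetry < 0 || asymmetry > 1))
      stop("configuration error: amplification >= 1 and asymmetry in [0, 1]")
    s1 <- min(region$s); s2 <- max(region$s)
    if (is.null(transition)) transition <- (s2 - s1) / 4
  }
  l_plus <- switch(kind,
    uniform = function(qp) rep(1, nrow(qp)),
    reduced = function(qp) {
      g <- ifelse(qp$branch == region$branch,
                  plateau_profile(qp$s, s1, s2, transition), 0)
      1 - depth * g
    },
    swirl = function(qp) {
      g <- ifelse(qp$branch == region$branch,
                  plateau_profile(qp$s, s1, s2, transition), 0)
      pmax(1 + g * (amplification * (1 - asymmetry * qp$t) - 1), 0)
    })
  l_minus <- if (!bidir) {
    function(qp) rep(0, nrow(qp))
  } else if (kind == "swirl") {
    ## minus-directed tracks exist only inside the swirl region; a small
    ## positive floor keeps the minus equation non-degenerate outside
    function(qp) {
      g <- ifelse(qp$branch == region$branch,
                  plateau_profile(qp$s, s1, s2, transition), 0)
      pmax(minus_floor + g * (amplification * (1 + asymmetry * qp$t) -
                                minus_floor), 0)
    }
  } else {
    function(qp) rep(1, nrow(qp))
  }
  obj <- structure(list(kind = kind, region = region, depth = depth,
                        amplification = amplification, asymmetry = asymmetry,
                        transition = if (kind == "uniform") NULL else transition,
                        bidirectional = bidir,
                        l_plus = l_plus, l_minus = l_minus),
                   class = "mt_density")
  ## spline projections (smooth, differentiable representation on the basis)
  obj$lp_coef <- project_field(space, l_plus(space$qp))
  obj$lm_coef <- if (bidir) project_field(space, l_minus(space$qp)) else NULL
  obj
}

#' @export
print.mt_density <- function(x, ...) {
  cat("<mt_density> kind =", x$kind,
      if (x$bidirectional) "(bidirectional)" else "(unidirectional)", "\n")
  if (!is.null(x$region))
    cat(sprintf("  region: branch %s, s in [%.3g, %.3g] um\n",
                x$region$branch, min(x$region$s), max(x$region$s)))
  invisible(x)
}

## boundary transverse coordinate from edge geometry (for inlet profiles);
## valid for a tag consisting of a single straight cross-section
edge_transverse <- function(b) {
  ctr <- c(mean(range(b$x)), mean(range(b$y)))
  d <- cbind(b$x - ctr[1], b$y - ctr[2])
  e <- sqrt(d[, 1]^2 + d[, 2]^2)
  half <- sum(b$w) / 2                     # edge length / 2
  sgn <- sign(d[, 1] * (-b$ny) + d[, 2] * b$nx)   # along-edge direction
  sgn * e / half
}

## L2-project boundary values onto the edge dofs of a tag
project_boundary <- function(space, tag, values) {
  b <- space$bnd[[tag]]
  dofs <- b$dofs
  Pb <- b$Phib[, dofs, drop = FALSE]
  Mb <- Matrix::crossprod(Pb, Pb * b$w)
  rhs <- Matrix::crossprod(Pb, values * b$w)
  as.numeric(Matrix::solve(Mb, rhs))
}

#' Integrated normal flux of a vector field through a boundary tag
#'
#' @param space a \code{spline_space}
#' @param vx,vy coefficient vectors of the field components
#' @param tag boundary tag name
#' @return scalar flux (positive outward)
#' @export
boundary_flux <- function(space, vx, vy, tag) {
  b <- space$bnd[[tag]]
  un <- as.numeric(b$Phib %*% vx) * b$nx + as.numeric(b$Phib %*% vy) * b$ny
  sum(b$w * un)
}

#' Solve the predefined transport velocity target
#'
#' Solves steady incompressible flow on the tube domain with a parabolic
#' inlet profile of peak \code{inflow_speed}, no-slip walls and traction-free
#' outlets, using equal-order velocity/pressure on the spline space with
#' pressure-Laplacian stabilization and Newton iterations started from the
#' Stokes solution.  The resulting velocity is the tracking target \code{V+}
#' of the optimization; in bidirectional mode \code{V-} is its negation.
#'
#' @param space a \code{spline_space}
#' @param inflow_speed peak inlet speed, um/s
#' @param params a \code{parameter_set} (supplies the mode)
#' @param nu flow kinematic viscosity used for the target solve (um^2/s)
#' @param tol nonlinear residual tolerance
#' @param max_iter Newton iteration cap
#' @return object of class \code{"velocity_target"} with coefficient vectors
#'   \code{vx}, \code{vy} (and \code{vmx}, \code{vmy} in bidirectional mode)
#' @export
solve_predefined_velocity <- function(space, inflow_speed = 1.0,
                                      params = parameter_set(), nu = 1.0,
                                      tol = 1e-10, max_iter = 25) {
  N <- space$ndof
  if (inflow_speed == 0) {
    tgt <- list(vx = numeric(N), vy = numeric(N), inflow_speed = 0, nu = nu)
    if (params$mode == "bidirectional") { tgt$vmx <- numeric(N); tgt$vmy <- numeric(N) }
    class(tgt) <- "velocity_target"
    return(tgt)
  }
  Phi <- space$Phi; Phix <- space$Phix; Phiy <- space$Phiy; w <- space$w
  K <- Matrix::crossprod(Phix, Phix * w) + Matrix::crossprod(Phiy, Phiy * w)
  ## mixed discretisation: velocity on the given (quadratic) space, pressure
  ## on a degree-1 space over the same mesh (Taylor-Hood style, inf-sup
  ## stable); if the velocity space is itself degree 1, fall back to
  ## equal-order with a small pressure-Laplacian stabilization
  if (space$degree > 1L) {
    pspace <- build_spline_space(space$mesh, 1L)
    Php <- pspace$Phi; Phpx <- pspace$Phix; Phpy <- pspace$Phiy
    Np <- pspace$ndof
    Kp <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = c(Np, Np))
  } else {
    Php <- Phi; Phpx <- Phix; Phpy <- Phiy
    Np <- space$ndof
    el_area <- tapply(w, space$qp$element, sum)
    h_q <- sqrt(as.numeric(el_area))[space$qp$element]
    delta <- 0.01 * h_q^2 / nu
    Kp <- Matrix::crossprod(Phpx, Phpx * (w * delta)) +
      Matrix::crossprod(Phpy, Phpy * (w * delta))
  }
  Dx <- Matrix::crossprod(Php, Phix * w)      # q * dux/dx
  Dy <- Matrix::crossprod(Php, Phiy * w)
  Gx <- Matrix::crossprod(Phix, Php * w)      # dphi/dx * p
  Gy <- Matrix::crossprod(Phiy, Php * w)

  ## Dirichlet data: parabolic inlet along the inlet direction, no-slip walls
  bin <- space$bnd$inlet
  if (is.null(bin)) stop("solver error: space has no inlet boundary")
  tcoord <- edge_transverse(bin)
  ## inlet direction: inward normal
  din <- c(-mean(bin$nx), -mean(bin$ny)); din <- din / sqrt(sum(din^2))
  prof <- inflow_speed * (1 - tcoord^2)
  gin_x <- project_boundary(space, "inlet", prof * din[1])
  gin_y <- project_boundary(space, "inlet", prof * din[2])
  fix <- sort(unique(c(space$bnd$inlet$dofs, space$bnd$wall$dofs)))
  gx_val <- numeric(N); gy_val <- numeric(N)
  gx_val[bin$dofs] <- gin_x; gy_val[bin$dofs] <- gin_y
  ## wall dofs stay zero; inlet corners shared with walls: keep no-slip there
  wall_dofs <- space$bnd$wall$dofs
  gx_val[intersect(bin$dofs, wall_dofs)] <- 0
  gy_val[intersect(bin$dofs, wall_dofs)] <- 0
  free_u <- setdiff(seq_len(N), fix)

  ux <- gx_val; uy <- gy_val; pr <- numeric(Np)
  idx_ux <- seq_len(length(free_u))
  idx_uy <- length(free_u) + idx_ux
  idx_p <- 2 * length(free_u) + seq_len(Np)
  for (it in seq_len(max_iter)) {
    uxq <- as.numeric(Phi %*% ux); uyq <- as.numeric(Phi %*% uy)
    uxxq <- as.numeric(Phix %*% ux); uxyq <- as.numeric(Phiy %*% ux)
    uyxq <- as.numeric(Phix %*% uy); uyyq <- as.numeric(Phiy %*% uy)
    r_mx <- nu * (K %*% ux) - Gx %*% pr +
      Matrix::crossprod(Phi, w * (uxq * uxxq + uyq * uxyq))
    r_my <- nu * (K %*% uy) - Gy %*% pr +
      Matrix::crossprod(Phi, w * (uxq * uyxq + uyq * uyyq))
    r_c <- Dx %*% ux + Dy %*% uy + Kp %*% pr
    res <- c(as.numeric(r_mx)[free_u], as.numeric(r_my)[free_u],
             as.numeric(r_c))
    if (sqrt(sum(res^2)) < tol) break
    Axx <- nu * K + Matrix::crossprod(Phi, (Phix * (w * uxq)) +
                                        (Phiy * (w * uyq))) +
      Matrix::crossprod(Phi, Phi * (w * uxxq))
    Axy <- Matrix::crossprod(Phi, Phi * (w * uxyq))
    Ayx <- Matrix::crossprod(Phi, Phi * (w * uyxq))
    Ayy <- nu * K + Matrix::crossprod(Phi, (Phix * (w * uxq)) +
                                        (Phiy * (w * uyq))) +
      Matrix::crossprod(Phi, Phi * (w * uyyq))
    A <- rbind(
      cbind(Axx[free_u, free_u], Axy[free_u, free_u], -Gx[free_u, ]),
      cbind(Ayx[free_u, free_u], Ayy[free_u, free_u], -Gy[free_u, ]),
      cbind(Dx[, free_u], Dy[, free_u], Kp))
    dz <- as.numeric(Matrix::solve(A, -res))
    ux[free_u] <- ux[free_u] + dz[idx_ux]
    uy[free_u] <- uy[free_u] + dz[idx_uy]
    pr <- pr + dz[idx_p]
    if (it == max_iter) {
      rn <- sqrt(sum(res^2))
      if (rn > 1e-6)
        stop("solver error: flow solve did not converge (residual ",
             signif(rn, 3), ")")
    }
  }
  tgt <- list(vx = ux, vy = uy, pressure = pr, inflow_speed = inflow_speed,
              nu = nu)
  if (params$mode == "bidirectional") { tgt$vmx <- -ux; tgt$vmy <- -uy }
  class(tgt) <- "velocity_target"
  tgt
}

#' @export
print.velocity_target <- function(x, ...) {
  cat("<velocity_target> peak inflow", x$inflow_speed, "um/s",
      if (!is.null(x$vmx)) "(bidirectional)" else "", "\n")
  invisible(x)
}
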