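## Discrete weak forms of the transport constraints and the control
## objective.  State fields (free concentration n0, bound concentrations
## n+/n-, transport velocities v+/v-) and control forces f+/f- are
## coefficient vectors on one spline space; all integrals are evaluated
## through the cached quadrature operators Phi/Phix/Phiy.  The advective
## equations carry optional SUPG stabilization with the wind frozen at the
## predefined velocity, so the discrete system stays exactly differentiable.

state_names <- function(params) {
  if (params$mode == "bidirectional")
    c("n0", "np", "nm", "vx", "vy", "wx", "wy")
  else c("n0", "np", "vx", "vy")
}

control_names <- function(params) {
  if (params$mode == "bidirectional") c("fx", "fy", "gx", "gy")
  else c("fx", "fy")
}

## context with cached quadrature values, stabilization operators and
## Dirichlet bookkeeping
make_transport_ctx <- function(space, params, mt, target) {
  stopifnot(inherits(space, "spline_space"), inherits(params, "parameter_set"),
            inherits(mt, "mt_density"))
  bidir <- params$mode == "bidirectional"
  if (bidir && is.null(mt$lm_coef))
    stop("configuration error: bidirectional mode needs a bidirectional mt_density")
  if (!bidir && mt$bidirectional)
    stop("configuration error: mt_density was built for bidirectional mode")
  Phi <- space$Phi; Phix <- space$Phix; Phiy <- space$Phiy; w <- space$w
  N <- space$ndof
  ctx <- list(space = space, params = params, mt = mt, target = target,
              N = N, Phi = Phi, Phix = Phix, Phiy = Phiy, w = w,
              bidir = bidir)
  ctx$M <- Matrix::crossprod(Phi, Phi * w)
  ctx$Ks <- Matrix::crossprod(Phix, Phix * w) +
    Matrix::crossprod(Phiy, Phiy * w)
  ## microtubule density at quadrature points (spline-projected, smooth)
  ctx$lq <- as.numeric(Phi %*% mt$lp_coef)
  ctx$lxq <- as.numeric(Phix %*% mt$lp_coef)
  ctx$lyq <- as.numeric(Phiy %*% mt$lp_coef)
  if (bidir) {
    ctx$lmq <- as.numeric(Phi %*% mt$lm_coef)
    ctx$lmxq <- as.numeric(Phix %*% mt$lm_coef)
    ctx$lmyq <- as.numeric(Phiy %*% mt$lm_coef)
  }
  ## target velocity at quadrature points
  ctx$Vxq <- as.numeric(Phi %*% target$vx)
  ctx$Vyq <- as.numeric(Phi %*% target$vy)
  if (bidir) {
    ctx$Vmxq <- as.numeric(Phi %*% target$vmx)
    ctx$Vmyq <- as.numeric(Phi %*% target$vmy)
  }
  ## SUPG operators (wind frozen at the target velocity)
  el_area <- tapply(w, space$qp$element, sum)
  h_q <- sqrt(as.numeric(el_area))[space$qp$element]
  supg_op <- function(Vx, Vy, D) {
    if (!params$stabilize)
      return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                  x = numeric(0), dims = dim(Phi)))
    spd <- sqrt(Vx^2 + Vy^2)
    Pe <- spd * h_q / (2 * max(D, 1e-12))
    tau <- ifelse(spd > 1e-12, h_q / (2 * spd) * pmin(1, Pe / 3), 0)
    (Phix * (tau * Vx)) + (Phiy * (tau * Vy))
  }
  ctx$Wc <- Phi + supg_op(ctx$Vxq, ctx$Vyq, params$D_plus)
  ctx$Wv <- Phi + supg_op(ctx$Vxq, ctx$Vyq, params$mu)
  if (bidir) {
    ctx$Wcm <- Phi + supg_op(ctx$Vmxq, ctx$Vmyq, params$D_minus)
    ctx$Wvm <- Phi + supg_op(ctx$Vmxq, ctx$Vmyq, params$mu)
  }
  ## Dirichlet sets
  outlet_tags <- grep("^outlet:", names(space$bnd), value = TRUE)
  inlet_dofs <- space$bnd$inlet$dofs
  outlet_dofs <- sort(unique(unlist(lapply(outlet_tags,
                                           function(tg) space$bnd[[tg]]$dofs))))
  dirichlet <- list()
  dirichlet$n0 <- list(idx = c(inlet_dofs, outlet_dofs),
                       val = c(rep(params$n_in, length(inlet_dofs)),
                               rep(params$n_out, length(outlet_dofs))))
  dirichlet$np <- list(idx = inlet_dofs,
                       val = rep(params$lambda_in * params$n_in,
                                 length(inlet_dofs)))
  dirichlet$vx <- list(idx = inlet_dofs, val = target$vx[inlet_dofs])
  dirichlet$vy <- list(idx = inlet_dofs, val = target$vy[inlet_dofs])
  if (bidir) {
    dirichlet$nm <- list(idx = outlet_dofs,
                         val = rep(params$lambda_out * params$n_out,
                                   length(outlet_dofs)))
    dirichlet$wx <- list(idx = inlet_dofs, val = target$vmx[inlet_dofs])
    dirichlet$wy <- list(idx = inlet_dofs, val = target$vmy[inlet_dofs])
  }
  sn <- state_names(params); cn <- control_names(params)
  free <- list()
  for (b in sn) {
    d <- dirichlet[[b]]
    free[[b]] <- if (is.null(d)) seq_len(N) else setdiff(seq_len(N), d$idx)
  }
  for (b in cn) free[[b]] <- seq_len(N)
  ctx$dirichlet <- dirichlet
  ctx$free <- free
  ctx$state_names <- sn
  ctx$control_names <- cn
  ctx
}

## impose Dirichlet values on a state list
impose_dirichlet <- function(ctx, st) {
  for (b in names(ctx$dirichlet)) {
    d <- ctx$dirichlet[[b]]
    st[[b]][d$idx] <- d$val
  }
  st
}

## default initial fields: velocities at the target, concentrations linear in
## arc length between the boundary data, controls zero
initial_fields <- function(ctx) {
  p <- ctx$params; N <- ctx$N
  smax <- max(ctx$space$qp$s)
  lin <- function(a, b) project_field(ctx$space,
                                      a + (b - a) * ctx$space$qp$s / smax)
  st <- list(n0 = lin(p$n_in, p$n_out),
             np = lin(p$lambda_in * p$n_in, 0),
             vx = ctx$target$vx, vy = ctx$target$vy)
  if (ctx$bidir) {
    st$nm <- lin(0, p$lambda_out * p$n_out)
    st$wx <- ctx$target$vmx; st$wy <- ctx$target$vmy
  }
  st <- impose_dirichlet(ctx, st[ctx$state_names])
  ct <- stats::setNames(rep(list(numeric(N)), length(ctx$control_names)),
                        ctx$control_names)
  list(state = st, control = ct)
}

## pointwise field evaluations used by residual/jacobian/hessian
point_values <- function(ctx, st, ct) {
  Phi <- ctx$Phi; Phix <- ctx$Phix; Phiy <- ctx$Phiy
  pv <- list()
  for (b in names(st)) {
    pv[[b]] <- as.numeric(Phi %*% st[[b]])
    pv[[paste0(b, "_x")]] <- as.numeric(Phix %*% st[[b]])
    pv[[paste0(b, "_y")]] <- as.numeric(Phiy %*% st[[b]])
  }
  for (b in names(ct)) pv[[b]] <- as.numeric(Phi %*% ct[[b]])
  ## bound concentrations m = l n and their gradients
  pv$mp <- ctx$lq * pv$np
  pv$mp_x <- ctx$lq * pv$np_x + ctx$lxq * pv$np
  pv$mp_y <- ctx$lq * pv$np_y + ctx$lyq * pv$np
  if (ctx$bidir) {
    pv$mm <- ctx$lmq * pv$nm
    pv$mm_x <- ctx$lmq * pv$nm_x + ctx$lmxq * pv$nm
    pv$mm_y <- ctx$lmq * pv$nm_y + ctx$lmyq * pv$nm
  }
  pv
}

## full (unrestricted) residual blocks of the discrete constraints
residual_blocks <- function(ctx, st, ct, prev = NULL, dt = NULL) {
  p <- ctx$params; w <- ctx$w
  pv <- point_values(ctx, st, ct)
  pvp <- if (!is.null(prev)) point_values(ctx, prev, ct) else NULL
  tderiv <- function(cur, old) if (is.null(dt)) 0 else (cur - old) / dt
  R <- list()
  ## free concentration: mass-weak reaction balance; attachment scales with
  ## the local track density l
  katt <- p$k_plus * ctx$lq
  if (ctx$bidir) katt <- katt + p$k_minus * ctx$lmq
  r0 <- katt * pv$n0 - p$kprime_plus * pv$mp
  if (ctx$bidir) r0 <- r0 - p$kprime_minus * pv$mm
  if (!is.null(dt)) r0 <- r0 + tderiv(pv$n0, pvp$n0)
  R$n0 <- as.numeric(Matrix::crossprod(ctx$Phi, w * r0))
  ## bound concentration (+): advection-diffusion-reaction in m+ = l+ n+
  rc <- pv$vx * pv$mp_x + pv$vy * pv$mp_y +
    p$kprime_plus * pv$mp - p$k_plus * ctx$lq * pv$n0
  if (!is.null(dt)) rc <- rc + tderiv(pv$mp, pvp$mp)
  R$np <- as.numeric(Matrix::crossprod(ctx$Wc, w * rc)) +
    p$D_plus * (as.numeric(Matrix::crossprod(ctx$Phix, w * pv$mp_x)) +
                  as.numeric(Matrix::crossprod(ctx$Phiy, w * pv$mp_y)))
  ## traffic-flow momentum (+)
  rvx <- pv$vx * pv$vx_x + pv$vy * pv$vx_y + pv$np_x - pv$fx
  rvy <- pv$vx * pv$vy_x + pv$vy * pv$vy_y + pv$np_y - pv$fy
  if (!is.null(dt)) {
    rvx <- rvx + tderiv(pv$vx, pvp$vx); rvy <- rvy + tderiv(pv$vy, pvp$vy)
  }
  R$vx <- as.numeric(Matrix::crossprod(ctx$Wv, w * rvx)) +
    p$mu * (as.numeric(Matrix::crossprod(ctx$Phix, w * pv$vx_x)) +
              as.numeric(Matrix::crossprod(ctx$Phiy, w * pv$vx_y)))
  R$vy <- as.numeric(Matrix::crossprod(ctx$Wv, w * rvy)) +
    p$mu * (as.numeric(Matrix::crossprod(ctx$Phix, w * pv$vy_x)) +
              as.numeric(Matrix::crossprod(ctx$Phiy, w * pv$vy_y)))
  if (ctx$bidir) {
    rcm <- pv$wx * pv$mm_x + pv$wy * pv$mm_y +
      p$kprime_minus * pv$mm - p$k_minus * ctx$lmq * pv$n0
    if (!is.null(dt)) rcm <- rcm + tderiv(pv$mm, pvp$mm)
    R$nm <- as.numeric(Matrix::crossprod(ctx$Wcm, w * rcm)) +
      p$D_minus * (as.numeric(Matrix::crossprod(ctx$Phix, w * pv$mm_x)) +
                     as.numeric(Matrix::crossprod(ctx$Phiy, w * pv$mm_y)))
    rwx <- pv$wx * pv$wx_x + pv$wy * pv$wx_y + pv$nm_x - pv$gx
    rwy <- pv$wx * pv$wy_x + pv$wy * pv$wy_y + pv$nm_y - pv$gy
    if (!is.null(dt)) {
      rwx <- rwx + tderiv(pv$wx, pvp$wx); rwy <- rwy + tderiv(pv$wy, pvp$wy)
    }
    R$wx <- as.numeric(Matrix::crossprod(ctx$Wvm, w * rwx)) +
      p$mu * (as.numeric(Matrix::crossprod(ctx$Phix, w * pv$wx_x)) +
                as.numeric(Matrix::crossprod(ctx$Phiy, w * pv$wx_y)))
    R$wy <- as.numeric(Matrix::crossprod(ctx$Wvm, w * rwy)) +
      p$mu * (as.numeric(Matrix::crossprod(ctx$Phix, w * pv$wy_x)) +
                as.numeric(Matrix::crossprod(ctx$Phiy, w * pv$wy_y)))
  }
  R[ctx$state_names]
}

## Jacobian blocks d R[eq] / d field; returns nested list jac[[eq]][[var]]
jacobian_blocks <- function(ctx, st, ct, dt = NULL) {
  p <- ctx$params; w <- ctx$w
  Phi <- ctx$Phi; Phix <- ctx$Phix; Phiy <- ctx$Phiy
  pv <- point_values(ctx, st, ct)
  W <- function(A, d) Matrix::crossprod(A, Phi * (w * d))
  Wg <- function(A, d, G) Matrix::crossprod(A, G * (w * d))
  ## derivative operators of m+ and grad m+ w.r.t. the n+ coefficients
  L0 <- Phi * ctx$lq
  Lx <- Phix * ctx$lq + Phi * ctx$lxq
  Ly <- Phiy * ctx$lq + Phi * ctx$lyq
  katt <- p$k_plus * ctx$lq
  if (ctx$bidir) katt <- katt + p$k_minus * ctx$lmq
  idt <- if (is.null(dt)) 0 else 1 / dt
  J <- list()
  ## n0 equation
  J$n0 <- list(
    n0 = Matrix::crossprod(Phi, Phi * (w * (katt + idt))),
    np = -p$kprime_plus * Matrix::crossprod(Phi, L0 * w))
  ## n+ equation
  Anp <- Matrix::crossprod(ctx$Wc, (Lx * (w * pv$vx)) + (Ly * (w * pv$vy)) +
                             L0 * (w * (p$kprime_plus + idt))) +
    p$D_plus * (Matrix::crossprod(Phix, Lx * w) +
                  Matrix::crossprod(Phiy, Ly * w))
  J$np <- list(
    n0 = -p$k_plus * Matrix::crossprod(ctx$Wc, Phi * (w * ctx$lq)),
    np = Anp,
    vx = Matrix::crossprod(ctx$Wc, Phi * (w * pv$mp_x)),
    vy = Matrix::crossprod(ctx$Wc, Phi * (w * pv$mp_y)))
  ## v+ equations
  conv_diag <- Matrix::crossprod(ctx$Wv, (Phix * (w * pv$vx)) +
                                   (Phiy * (w * pv$vy)))
  visc <- p$mu * (Matrix::crossprod(Phix, Phix * w) +
                    Matrix::crossprod(Phiy, Phiy * w))
  J$vx <- list(
    np = Matrix::crossprod(ctx$Wv, Phix * w),
    vx = conv_diag + Matrix::crossprod(ctx$Wv, Phi * (w * (pv$vx_x + idt))) + visc,
    vy = Matrix::crossprod(ctx$Wv, Phi * (w * pv$vx_y)),
    fx = -Matrix::crossprod(ctx$Wv, Phi * w))
  J$vy <- list(
    np = Matrix::crossprod(ctx$Wv, Phiy * w),
    vx = Matrix::crossprod(ctx$Wv, Phi * (w * pv$vy_x)),
    vy = conv_diag + Matrix::crossprod(ctx$Wv, Phi * (w * (pv$vy_y + idt))) + visc,
    fy = -Matrix::crossprod(ctx$Wv, Phi * w))
  if (ctx$bidir) {
    Lm0 <- Phi * ctx$lmq
    Lmx <- Phix * ctx$lmq + Phi * ctx$lmxq
    Lmy <- Phiy * ctx$lmq + Phi * ctx$lmyq
    J$n0$nm <- -p$kprime_minus * Matrix::crossprod(Phi, Lm0 * w)
    Anm <- Matrix::crossprod(ctx$Wcm, (Lmx * (w * pv$wx)) +
                               (Lmy * (w * pv$wy)) +
                               Lm0 * (w * (p$kprime_minus + idt))) +
      p$D_minus * (Matrix::crossprod(Phix, Lmx * w) +
                     Matrix::crossprod(Phiy, Lmy * w))
    J$nm <- list(
      n0 = -p$k_minus * Matrix::crossprod(ctx$Wcm, Phi * (w * ctx$lmq)),
      nm = Anm,
      wx = Matrix::crossprod(ctx$Wcm, Phi * (w * pv$mm_x)),
      wy = Matrix::crossprod(ctx$Wcm, Phi * (w * pv$mm_y)))
    conv_m <- Matrix::crossprod(ctx$Wvm, (Phix * (w * pv$wx)) +
                                  (Phiy * (w * pv$wy)))
    J$wx <- list(
      nm = Matrix::crossprod(ctx$Wvm, Phix * w),
      wx = conv_m + Matrix::crossprod(ctx$Wvm, Phi * (w * (pv$wx_x + idt))) + visc,
      wy = Matrix::crossprod(ctx$Wvm, Phi * (w * pv$wx_y)),
      gx = -Matrix::crossprod(ctx$Wvm, Phi * w))
    J$wy <- list(
      nm = Matrix::crossprod(ctx$Wvm, Phiy * w),
      wx = Matrix::crossprod(ctx$Wvm, Phi * (w * pv$wy_x)),
      wy = conv_m + Matrix::crossprod(ctx$Wvm, Phi * (w * (pv$wy_y + idt))) + visc,
      gy = -Matrix::crossprod(ctx$Wvm, Phi * w))
  }
  J[ctx$state_names]
}

## objective gradient blocks over state and control fields
objective_gradient <- function(ctx, st, ct, weight = 1) {
  p <- ctx$params
  g <- list()
  g$n0 <- numeric(ctx$N)
  g$np <- weight * p$alpha * as.numeric(ctx$Ks %*% st$np)
  g$vx <- weight * as.numeric(ctx$M %*% (st$vx - ctx$target$vx))
  g$vy <- weight * as.numeric(ctx$M %*% (st$vy - ctx$target$vy))
  g$fx <- weight * p$beta * as.numeric(ctx$M %*% ct$fx)
  g$fy <- weight * p$beta * as.numeric(ctx$M %*% ct$fy)
  if (ctx$bidir) {
    g$nm <- weight * p$alpha * as.numeric(ctx$Ks %*% st$nm)
    g$wx <- weight * as.numeric(ctx$M %*% (st$wx - ctx$target$vmx))
    g$wy <- weight * as.numeric(ctx$M %*% (st$wy - ctx$target$vmy))
    g$gx <- weight * p$beta * as.numeric(ctx$M %*% ct$gx)
    g$gy <- weight * p$beta * as.numeric(ctx$M %*% ct$gy)
  }
  g[c(ctx$state_names, ctx$control_names)]
}

## Hessian of J: constant diagonal blocks
objective_hessian <- function(ctx, weight = 1) {
  p <- ctx$params
  H <- list()
  zero <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = c(ctx$N, ctx$N))
  H$n0 <- zero
  H$np <- weight * p$alpha * ctx$Ks
  H$vx <- weight * ctx$M; H$vy <- weight * ctx$M
  H$fx <- weight * p$beta * ctx$M; H$fy <- weight * p$beta * ctx$M
  if (ctx$bidir) {
    H$nm <- weight * p$alpha * ctx$Ks
    H$wx <- weight * ctx$M; H$wy <- weight * ctx$M
    H$gx <- weight * p$beta * ctx$M; H$gy <- weight * p$beta * ctx$M
  }
  H[c(ctx$state_names, ctx$control_names)]
}

## second-derivative (adjoint-weighted) contributions of the nonlinear
## constraint terms; returns list of blocks H2[[var1]][[var2]] (upper set)
constraint_hessian <- function(ctx, st, ct, padj) {
  ## Dirichlet constraint rows are eliminated from the KKT system, so any
  ## adjoint values carried on them must not enter the curvature weights
  for (eq in names(padj)) {
    d <- ctx$dirichlet[[eq]]
    if (!is.null(d)) padj[[eq]][d$idx] <- 0
  }
  w <- ctx$w; Phi <- ctx$Phi; Phix <- ctx$Phix; Phiy <- ctx$Phiy
  L0 <- Phi * ctx$lq
  Lx <- Phix * ctx$lq + Phi * ctx$lxq
  Ly <- Phiy * ctx$lq + Phi * ctx$lyq
  pcq <- as.numeric(ctx$Wc %*% padj$np)
  pvxq <- as.numeric(ctx$Wv %*% padj$vx)
  pvyq <- as.numeric(ctx$Wv %*% padj$vy)
  H2 <- list()
  put <- function(a, b, val) {
    if (is.null(H2[[a]])) H2[[a]] <<- list()
    H2[[a]][[b]] <<- if (is.null(H2[[a]][[b]])) val else H2[[a]][[b]] + val
  }
  ## p_np' * (v . grad m+): cross terms velocity x concentration
  put("vx", "np", Matrix::crossprod(Phi, Lx * (w * pcq)))
  put("vy", "np", Matrix::crossprod(Phi, Ly * (w * pcq)))
  ## p_v' * (v . grad v)
  put("vx", "vx", Matrix::crossprod(Phi, Phix * (w * pvxq)) +
        Matrix::crossprod(Phix, Phi * (w * pvxq)))
  put("vy", "vy", Matrix::crossprod(Phi, Phiy * (w * pvyq)) +
        Matrix::crossprod(Phiy, Phi * (w * pvyq)))
  put("vx", "vy", Matrix::crossprod(Phiy, Phi * (w * pvxq)) +
        Matrix::crossprod(Phi, Phix * (w * pvyq)))
  if (ctx$bidir) {
    Lm0 <- Phi * ctx$lmq
    Lmx <- Phix * ctx$lmq + Phi * ctx$lmxq
    Lmy <- Phiy * ctx$lmq + Phi * ctx$lmyq
    pcmq <- as.numeric(ctx$Wcm %*% padj$nm)
    pwxq <- as.numeric(ctx$Wvm %*% padj$wx)
    pwyq <- as.numeric(ctx$Wvm %*% padj$wy)
    put("wx", "nm", Matrix::crossprod(Phi, Lmx * (w * pcmq)))
    put("wy", "nm", Matrix::crossprod(Phi, Lmy * (w * pcmq)))
    put("wx", "wx", Matrix::crossprod(Phi, Phix * (w * pwxq)) +
          Matrix::crossprod(Phix, Phi * (w * pwxq)))
    put("wy", "wy", Matrix::crossprod(Phi, Phiy * (w * pwyq)) +
          Matrix::crossprod(Phiy, Phi * (w * pwyq)))
    put("wx", "wy", Matrix::crossprod(Phiy, Phi * (w * pwxq)) +
          Matrix::crossprod(Phi, Phix * (w * pwyq)))
  }
  H2
}

#' Assemble the Galerkin residual of the transport constraints
#'
#' Computes the weak residual of the coupled reaction (free concentration),
#' advection-diffusion-reaction (bound concentrations) and traffic-momentum
#' (transport velocities) equations at the given fields, with inlet/outlet
#' Dirichlet rows removed (their values are imposed on the fields
#' themselves).  In transient mode a backward-Euler time derivative against
#' \code{previous_state} is added.
#'
#' @param space a \code{spline_space}
#' @param params a \code{parameter_set}
#' @param mt a \code{mt_density}
#' @param state named list of state coefficient vectors (\code{n0},
#'   \code{np}, \code{vx}, \code{vy}, plus \code{nm}, \code{wx}, \code{wy}
#'   in bidirectional mode)
#' @param control named list of control coefficient vectors (\code{fx},
#'   \code{fy}, plus \code{gx}, \code{gy})
#' @param target a \code{velocity_target} (supplies velocity Dirichlet data)
#' @param previous_state optional previous-step state for transient mode
#' @param restricted if TRUE (default) drop Dirichlet rows
#' @return named list of residual vectors, one per constraint equation
#' @export
assemble_constraint_residual <- function(space, params, mt, state, control,
                                         target, previous_state = NULL,
                                         restricted = TRUE) {
  ctx <- make_transport_ctx(space, params, mt, target)
  if (!setequal(names(state), ctx$state_names))
    stop("configuration error: state fields ",
         paste(names(state), collapse = ","), " do not match mode ",
         params$mode)
  dt <- if (params$n_time_steps > 0)
    params$T_horizon / params$n_time_steps else NULL
  if (!is.null(dt) && is.null(previous_state))
    stop("configuration error: transient mode requires previous_state")
  R <- residual_blocks(ctx, state, control, prev = previous_state, dt = dt)
  if (restricted) for (b in names(R)) R[[b]] <- R[[b]][ctx$free[[b]]]
  R
}

#' Evaluate the transport-control objective
#'
#' The objective is the sum of a velocity-tracking term
#' \eqn{\frac12\int (v - V)^2}, a concentration-gradient penalty
#' \eqn{\frac{\alpha}{2}\int \|\nabla n\|^2} and a control-effort penalty
#' \eqn{\frac{\beta}{2}\int f^2}, summed over the plus (and, in
#' bidirectional mode, minus) populations.
#'
#' @inheritParams assemble_constraint_residual
#' @param weight quadrature weight for one time slab (1 in steady mode)
#' @return object of class \code{"objective_breakdown"}: list with
#'   \code{tracking_term}, \code{gradient_term}, \code{control_term},
#'   \code{total}
#' @export
evaluate_objective <- function(space, params, state, control, target,
                               weight = 1) {
  Phi <- space$Phi; Phix <- space$Phix; Phiy <- space$Phiy; w <- space$w
  sq_int <- function(vals) sum(w * vals^2)
  track <- sq_int(as.numeric(Phi %*% (state$vx - target$vx))) +
    sq_int(as.numeric(Phi %*% (state$vy - target$vy)))
  grad <- sq_int(as.numeric(Phix %*% state$np)) +
    sq_int(as.numeric(Phiy %*% state$np))
  ctrl <- sq_int(as.numeric(Phi %*% control$fx)) +
    sq_int(as.numeric(Phi %*% control$fy))
  if (params$mode == "bidirectional") {
    track <- track + sq_int(as.numeric(Phi %*% (state$wx - target$vmx))) +
      sq_int(as.numeric(Phi %*% (state$wy - target$vmy)))
    grad <- grad + sq_int(as.numeric(Phix %*% state$nm)) +
      sq_int(as.numeric(Phiy %*% state$nm))
    ctrl <- ctrl + sq_int(as.numeric(Phi %*% control$gx)) +
      sq_int(as.numeric(Phi %*% control$gy))
  }
  out <- list(tracking_term = weight * track / 2,
              gradient_term = weight * params$alpha * grad / 2,
              control_term = weight * params$beta * ctrl / 2)
  out$total <- out$tracking_term + out$gradient_term + out$control_term
  structure(out, class = "objective_breakdown")
}

#' @export
print.objective_breakdown <- function(x, ...) {
  cat(sprintf("objective: total %.6g (tracking %.6g, gradient %.6g, control %.6g)\n",
              x$total, x$tracking_term, x$gradient_term, x$control_term))
  invisible(x)
}
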