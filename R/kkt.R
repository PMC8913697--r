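## All-at-once solution of the first-order optimality (KKT) system: state,
## control and adjoint unknowns are updated together by Newton iterations on
## the gradient of the discrete Lagrangian L = J + p' B, each linear step
## solved by right-preconditioned restarted GMRES.

#' Solver options for the all-at-once KKT solve
#'
#' @param kkt_tolerance stopping tolerance on the Euclidean norm of the full
#'   KKT residual (default \code{1e-7})
#' @param max_newton_iterations outer Newton iteration cap
#' @param gmres_restart GMRES restart length
#' @param gmres_max_iterations total inner iteration cap
#' @param gmres_tolerance relative residual tolerance of the inner solves
#' @param preconditioner \code{"constraint"} (default; a sparse factorization
#'   of the KKT matrix at the first Newton iterate, reused across the outer
#'   iterations) or \code{"none"}
#' @param random_seed seed fixed at the start of each solve so any randomized
#'   choices are reproducible
#' @param verbose print one line per Newton iteration
#' @return an object of class \code{"solver_options"}
#' @export
solver_options <- function(kkt_tolerance = 1e-7, max_newton_iterations = 30,
                           gmres_restart = 100, gmres_max_iterations = 500,
                           gmres_tolerance = 1e-9,
                           preconditioner = c("constraint", "none"),
                           random_seed = 1L, verbose = FALSE) {
  stopifnot(kkt_tolerance > 0, gmres_tolerance > 0)
  structure(list(kkt_tolerance = kkt_tolerance,
                 max_newton_iterations = as.integer(max_newton_iterations),
                 gmres_restart = as.integer(gmres_restart),
                 gmres_max_iterations = as.integer(gmres_max_iterations),
                 gmres_tolerance = gmres_tolerance,
                 preconditioner = match.arg(preconditioner),
                 random_seed = as.integer(random_seed),
                 verbose = isTRUE(verbose)),
            class = "solver_options")
}

#' Right-preconditioned restarted GMRES
#'
#' @param amul function returning \code{A \%*\% v}
#' @param b right-hand side
#' @param prec function applying the (right) preconditioner inverse
#' @param restart restart length
#' @param maxit total iteration cap
#' @param tol relative residual tolerance
#' @return list with \code{x}, \code{iterations}, \code{relres},
#'   \code{converged}
#' @export
gmres_solve <- function(amul, b, prec = identity, restart = 100, maxit = 500,
                        tol = 1e-9) {
  n <- length(b)
  x <- numeric(n)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(list(x = x, iterations = 0L, relres = 0,
                              converged = TRUE))
  total_it <- 0L
  repeat {
    r <- b - amul(x)
    beta <- sqrt(sum(r^2))
    if (beta / bnorm <= tol || total_it >= maxit)
      return(list(x = x, iterations = total_it, relres = beta / bnorm,
                  converged = beta / bnorm <= tol))
    m <- min(restart, maxit - total_it)
    V <- matrix(0, n, m + 1)
    H <- matrix(0, m + 1, m)
    cs <- numeric(m); sn <- numeric(m)
    g <- numeric(m + 1); g[1] <- beta
    V[, 1] <- r / beta
    k_used <- 0L
    for (k in seq_len(m)) {
      z <- prec(V[, k])
      wv <- amul(z)
      for (i in seq_len(k)) {
        H[i, k] <- sum(wv * V[, i])
        wv <- wv - H[i, k] * V[, i]
      }
      H[k + 1, k] <- sqrt(sum(wv^2))
      if (H[k + 1, k] > 1e-14) V[, k + 1] <- wv / H[k + 1, k]
      ## apply accumulated Givens rotations
      for (i in seq_len(k - 1)) {
        tmp <- cs[i] * H[i, k] + sn[i] * H[i + 1, k]
        H[i + 1, k] <- -sn[i] * H[i, k] + cs[i] * H[i + 1, k]
        H[i, k] <- tmp
      }
      d <- sqrt(H[k, k]^2 + H[k + 1, k]^2)
      if (d == 0) stop("solver error: GMRES breakdown")
      cs[k] <- H[k, k] / d; sn[k] <- H[k + 1, k] / d
      H[k, k] <- d; H[k + 1, k] <- 0
      g[k + 1] <- -sn[k] * g[k]; g[k] <- cs[k] * g[k]
      k_used <- k
      total_it <- total_it + 1L
      if (abs(g[k + 1]) / bnorm <= tol) break
    }
    y <- backsolve(H[seq_len(k_used), seq_len(k_used), drop = FALSE],
                   g[seq_len(k_used)])
    x <- x + prec(as.numeric(V[, seq_len(k_used), drop = FALSE] %*% y))
  }
}

## ---- block bookkeeping --------------------------------------------------

kkt_layout <- function(ctx) {
  yb <- c(ctx$state_names, ctx$control_names)
  ylen <- vapply(yb, function(b) length(ctx$free[[b]]), 0L)
  yoff <- c(0L, cumsum(ylen))
  pb <- ctx$state_names
  plen <- vapply(pb, function(b) length(ctx$free[[b]]), 0L)
  poff <- c(0L, cumsum(plen))
  list(y_blocks = yb, y_len = ylen, y_off = stats::setNames(yoff[-length(yoff)], yb),
       ny = sum(ylen), p_blocks = pb, p_len = plen,
       p_off = stats::setNames(poff[-length(poff)], pb), np = sum(plen))
}

pack_y <- function(ctx, lay, st, ct) {
  out <- numeric(lay$ny)
  for (b in lay$y_blocks) {
    v <- if (b %in% ctx$state_names) st[[b]] else ct[[b]]
    out[lay$y_off[b] + seq_len(lay$y_len[b])] <- v[ctx$free[[b]]]
  }
  out
}

unpack_y <- function(ctx, lay, yv, st, ct) {
  for (b in lay$y_blocks) {
    piece <- yv[lay$y_off[b] + seq_len(lay$y_len[b])]
    if (b %in% ctx$state_names) st[[b]][ctx$free[[b]]] <- piece
    else ct[[b]][ctx$free[[b]]] <- piece
  }
  list(state = st, control = ct)
}

pack_p <- function(ctx, lay, padj) {
  out <- numeric(lay$np)
  for (b in lay$p_blocks)
    out[lay$p_off[b] + seq_len(lay$p_len[b])] <- padj[[b]][ctx$free[[b]]]
  out
}

unpack_p <- function(ctx, lay, pv, padj) {
  for (b in lay$p_blocks)
    padj[[b]][ctx$free[[b]]] <- pv[lay$p_off[b] + seq_len(lay$p_len[b])]
  padj
}

zero_adjoint <- function(ctx)
  stats::setNames(rep(list(numeric(ctx$N)), length(ctx$state_names)),
                  ctx$state_names)

## KKT gradient (free dofs): gy = dJ/dy + (dB/dy)' p ; gp = B
kkt_gradient <- function(ctx, lay, st, ct, padj, prev = NULL, dt = NULL,
                         weight = 1, R = NULL, Jac = NULL) {
  if (is.null(R)) R <- residual_blocks(ctx, st, ct, prev = prev, dt = dt)
  if (is.null(Jac)) Jac <- jacobian_blocks(ctx, st, ct, dt = dt)
  gJ <- objective_gradient(ctx, st, ct, weight = weight)
  gy <- numeric(lay$ny); gp <- numeric(lay$np)
  for (b in lay$y_blocks) {
    acc <- gJ[[b]][ctx$free[[b]]]
    for (eq in lay$p_blocks) {
      Jb <- Jac[[eq]][[b]]
      if (!is.null(Jb))
        acc <- acc + as.numeric(Matrix::crossprod(
          Jb[ctx$free[[eq]], ctx$free[[b]], drop = FALSE],
          padj[[eq]][ctx$free[[eq]]]))
    }
    gy[lay$y_off[b] + seq_len(lay$y_len[b])] <- acc
  }
  for (eq in lay$p_blocks)
    gp[lay$p_off[eq] + seq_len(lay$p_len[eq])] <- R[[eq]][ctx$free[[eq]]]
  list(gy = gy, gp = gp, norm = sqrt(sum(gy^2) + sum(gp^2)), R = R, Jac = Jac)
}

## assemble the sparse KKT (Newton) matrix at an iterate; `reg` adds a
## primal-dual Levenberg regularization (+reg M on the primal diagonal,
## -reg M on the adjoint diagonal) used to globalize stalled steps
kkt_matrix <- function(ctx, lay, st, ct, padj, dt = NULL, weight = 1,
                       Jac = NULL, reg = 0) {
  if (is.null(Jac)) Jac <- jacobian_blocks(ctx, st, ct, dt = dt)
  HJ <- objective_hessian(ctx, weight = weight)
  H2 <- constraint_hessian(ctx, st, ct, padj)
  ntot <- lay$ny + lay$np
  ti <- list(); tj <- list(); tv <- list(); kk <- 0L
  add_block <- function(ri, ci, B) {
    if (is.null(B)) return()
    B <- methods::as(methods::as(B, "generalMatrix"), "TsparseMatrix")
    if (length(B@x) == 0) return()
    kk <<- kk + 1L
    ti[[kk]] <<- ri + B@i + 1L
    tj[[kk]] <<- ci + B@j + 1L
    tv[[kk]] <<- B@x
  }
  restr <- function(B, rb, cb)
    B[ctx$free[[rb]], ctx$free[[cb]], drop = FALSE]
  ## H block (objective Hessian on the diagonal)
  for (b in lay$y_blocks)
    add_block(lay$y_off[b], lay$y_off[b],
              restr(HJ[[b]] + reg * ctx$M, b, b))
  if (reg > 0)
    for (eq in lay$p_blocks)
      add_block(lay$ny + lay$p_off[eq], lay$ny + lay$p_off[eq],
                restr(-reg * ctx$M, eq, eq))
  ## constraint curvature (symmetric pairs)
  for (a in names(H2)) for (b2 in names(H2[[a]])) {
    Bl <- restr(H2[[a]][[b2]], a, b2)
    add_block(lay$y_off[a], lay$y_off[b2], Bl)
    if (a != b2) add_block(lay$y_off[b2], lay$y_off[a], Matrix::t(Bl))
    else NULL
  }
  ## constraint Jacobian and its transpose
  for (eq in lay$p_blocks) for (b in lay$y_blocks) {
    Jb <- Jac[[eq]][[b]]
    if (is.null(Jb)) next
    Bl <- restr(Jb, eq, b)
    add_block(lay$ny + lay$p_off[eq], lay$y_off[b], Bl)
    add_block(lay$y_off[b], lay$ny + lay$p_off[eq], Matrix::t(Bl))
  }
  Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tv),
                       dims = c(ntot, ntot))
}

## symmetric-only diagonal a != b guard above: H2 off-diagonal pairs where
## a == b must not be added twice; handled by the if().

#' Assemble the KKT saddle-point system at an iterate
#'
#' Builds the Newton linearization of the stationarity conditions of the
#' discrete Lagrangian: objective curvature plus adjoint-weighted constraint
#' curvature in the (state, control) block, the constraint Jacobian in the
#' off-diagonal blocks, and the negative current KKT residual as right-hand
#' side.  Dirichlet degrees of freedom are eliminated symmetrically.
#'
#' @inheritParams assemble_constraint_residual
#' @param iterate list with \code{state}, \code{control}, \code{adjoint}
#' @return object of class \code{"kkt_system"}: \code{A} (sparse matrix),
#'   \code{rhs}, \code{layout}, and the residual norm at the iterate
#' @export
assemble_kkt <- function(space, params, mt, iterate, target) {
  ctx <- make_transport_ctx(space, params, mt, target)
  lay <- kkt_layout(ctx)
  st <- impose_dirichlet(ctx, iterate$state)
  ct <- iterate$control
  padj <- if (!is.null(iterate$adjoint)) iterate$adjoint else zero_adjoint(ctx)
  g <- kkt_gradient(ctx, lay, st, ct, padj)
  A <- kkt_matrix(ctx, lay, st, ct, padj, Jac = g$Jac)
  structure(list(A = A, rhs = -c(g$gy, g$gp), layout = lay,
                 residual_norm = g$norm, ctx = ctx),
            class = "kkt_system")
}

#' @export
print.kkt_system <- function(x, ...) {
  cat("<kkt_system> dimension", nrow(x$A), "; KKT residual",
      signif(x$residual_norm, 4), "\n")
  invisible(x)
}

## Newton solve of one (steady or single time-slab) KKT system
newton_kkt <- function(ctx, lay, st, ct, padj, prev = NULL, dt = NULL,
                       weight = 1, options = solver_options()) {
  hist_it <- integer(0); hist_res <- numeric(0); hist_obj <- numeric(0)
  prec_fact <- NULL
  converged <- FALSE
  reg <- 0
  g <- kkt_gradient(ctx, lay, st, ct, padj, prev = prev, dt = dt,
                    weight = weight)
  linsolve <- function(A, rhs) {
    if (options$preconditioner == "constraint") {
      if (is.null(prec_fact)) prec_fact <<- Matrix::lu(A)
      prec <- function(v) as.numeric(Matrix::solve(prec_fact, v))
    } else prec <- identity
    sol <- gmres_solve(function(v) as.numeric(A %*% v), rhs, prec,
                       restart = options$gmres_restart,
                       maxit = options$gmres_max_iterations,
                       tol = options$gmres_tolerance)
    if (!sol$converged && options$preconditioner == "constraint") {
      ## refresh the frozen factorization at the current iterate and retry
      prec_fact <<- Matrix::lu(A)
      prec <- function(v) as.numeric(Matrix::solve(prec_fact, v))
      sol <- gmres_solve(function(v) as.numeric(A %*% v), rhs, prec,
                         restart = options$gmres_restart,
                         maxit = options$gmres_max_iterations,
                         tol = options$gmres_tolerance)
    }
    sol$x
  }
  for (it in seq_len(options$max_newton_iterations)) {
    obj <- evaluate_objective(ctx$space, ctx$params, st, ct, ctx$target,
                              weight = weight)
    hist_it <- c(hist_it, it - 1L); hist_res <- c(hist_res, g$norm)
    hist_obj <- c(hist_obj, obj$total)
    if (options$verbose)
      cat(sprintf("  newton %2d  kkt %.3e  J %.6g  reg %.1e\n", it - 1L,
                  g$norm, obj$total, reg))
    if (g$norm <= options$kkt_tolerance) { converged <- TRUE; break }
    y0 <- pack_y(ctx, lay, st, ct); p0 <- pack_p(ctx, lay, padj)
    best <- NULL
    for (attempt in 1:4) {
      A <- kkt_matrix(ctx, lay, st, ct, padj, dt = dt, weight = weight,
                      Jac = g$Jac, reg = reg)
      if (reg > 0) prec_fact <- NULL   # regularized matrix needs own factor
      dz <- linsolve(A, -c(g$gy, g$gp))
      dy <- dz[seq_len(lay$ny)]
      dp <- dz[lay$ny + seq_len(lay$np)]
      ## backtracking line search on the KKT residual norm
      alpha <- 1
      for (ls in 1:7) {
        cand <- unpack_y(ctx, lay, y0 + alpha * dy, st, ct)
        padj_c <- unpack_p(ctx, lay, p0 + alpha * dp, padj)
        gc <- kkt_gradient(ctx, lay, cand$state, cand$control, padj_c,
                           prev = prev, dt = dt, weight = weight)
        if (is.null(best) || gc$norm < best$g$norm)
          best <- list(state = cand$state, control = cand$control,
                       adjoint = padj_c, g = gc, alpha = alpha)
        if (gc$norm <= (1 - 1e-4 * alpha) * g$norm) break
        alpha <- alpha / 2
      }
      if (best$g$norm < (1 - 1e-6) * g$norm) {
        reg <- reg / 3; if (reg < 1e-8) reg <- 0
        break
      }
      ## stalled: escalate the primal-dual regularization and retry
      reg <- max(10 * reg, 1e-4)
      if (attempt == 4L) break
    }
    if (best$g$norm >= g$norm) break   # no progress possible
    st <- best$state; ct <- best$control; padj <- best$adjoint
    g <- best$g
    if (it == options$max_newton_iterations) {
      obj <- evaluate_objective(ctx$space, ctx$params, st, ct, ctx$target,
                                weight = weight)
      hist_it <- c(hist_it, it); hist_res <- c(hist_res, g$norm)
      hist_obj <- c(hist_obj, obj$total)
      converged <- g$norm <= options$kkt_tolerance
    }
  }
  list(state = st, control = ct, adjoint = padj, converged = converged,
       history = data.frame(iteration = hist_it, kkt_residual = hist_res,
                            objective = hist_obj))
}

#' Solve the transport optimal-control problem all-at-once
#'
#' Newton iterations on the coupled first-order optimality system of the
#' discrete Lagrangian, each linearized saddle-point system solved with
#' right-preconditioned restarted GMRES.  In steady mode (the default) a
#' single KKT system is solved; in transient mode the time slabs are solved
#' sequentially with backward-Euler coupling to the previous state.
#'
#' @inheritParams assemble_constraint_residual
#' @param options a \code{\link{solver_options}}
#' @param init optional list(state, control) initial iterate; by default the
#'   velocities start at the target and the concentrations at a linear
#'   interpolant of the boundary data
#' @return an object of class \code{"pdeco_solution"}
#' @export
solve_pdeco <- function(space, params, mt, target,
                        options = solver_options(), init = NULL) {
  set.seed(options$random_seed)
  ctx <- make_transport_ctx(space, params, mt, target)
  lay <- kkt_layout(ctx)
  start <- if (is.null(init)) initial_fields(ctx) else init
  st <- impose_dirichlet(ctx, start$state)
  ct <- start$control
  padj <- zero_adjoint(ctx)
  if (params$n_time_steps == 0L) {
    out <- newton_kkt(ctx, lay, st, ct, padj, options = options)
    hist <- out$history
  } else {
    dt <- params$T_horizon / params$n_time_steps
    prev <- st
    hist <- NULL
    conv_all <- TRUE
    for (step in seq_len(params$n_time_steps)) {
      out <- newton_kkt(ctx, lay, st, ct, padj, prev = prev, dt = dt,
                        weight = dt, options = options)
      st <- out$state; ct <- out$control; padj <- out$adjoint
      conv_all <- conv_all && out$converged
      h <- out$history; h$step <- step
      hist <- rbind(hist, h)
      prev <- st
    }
    out$converged <- conv_all
    out$history <- hist
  }
  obj <- evaluate_objective(space, params, out$state, out$control, target)
  structure(list(state = out$state, control = out$control,
                 adjoint = out$adjoint, objective = obj,
                 history = out$history, converged = out$converged,
                 kkt_residual = utils::tail(out$history$kkt_residual, 1),
                 space = space, params = params, mt = mt, target = target,
                 options = options),
            class = "pdeco_solution")
}

#' @export
print.pdeco_solution <- function(x, ...) {
  cat("<pdeco_solution>", x$params$mode, "mode,",
      if (x$converged) "converged" else "NOT converged",
      "- final KKT residual", signif(x$kkt_residual, 4), "\n")
  print(x$objective)
  invisible(x)
}

#' @export
summary.pdeco_solution <- function(object, ...) {
  x <- object
  cat("Transport optimal-control solution\n")
  cat("  mode:         ", x$params$mode, "\n")
  cat("  dofs per field:", x$space$ndof, "\n")
  cat("  unknown groups:", n_unknown_groups(x$params), "\n")
  cat("  Newton iterations:", nrow(x$history) - 1L, "\n")
  cat("  final KKT residual:", signif(x$kkt_residual, 4),
      if (x$converged) "(converged)" else "(not converged)", "\n")
  print(x$objective)
  invisible(x)
}

#' KKT residual history of a solution
#' @param object a \code{pdeco_solution}
#' @param ... unused
#' @return numeric vector of KKT residual norms per Newton iteration
#' @export
residuals.pdeco_solution <- function(object, ...) object$history$kkt_residual

#' Objective terms of a solution
#' @param object a \code{pdeco_solution}
#' @param ... unused
#' @return named numeric vector of the objective terms
#' @export
coef.pdeco_solution <- function(object, ...)
  unlist(object$objective[c("tracking_term", "gradient_term",
                            "control_term", "total")])

#' Forward solve of the transport constraints with zero control
#'
#' Solves the constraint equations alone (f = 0) for the state fields; the
#' oracle counterpart of the optimizer in the large-beta limit.  The
#' nonlinear solve uses pseudo-transient continuation (a backward-Euler mass
#' shift whose pseudo-step grows as the residual drops) with backtracking,
#' which tolerates the weakly-constrained outflow velocity modes of the
#' natural boundary conditions.
#'
#' @inheritParams assemble_constraint_residual
#' @param tol residual tolerance
#' @param max_iter iteration cap
#' @param init optional initial state
#' @return list with state fields and convergence info
#' @export
forward_transport_solve <- function(space, params, mt, target, tol = 1e-10,
                                    max_iter = 60, init = NULL) {
  ctx <- make_transport_ctx(space, params, mt, target)
  st <- impose_dirichlet(ctx, if (is.null(init)) initial_fields(ctx)$state
                         else init)
  ct <- stats::setNames(rep(list(numeric(ctx$N)), length(ctx$control_names)),
                        ctx$control_names)
  sn <- ctx$state_names
  len <- vapply(sn, function(b) length(ctx$free[[b]]), 0L)
  off <- stats::setNames(c(0L, cumsum(len))[seq_along(sn)], sn)
  ntot <- sum(len)
  resvec <- function(st, prev = NULL, dt = NULL) {
    R <- residual_blocks(ctx, st, ct, prev = prev, dt = dt)
    res <- numeric(ntot)
    for (b in sn) res[off[b] + seq_len(len[b])] <- R[[b]][ctx$free[[b]]]
    res
  }
  newton_step <- function(st, res, prev = NULL, dt = NULL, dtau = Inf) {
    Jac <- jacobian_blocks(ctx, st, ct, dt = dt)
    ti <- list(); tj <- list(); tv <- list(); kk <- 0L
    for (eq in sn) for (b in sn) {
      Jb <- if (eq == b && is.finite(dtau))
        Jac[[eq]][[b]] + (1 / dtau) * ctx$M else Jac[[eq]][[b]]
      if (is.null(Jb)) next
      Bl <- methods::as(methods::as(
        Jb[ctx$free[[eq]], ctx$free[[b]], drop = FALSE], "generalMatrix"),
        "TsparseMatrix")
      if (length(Bl@x) == 0) next
      kk <- kk + 1L
      ti[[kk]] <- off[eq] + Bl@i + 1L
      tj[[kk]] <- off[b] + Bl@j + 1L
      tv[[kk]] <- Bl@x
    }
    A <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj),
                              x = unlist(tv), dims = c(ntot, ntot))
    as.numeric(Matrix::solve(A, -res))
  }
  apply_step <- function(st, dz, alpha) {
    for (b in sn) st[[b]][ctx$free[[b]]] <- st[[b]][ctx$free[[b]]] +
        alpha * dz[off[b] + seq_len(len[b])]
    st
  }
  ## transient mode: backward-Euler marching, damped Newton per step
  if (params$n_time_steps > 0L) {
    dt <- params$T_horizon / params$n_time_steps
    prev <- st
    for (step in seq_len(params$n_time_steps)) {
      for (itn in 1:20) {
        res <- resvec(st, prev = prev, dt = dt)
        rn <- sqrt(sum(res^2))
        if (rn < tol) break
        dz <- newton_step(st, res, prev = prev, dt = dt)
        alpha <- 1; best <- NULL
        for (ls in 1:8) {
          stc <- apply_step(st, dz, alpha)
          rc <- sqrt(sum(resvec(stc, prev = prev, dt = dt)^2))
          if (is.null(best) || rc < best$rn) best <- list(st = stc, rn = rc)
          if (rc <= (1 - 1e-4 * alpha) * rn) break
          alpha <- alpha / 2
        }
        st <- best$st
        rn <- best$rn
      }
      prev <- st
    }
    return(list(state = st, converged = rn < tol, residual = rn,
                iterations = params$n_time_steps))
  }
  res <- resvec(st)
  rn <- sqrt(sum(res^2))
  rn0 <- rn
  dtau <- 1
  for (it in seq_len(max_iter)) {
    if (rn < tol) return(list(state = st, converged = TRUE, residual = rn,
                              iterations = it - 1L))
    Jac <- jacobian_blocks(ctx, st, ct)
    ti <- list(); tj <- list(); tv <- list(); kk <- 0L
    for (eq in sn) for (b in sn) {
      Jb <- if (eq == b) Jac[[eq]][[b]] + (1 / dtau) * ctx$M else Jac[[eq]][[b]]
      if (is.null(Jb)) next
      Bl <- methods::as(methods::as(
        Jb[ctx$free[[eq]], ctx$free[[b]], drop = FALSE], "generalMatrix"),
        "TsparseMatrix")
      if (length(Bl@x) == 0) next
      kk <- kk + 1L
      ti[[kk]] <- off[eq] + Bl@i + 1L
      tj[[kk]] <- off[b] + Bl@j + 1L
      tv[[kk]] <- Bl@x
    }
    A <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tv),
                              dims = c(ntot, ntot))
    dz <- as.numeric(Matrix::solve(A, -res))
    ## backtrack on the residual norm
    alpha <- 1; best <- NULL
    for (ls in 1:8) {
      stc <- st
      for (b in sn) stc[[b]][ctx$free[[b]]] <- st[[b]][ctx$free[[b]]] +
          alpha * dz[off[b] + seq_len(len[b])]
      resc <- resvec(stc)
      rc <- sqrt(sum(resc^2))
      if (is.null(best) || rc < best$rn)
        best <- list(st = stc, rn = rc, res = resc)
      if (rc <= (1 - 1e-4 * alpha) * rn) break
      alpha <- alpha / 2
    }
    if (best$rn < rn) {
      st <- best$st; res <- best$res; rn <- best$rn
      ## switched-evolution-relaxation pseudo-step growth
      dtau <- min(1e10, max(dtau, rn0 / max(rn, 1e-300)))
    } else {
      dtau <- dtau / 4
      if (dtau < 1e-6) break
    }
  }
  list(state = st, converged = rn < tol, residual = rn,
       iterations = max_iter)
}

#' Finite-difference check of the assembled Lagrangian gradient
#'
#' Compares the assembled gradient of the discrete Lagrangian with central
#' finite differences along random unit directions in the free (state,
#' control) space.
#'
#' @inheritParams assemble_constraint_residual
#' @param iterate optional list(state, control, adjoint); defaults to the
#'   standard initial fields with a smooth nonzero adjoint
#' @param epsilon finite-difference step (in [1e-8, 2e-2]; large steps are
#'   useful for verifying the second-order step dependence of the error)
#' @param n_directions number of random directions
#' @param seed RNG seed for the directions
#' @return the maximum relative discrepancy over the tested directions
#' @export
finite_difference_gradient_check <- function(space, params, mt, target,
                                             iterate = NULL, epsilon = 1e-6,
                                             n_directions = 20, seed = 1L) {
  stopifnot(epsilon >= 1e-8, epsilon <= 2e-2)
  ctx <- make_transport_ctx(space, params, mt, target)
  lay <- kkt_layout(ctx)
  if (is.null(iterate)) {
    ini <- initial_fields(ctx)
    padj <- zero_adjoint(ctx)
    smooth <- project_field(space, 0.1 * sin(space$qp$x / 7) *
                              cos(space$qp$y / 3))
    for (b in names(padj)) padj[[b]] <- smooth
    iterate <- list(state = ini$state, control = ini$control, adjoint = padj)
  }
  st <- impose_dirichlet(ctx, iterate$state); ct <- iterate$control
  padj <- iterate$adjoint
  lag <- function(yv) {
    z <- unpack_y(ctx, lay, yv, st, ct)
    obj <- evaluate_objective(space, params, z$state, z$control, target)
    R <- residual_blocks(ctx, z$state, z$control)
    val <- obj$total
    for (eq in lay$p_blocks)
      val <- val + sum(padj[[eq]][ctx$free[[eq]]] * R[[eq]][ctx$free[[eq]]])
    val
  }
  g <- kkt_gradient(ctx, lay, st, ct, padj)
  y0 <- pack_y(ctx, lay, st, ct)
  set.seed(seed)
  worst <- 0
  gscale <- sqrt(sum(g$gy^2))
  for (k in seq_len(n_directions)) {
    d <- stats::rnorm(lay$ny); d <- d / sqrt(sum(d^2))
    fd <- (lag(y0 + epsilon * d) - lag(y0 - epsilon * d)) / (2 * epsilon)
    an <- sum(g$gy * d)
    rel <- abs(fd - an) / max(abs(an), gscale * 1e-3, 1e-12)
    worst <- max(worst, rel)
  }
  worst
}
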