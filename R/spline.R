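## Quadratic spline Galerkin space on a swept control mesh.  Each patch
## carries a tensor-product B-spline basis on open uniform knot vectors
## (C^(degree-1) inside the patch); patches are glued C0 by identifying
## coincident Greville points across shared edges.  The geometry map is
## piecewise bilinear per control-mesh quad (sub-parametric), with 3x3 Gauss
## quadrature per element.

## all 1D B-spline basis values and first derivatives at a single point
bspline_all <- function(u, p, U) {
  nb <- length(U) - p - 1L
  nspans <- length(U) - 1L
  N <- numeric(nspans)
  if (u >= U[nb + 1L]) {
    j <- max(which(diff(U) > 0))
    N[j] <- 1
  } else {
    j <- findInterval(u, U, rightmost.closed = FALSE)
    N[j] <- 1
  }
  Nprev <- NULL
  for (d in seq_len(p)) {
    Nd <- numeric(nspans - d)
    for (jj in seq_len(nspans - d)) {
      a <- 0; b <- 0
      den1 <- U[jj + d] - U[jj]
      den2 <- U[jj + d + 1L] - U[jj + 1L]
      if (den1 > 0) a <- (u - U[jj]) / den1 * N[jj]
      if (den2 > 0) b <- (U[jj + d + 1L] - u) / den2 * N[jj + 1L]
      Nd[jj] <- a + b
    }
    if (d == p) Nprev <- N
    N <- Nd
  }
  val <- N[seq_len(nb)]
  der <- numeric(nb)
  if (p >= 1) {
    for (jj in seq_len(nb)) {
      d1 <- U[jj + p] - U[jj]
      d2 <- U[jj + p + 1L] - U[jj + 1L]
      a <- if (d1 > 0) p / d1 * Nprev[jj] else 0
      b <- if (d2 > 0) p / d2 * Nprev[jj + 1L] else 0
      der[jj] <- a - b
    }
  }
  list(val = val, der = der)
}

open_knots <- function(n_el, p) c(rep(0, p + 1L), seq_len(n_el - 1L), rep(n_el, p + 1L))

## open knot vector with a C0 break (multiplicity p) at the mid element line;
## used transversely on branch patches of branched meshes so that branch end
## cross-sections span the same edge space as the two half-edge junction
## patches they meet
open_knots_c0mid <- function(n_el, p) {
  m <- n_el %/% 2L
  sort(c(open_knots(n_el, p), rep(m, p - 1L)))
}

greville_of <- function(U, p) {
  nb <- length(U) - p - 1L
  vapply(seq_len(nb), function(i) mean(U[(i + 1L):(i + p)]), 0)
}

## active basis indices for element k (covering [k-1, k]) of knot vector U
active_funs <- function(U, k, p) {
  i <- findInterval(k - 0.5, U)
  (i - p):i
}

patch_knots <- function(pa, p, c0_mid) {
  Uu <- open_knots(pa$n_u, p)
  Uv <- if (c0_mid && pa$type == "branch" && p > 1L)
    open_knots_c0mid(pa$n_v, p) else open_knots(pa$n_v, p)
  list(Uu = Uu, Uv = Uv)
}

## bilinear geometry map of one control-mesh quad, local coords in [0,1]^2
bilinear_map <- function(q, xi, eta) {
  ## q: 4x2 corners v00, v10, v11, v01 (CCW); returns x, J (2x2), det
  x <- (1 - xi) * (1 - eta) * q[1, ] + xi * (1 - eta) * q[2, ] +
    xi * eta * q[3, ] + (1 - xi) * eta * q[4, ]
  dxi <- (1 - eta) * (q[2, ] - q[1, ]) + eta * (q[3, ] - q[4, ])
  deta <- (1 - xi) * (q[4, ] - q[1, ]) + xi * (q[3, ] - q[2, ])
  J <- cbind(dxi, deta)
  list(x = x, J = J, det = J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1])
}

patch_corners <- function(mesh, patch, iu, iv) {
  g <- patch$grid
  ids <- c(g[iu, iv], g[iu + 1L, iv], g[iu + 1L, iv + 1L], g[iu, iv + 1L])
  mesh$vertices[ids, , drop = FALSE]
}

#' Build a spline Galerkin space on a control mesh
#'
#' @param mesh a \code{\link{sweep_mesh}} result
#' @param degree basis degree, 1 (bilinear) or 2 (quadratic, default)
#' @return an object of class \code{"spline_space"} holding the global
#'   degree-of-freedom map, cached basis value/gradient matrices at the
#'   quadrature points (\code{Phi}, \code{Phix}, \code{Phiy}), quadrature
#'   weights \code{w}, per-point metadata (coordinates, branch, axial
#'   arc-length \code{s}, transverse coordinate \code{t}) and boundary
#'   structures (Dirichlet dof lists and edge quadrature with outward
#'   normals) for every boundary tag.
#' @export
build_spline_space <- function(mesh, degree = 2) {
  stopifnot(inherits(mesh, "control_mesh"), degree %in% c(1L, 2L))
  p <- as.integer(degree)
  gp <- c((1 - sqrt(3 / 5)) / 2, 0.5, (1 + sqrt(3 / 5)) / 2)
  gw <- c(5, 8, 5) / 18
  nq1 <- 3L

  has_junction <- any(vapply(mesh$patches, function(pa) pa$type == "junction",
                             TRUE))

  ## ---- global dof numbering via Greville-point dedup -------------------
  dhash <- new.env(hash = TRUE, parent = emptyenv())
  dof_x <- numeric(0); dof_y <- numeric(0)
  patch_dofs <- vector("list", length(mesh$patches))
  pknots <- lapply(mesh$patches, patch_knots, p = p, c0_mid = has_junction)
  for (pa in mesh$patches) {
    kn <- pknots[[pa$id]]
    gu <- greville_of(kn$Uu, p); gv <- greville_of(kn$Uv, p)
    loc <- matrix(0L, length(gu), length(gv))
    for (i in seq_along(gu)) for (j in seq_along(gv)) {
      ku <- min(floor(gu[i]) + 1, pa$n_u); xi <- gu[i] - (ku - 1)
      kv <- min(floor(gv[j]) + 1, pa$n_v); eta <- gv[j] - (kv - 1)
      q <- patch_corners(mesh, pa, ku, kv)
      pt <- bilinear_map(q, xi, eta)$x
      key <- paste0(round(pt[1], 6), "_", round(pt[2], 6))
      id <- dhash[[key]]
      if (is.null(id)) {
        id <- length(dof_x) + 1L
        dof_x[id] <- pt[1]; dof_y[id] <- pt[2]
        dhash[[key]] <- id
      }
      loc[i, j] <- id
    }
    patch_dofs[[pa$id]] <- loc
  }
  ndof <- length(dof_x)

  ## ---- element quadrature and basis caches -----------------------------
  trip_i <- list(); trip_j <- list(); trip_v <- list()
  trip_vx <- list(); trip_vy <- list()
  w_all <- list(); qx <- list(); qy <- list()
  q_branch <- list(); q_s <- list(); q_t <- list(); q_el <- list(); q_patch <- list()
  el_dofs <- list()
  el_of_patch <- vector("list", length(mesh$patches))
  nq_el <- nq1 * nq1
  ecount <- 0L; qcount <- 0L
  min_det <- Inf
  for (pa in mesh$patches) {
    Uu <- pknots[[pa$id]]$Uu; Uv <- pknots[[pa$id]]$Uv
    ## 1D bases per element row/col at gauss offsets
    bu <- lapply(seq_len(pa$n_u), function(k)
      lapply(gp, function(g) bspline_all(k - 1 + g, p, Uu)))
    bv <- lapply(seq_len(pa$n_v), function(k)
      lapply(gp, function(g) bspline_all(k - 1 + g, p, Uv)))
    ldofs <- patch_dofs[[pa$id]]
    el_of_patch[[pa$id]] <- matrix(0L, pa$n_u, pa$n_v)
    for (iu in seq_len(pa$n_u)) for (iv in seq_len(pa$n_v)) {
      ecount <- ecount + 1L
      el_of_patch[[pa$id]][iu, iv] <- ecount
      au <- active_funs(Uu, iu, p); av <- active_funs(Uv, iv, p)
      gdof <- as.integer(ldofs[au, av])       # (p+1)^2, column-major (u fast)
      el_dofs[[ecount]] <- gdof
      q <- patch_corners(mesh, pa, iu, iv)
      nloc <- (p + 1L)^2
      Nv <- matrix(0, nq_el, nloc); Gx <- matrix(0, nq_el, nloc)
      Gy <- matrix(0, nq_el, nloc)
      wdet <- numeric(nq_el); xs <- numeric(nq_el); ys <- numeric(nq_el)
      k <- 0L
      for (jq in seq_len(nq1)) for (iq in seq_len(nq1)) {
        k <- k + 1L
        Bu <- bu[[iu]][[iq]]; Bv <- bv[[iv]][[jq]]
        Nu <- Bu$val[au]; dNu <- Bu$der[au]
        Nvv <- Bv$val[av]; dNv <- Bv$der[av]
        Nloc <- as.numeric(outer(Nu, Nvv))
        dNdu <- as.numeric(outer(dNu, Nvv))
        dNdv <- as.numeric(outer(Nu, dNv))
        bm <- bilinear_map(q, gp[iq], gp[jq])
        if (bm$det <= 0)
          stop("geometry error: non-positive Jacobian in element ", ecount)
        min_det <- min(min_det, bm$det)
        ## param (u,v) derivative of geometry equals local (xi,eta) derivative
        Jinv <- solve(bm$J)
        Gx[k, ] <- dNdu * Jinv[1, 1] + dNdv * Jinv[2, 1]
        Gy[k, ] <- dNdu * Jinv[1, 2] + dNdv * Jinv[2, 2]
        Nv[k, ] <- Nloc
        wdet[k] <- gw[iq] * gw[jq] * bm$det
        xs[k] <- bm$x[1]; ys[k] <- bm$x[2]
      }
      rows <- rep(qcount + seq_len(nq_el), times = nloc)
      cols <- rep(gdof, each = nq_el)
      trip_i[[ecount]] <- rows; trip_j[[ecount]] <- cols
      trip_v[[ecount]] <- as.numeric(Nv)
      trip_vx[[ecount]] <- as.numeric(Gx)
      trip_vy[[ecount]] <- as.numeric(Gy)
      w_all[[ecount]] <- wdet; qx[[ecount]] <- xs; qy[[ecount]] <- ys
      ## axial/transverse metadata
      uu <- iu - 1 + gp[rep(seq_len(nq1), times = nq1)]
      vv <- iv - 1 + gp[rep(seq_len(nq1), each = nq1)]
      if (pa$type == "branch") {
        s0 <- pa$s_range[1]; s1 <- pa$s_range[2]
        q_s[[ecount]] <- s0 + (uu / pa$n_u) * (s1 - s0)
        q_t[[ecount]] <- 2 * vv / pa$n_v - 1
      } else {
        q_s[[ecount]] <- rep(pa$s_range[1], nq_el)
        q_t[[ecount]] <- rep(0, nq_el)
      }
      q_branch[[ecount]] <- rep(pa$branch, nq_el)
      q_el[[ecount]] <- rep(ecount, nq_el)
      q_patch[[ecount]] <- rep(pa$id, nq_el)
      qcount <- qcount + nq_el
    }
  }
  nq <- qcount
  Phi <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                              x = unlist(trip_v), dims = c(nq, ndof))
  Phix <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                               x = unlist(trip_vx), dims = c(nq, ndof))
  Phiy <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                               x = unlist(trip_vy), dims = c(nq, ndof))
  qp <- data.frame(x = unlist(qx), y = unlist(qy), w = unlist(w_all),
                   branch = unlist(q_branch), s = unlist(q_s),
                   t = unlist(q_t), element = unlist(q_el),
                   patch = unlist(q_patch))

  ## ---- boundary structures --------------------------------------------
  bnd <- list()
  for (pa in mesh$patches) {
    for (side in names(pa$tags)) {
      tag <- pa$tags[[side]]
      ldofs <- patch_dofs[[pa$id]]
      nbu <- nrow(ldofs); nbv <- ncol(ldofs)
      sdofs <- switch(side,
                      u0 = ldofs[1, ], u1 = ldofs[nbu, ],
                      v0 = ldofs[, 1], v1 = ldofs[, nbv])
      ## edge quadrature: iterate edge elements
      n_edge <- if (side %in% c("u0", "u1")) pa$n_v else pa$n_u
      bi <- list(); bjj <- list(); bvv <- list(); bvx <- list(); bvy <- list()
      bw <- list(); bnx <- list(); bny <- list(); bx <- list(); by <- list()
      rcount <- if (is.null(bnd[[tag]])) 0L else bnd[[tag]]$nq
      Uu <- pknots[[pa$id]]$Uu; Uv <- pknots[[pa$id]]$Uv
      for (ke in seq_len(n_edge)) {
        if (side %in% c("u0", "u1")) {
          iu <- if (side == "u0") 1L else pa$n_u
          iv <- ke
          xi_fix <- if (side == "u0") 0 else 1
        } else {
          iu <- ke
          iv <- if (side == "v0") 1L else pa$n_v
          eta_fix <- if (side == "v0") 0 else 1
        }
        au <- active_funs(Uu, iu, p); av <- active_funs(Uv, iv, p)
        gdof <- as.integer(patch_dofs[[pa$id]][au, av])
        q <- patch_corners(mesh, pa, iu, iv)
        for (iq in seq_len(nq1)) {
          if (side %in% c("u0", "u1")) { xi <- xi_fix; eta <- gp[iq] }
          else { xi <- gp[iq]; eta <- eta_fix }
          Bu <- bspline_all(iu - 1 + xi, p, Uu)
          Bv <- bspline_all(iv - 1 + eta, p, Uv)
          Nloc <- as.numeric(outer(Bu$val[au], Bv$val[av]))
          dNdu <- as.numeric(outer(Bu$der[au], Bv$val[av]))
          dNdv <- as.numeric(outer(Bu$val[au], Bv$der[av]))
          bm <- bilinear_map(q, xi, eta)
          Jinv <- solve(bm$J)
          gx <- dNdu * Jinv[1, 1] + dNdv * Jinv[2, 1]
          gy <- dNdu * Jinv[1, 2] + dNdv * Jinv[2, 2]
          tan_vec <- if (side %in% c("u0", "u1")) bm$J[, 2] else bm$J[, 1]
          elen <- sqrt(sum(tan_vec^2))
          nrm <- c(tan_vec[2], -tan_vec[1]) / elen
          ## orient outward: away from the element center
          ctr <- colMeans(q)
          if (sum(nrm * (bm$x - ctr)) < 0) nrm <- -nrm
          kk <- length(bw) + 1L
          bi[[kk]] <- rep(rcount + kk, length(gdof))
          bjj[[kk]] <- gdof
          bvv[[kk]] <- Nloc; bvx[[kk]] <- gx; bvy[[kk]] <- gy
          bw[[kk]] <- gw[iq] * elen
          bnx[[kk]] <- nrm[1]; bny[[kk]] <- nrm[2]
          bx[[kk]] <- bm$x[1]; by[[kk]] <- bm$x[2]
        }
      }
      add <- list(dofs = unique(as.integer(sdofs)),
                  i = unlist(bi), j = unlist(bjj), v = unlist(bvv),
                  vx = unlist(bvx), vy = unlist(bvy), w = unlist(bw),
                  nx = unlist(bnx), ny = unlist(bny),
                  x = unlist(bx), y = unlist(by), nq = length(unlist(bw)))
      if (is.null(bnd[[tag]])) bnd[[tag]] <- add
      else {
        old <- bnd[[tag]]
        bnd[[tag]] <- list(dofs = unique(c(old$dofs, add$dofs)),
                           i = c(old$i, add$i), j = c(old$j, add$j),
                           v = c(old$v, add$v), vx = c(old$vx, add$vx),
                           vy = c(old$vy, add$vy), w = c(old$w, add$w),
                           nx = c(old$nx, add$nx), ny = c(old$ny, add$ny),
                           x = c(old$x, add$x), y = c(old$y, add$y),
                           nq = old$nq + add$nq)
      }
    }
  }
  for (tag in names(bnd)) {
    b <- bnd[[tag]]
    b$Phib <- Matrix::sparseMatrix(i = b$i, j = b$j, x = b$v,
                                   dims = c(b$nq, ndof))
    b$Phibx <- Matrix::sparseMatrix(i = b$i, j = b$j, x = b$vx,
                                    dims = c(b$nq, ndof))
    b$Phiby <- Matrix::sparseMatrix(i = b$i, j = b$j, x = b$vy,
                                    dims = c(b$nq, ndof))
    b$i <- b$j <- b$v <- b$vx <- b$vy <- NULL
    bnd[[tag]] <- b
  }

  space <- structure(list(mesh = mesh, degree = p, ndof = ndof,
                          dof_xy = cbind(x = dof_x, y = dof_y),
                          Phi = Phi, Phix = Phix, Phiy = Phiy,
                          w = qp$w, qp = qp, el_dofs = el_dofs,
                          el_of_patch = el_of_patch, patch_dofs = patch_dofs,
                          pknots = pknots, bnd = bnd, n_elements = ecount,
                          min_det = min_det),
                     class = "spline_space")
  ## partition-of-unity sanity
  pou <- max(abs(Matrix::rowSums(Phi) - 1))
  if (pou > 1e-10)
    stop("assembly error: partition of unity violated (", signif(pou, 3), ")")
  space
}

#' @export
print.spline_space <- function(x, ...) {
  cat("<spline_space> degree ", x$degree, ", ", x$ndof, " dofs, ",
      x$n_elements, " elements, ", length(x$w), " quadrature points\n",
      sep = "")
  cat("  boundary tags:", paste(names(x$bnd), collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate the isoparametric geometry map of one element
#'
#' Reference coordinates live on the bi-unit square [-1, 1]^2.
#'
#' @param space a \code{spline_space}
#' @param element element index
#' @param ref_point length-2 reference coordinates in [-1, 1]^2
#' @return list with \code{x} (physical point, um), \code{J} (2x2 Jacobian of
#'   the map from the bi-unit square) and \code{det}
#' @export
evaluate_geometry <- function(space, element, ref_point) {
  stopifnot(length(ref_point) == 2, all(abs(ref_point) <= 1 + 1e-12))
  mesh <- space$mesh
  pa_id <- mesh$element_patch[element]
  pa <- mesh$patches[[pa_id]]
  ## locate (iu, iv) of this element inside the patch
  loc <- which(el_of_patch_lookup(space, pa_id) == element, arr.ind = TRUE)
  q <- patch_corners(mesh, pa, loc[1], loc[2])
  xi <- (ref_point[1] + 1) / 2; eta <- (ref_point[2] + 1) / 2
  bm <- bilinear_map(q, xi, eta)
  J <- bm$J / 2                       # chain rule [0,1] -> [-1,1]
  det <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  if (det <= 0)
    stop("geometry error: non-positive Jacobian in element ", element)
  list(x = bm$x, J = J, det = det)
}

el_of_patch_lookup <- function(space, pa_id) space$el_of_patch[[pa_id]]

#' Evaluate a spline field at parametric points of a patch
#'
#' @param space a \code{spline_space}
#' @param coef coefficient vector (length \code{space$ndof})
#' @param patch patch id
#' @param u,v parametric coordinates (u in [0, n_u], v in [0, n_v]); vectors
#' @return list with \code{value}, \code{x}, \code{y}
#' @export
evaluate_field <- function(space, coef, patch, u, v) {
  pa <- space$mesh$patches[[patch]]
  p <- space$degree
  Uu <- space$pknots[[patch]]$Uu; Uv <- space$pknots[[patch]]$Uv
  ldofs <- space$patch_dofs[[patch]]
  n <- max(length(u), length(v))
  u <- rep_len(u, n); v <- rep_len(v, n)
  val <- numeric(n); xs <- numeric(n); ys <- numeric(n)
  for (k in seq_len(n)) {
    ku <- min(floor(u[k]) + 1, pa$n_u); kv <- min(floor(v[k]) + 1, pa$n_v)
    au <- active_funs(Uu, ku, p); av <- active_funs(Uv, kv, p)
    Bu <- bspline_all(u[k], p, Uu); Bv <- bspline_all(v[k], p, Uv)
    N <- outer(Bu$val[au], Bv$val[av])
    cc <- matrix(coef[ldofs[au, av]], p + 1L, p + 1L)
    val[k] <- sum(N * cc)
    q <- patch_corners(space$mesh, pa, ku, kv)
    bm <- bilinear_map(q, u[k] - (ku - 1), v[k] - (kv - 1))
    xs[k] <- bm$x[1]; ys[k] <- bm$x[2]
  }
  list(value = val, x = xs, y = ys)
}

#' L2-project a function onto the spline space
#'
#' @param space a \code{spline_space}
#' @param f either a function of quadrature-point metadata (called as
#'   \code{f(qp)} with the \code{space$qp} data.frame, returning one value per
#'   point) or a numeric vector of values at the quadrature points
#' @return coefficient vector of length \code{space$ndof}
#' @export
project_field <- function(space, f) {
  vals <- if (is.function(f)) f(space$qp) else rep_len(f, length(space$w))
  M <- Matrix::crossprod(space$Phi, space$Phi * space$w)
  rhs <- Matrix::crossprod(space$Phi, vals * space$w)
  as.numeric(Matrix::solve(M, rhs))
}
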