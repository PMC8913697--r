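## Skeleton-based sweeping: convert a cleaned skeleton into a conforming
## quadrilateral control mesh of the planar tube domain.  Every branch (a
## maximal path between the root, branch points and leaves) becomes one
## structured patch of n_axial x n_transverse quads whose cross-sections sit
## perpendicular to the local centerline with half-width equal to the local
## radius.  At a bifurcation the incident branches are set back and the
## remaining hexagonal junction region is filled with a symmetric midpoint-
## subdivision template (six bilinear sub-patches around the hexagon
## centroid, two per incident branch), so the mesh is conforming and mirror-
## symmetric for any even transverse element count.

rot90ccw <- function(v) c(-v[2], v[1])

## piecewise-linear polyline sampler: positions, tangents and radii by arc
polyline_sampler <- function(pts, radii) {
  seg <- diff(pts)
  seglen <- sqrt(rowSums(seg^2))
  arc <- c(0, cumsum(seglen))
  len <- arc[length(arc)]
  pos <- function(s) {
    s <- pmin(pmax(s, 0), len)
    cbind(stats::approx(arc, pts[, 1], xout = s)$y,
          stats::approx(arc, pts[, 2], xout = s)$y)
  }
  tangent <- function(s) {
    s <- pmin(pmax(s, 1e-12), len - 1e-12)
    i <- findInterval(s, arc, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), nrow(seg))
    t(apply(cbind(i), 1, function(k) seg[k, ] / seglen[k]))
  }
  radius <- function(s) stats::approx(arc, radii, xout = pmin(pmax(s, 0), len))$y
  list(pos = pos, tangent = tangent, radius = radius, length = len)
}

## decompose skeleton into branches: maximal paths between root/junction/leaf
skeleton_branches <- function(skel) {
  nd <- skel$nodes
  children <- split(nd$id, factor(nd$parent, levels = nd$id))
  nkids <- lengths(children)
  names(nkids) <- nd$id
  root <- skeleton_root(skel)
  is_junction <- nkids >= 2L
  if (is_junction[as.character(root)])
    stop("meshing error: the root node must have a single child (inlet)")
  if (any(nkids > 2L))
    stop("meshing error: junctions with more than two children are unsupported (node ",
         nd$id[which(nkids > 2L)[1]], ")")
  branches <- list()
  walk <- function(start_id, s0, parent_branch, prefix = NULL) {
    path <- c(prefix, start_id)
    cur <- start_id
    repeat {
      kids <- children[[as.character(cur)]]
      if (length(kids) != 1L) break
      cur <- kids
      path <- c(path, cur)
      if (is_junction[as.character(cur)]) break
    }
    rows <- match(path, nd$id)
    pts <- as.matrix(nd[rows, c("x", "y")])
    radii <- nd$radius[rows]
    len <- sum(sqrt(rowSums(diff(pts)^2)))
    b <- length(branches) + 1L
    branches[[b]] <<- list(id = b, nodes = path, pts = pts, radii = radii,
                           length = len, s_start = s0,
                           parent_branch = parent_branch,
                           end_node = cur,
                           ends_at_junction = unname(is_junction[as.character(cur)]),
                           starts_at_junction = !is.null(prefix))
    if (is_junction[as.character(cur)]) {
      kids <- children[[as.character(cur)]]
      ## deterministic child order: by node id; children start at the junction
      for (k in sort(kids)) walk(k, s0 + len, b, prefix = cur)
    }
    b
  }
  ## root's single chain starts the first branch
  walk(root, 0, NA_integer_)
  branches
}

#' Sweep a skeleton into a quadrilateral control mesh
#'
#' @param skel a cleaned \code{\link{skeleton}}
#' @param n_transverse number of elements across the tube width (>= 2)
#' @param axial_density axial elements per micrometre of branch length
#' @param setback_factor branches are trimmed by \code{setback_factor} times
#'   the local radius on each side of a junction to make room for the
#'   three-patch junction template
#' @return an object of class \code{"control_mesh"}: vertices (um),
#'   counter-clockwise quad elements, patch descriptors, boundary edge tags
#'   (\code{inlet}, \code{outlet:<leaf id>}, \code{wall}) and an
#'   element-to-branch map with axial arc-length and transverse coordinates.
#' @export
sweep_mesh <- function(skel, n_transverse = 4, axial_density = 0.25,
                       setback_factor = 1.5) {
  stopifnot(inherits(skel, "skeleton"), n_transverse >= 2)
  branches <- skeleton_branches(skel)
  nd <- skel$nodes

  ## global vertex pool with coordinate dedup
  vx <- numeric(0); vy <- numeric(0)
  vhash <- new.env(hash = TRUE, parent = emptyenv())
  get_vid <- function(x, y) {
    key <- paste0(round(x, 7), "_", round(y, 7))
    id <- vhash[[key]]
    if (is.null(id)) {
      id <- length(vx) + 1L
      vx[id] <<- x; vy[id] <<- y
      vhash[[key]] <- id
    }
    id
  }
  patches <- list()
  add_patch <- function(grid_x, grid_y, branch, s_range, type, tags) {
    nu <- nrow(grid_x) - 1L; nv <- ncol(grid_x) - 1L
    grid <- matrix(0L, nu + 1L, nv + 1L)
    for (i in seq_len(nu + 1L)) for (j in seq_len(nv + 1L))
      grid[i, j] <- get_vid(grid_x[i, j], grid_y[i, j])
    p <- length(patches) + 1L
    patches[[p]] <<- list(id = p, grid = grid, n_u = nu, n_v = nv,
                          branch = unname(branch),
                          s_range = unname(as.numeric(s_range)), type = type,
                          tags = tags)
    p
  }

  junction_ids <- unique(unlist(lapply(branches, function(b)
    if (isTRUE(b$ends_at_junction)) b$end_node else NULL)))
  leaf_ids <- skeleton_leaves(skel)
  if (length(junction_ids) && n_transverse %% 2 != 0)
    stop("meshing error: branched skeletons require an even n_transverse")

  ## junction setbacks: large enough that the trimmed openings of adjacent
  ## branches do not overlap near the crotch
  samplers <- lapply(branches, function(b) polyline_sampler(b$pts, b$radii))
  setback <- stats::setNames(numeric(length(junction_ids)),
                             as.character(junction_ids))
  for (jn in junction_ids) {
    dirs <- list(); rads <- numeric(0)
    for (b in branches) {
      ps <- samplers[[b$id]]
      if (isTRUE(b$ends_at_junction) && b$end_node == jn) {
        dirs <- c(dirs, list(-ps$tangent(ps$length)[1, ]))
        rads <- c(rads, ps$radius(ps$length))
      }
      if (isTRUE(b$starts_at_junction) && b$nodes[1] == jn) {
        dirs <- c(dirs, list(ps$tangent(0)[1, ]))
        rads <- c(rads, ps$radius(0))
      }
    }
    d <- setback_factor * max(rads)
    for (i in seq_along(dirs)) for (j in seq_along(dirs)) if (i < j) {
      cosg <- sum(dirs[[i]] * dirs[[j]])
      gamma <- acos(pmin(pmax(cosg, -1), 1))
      if (gamma < 1e-6)
        stop("meshing error: coincident branch directions at junction node ", jn)
      d <- max(d, 1.1 * (rads[i] + rads[j]) / (2 * sin(gamma / 2)))
    }
    setback[as.character(jn)] <- d
  }

  openings <- list()  # per junction node id: (branch, role, patch, pos, dir, r)
  branch_info <- list()
  for (b in branches) {
    ps <- samplers[[b$id]]
    a <- if (isTRUE(b$starts_at_junction)) setback[as.character(b$nodes[1])] else 0
    bb <- if (isTRUE(b$ends_at_junction)) setback[as.character(b$end_node)] else 0
    if (ps$length - a - bb <= 1e-9)
      stop("meshing error: branch ", b$id,
           " is too short for its junction setbacks")
    branch_info[[b$id]] <- list(sampler = ps, trim0 = a, trim1 = bb)
  }

  for (b in branches) {
    info <- branch_info[[b$id]]
    ps <- info$sampler
    a <- info$trim0; bb <- info$trim1
    lt <- ps$length - a - bb
    nu <- max(1L, round(lt * axial_density))
    svals <- a + lt * (0:nu) / nu
    P <- ps$pos(svals); Tg <- ps$tangent(svals); R <- ps$radius(svals)
    gx <- matrix(0, nu + 1L, n_transverse + 1L)
    gy <- matrix(0, nu + 1L, n_transverse + 1L)
    for (i in seq_len(nu + 1L)) {
      nrm <- rot90ccw(Tg[i, ])
      tt <- 2 * (0:n_transverse) / n_transverse - 1
      gx[i, ] <- P[i, 1] + R[i] * nrm[1] * tt
      gy[i, ] <- P[i, 2] + R[i] * nrm[2] * tt
    }
    tags <- list()
    tags$v0 <- "wall"; tags$v1 <- "wall"
    if (!isTRUE(b$starts_at_junction) && is.na(b$parent_branch))
      tags$u0 <- "inlet"
    if (!isTRUE(b$ends_at_junction))
      tags$u1 <- paste0("outlet:", b$end_node)
    pid <- add_patch(gx, gy, b$id,
                     c(b$s_start + a, b$s_start + a + lt), "branch", tags)
    ## record junction openings
    if (isTRUE(b$starts_at_junction)) {
      jn <- b$nodes[1]
      d <- Tg[1, ]                 # outgoing from junction
      openings[[as.character(jn)]] <- c(openings[[as.character(jn)]], list(list(
        branch = b$id, role = "child", patch = pid,
        pos = P[1, ], dir = d, r = R[1])))
    }
    if (isTRUE(b$ends_at_junction)) {
      jn <- b$end_node
      d <- -Tg[nu + 1L, ]          # outgoing from junction
      openings[[as.character(jn)]] <- c(openings[[as.character(jn)]], list(list(
        branch = b$id, role = "parent", patch = pid,
        pos = P[nu + 1L, ], dir = d, r = R[nu + 1L])))
    }
  }

  ## junction templates
  for (jn in names(openings)) {
    ops <- openings[[jn]]
    if (length(ops) != 3L)
      stop("meshing error: junction at node ", jn, " does not have 3 openings")
    jrow <- match(as.integer(jn), nd$id)
    jpos <- c(nd$x[jrow], nd$y[jrow])
    ang <- vapply(ops, function(o) atan2(o$dir[2], o$dir[1]), 0)
    ops <- ops[order(ang)]
    ## hexagon, CCW: per opening (E-, E+) with E+- = pos -+ r * rot90(dir)
    hex <- matrix(0, 6, 2)
    for (i in 1:3) {
      o <- ops[[i]]
      nrm <- rot90ccw(o$dir)
      hex[2 * i - 1, ] <- o$pos - o$r * nrm
      hex[2 * i, ] <- o$pos + o$r * nrm
    }
    ctr <- colMeans(hex)
    ## star-shapedness: hexagon vertices must wind CCW around the centroid
    angs <- atan2(hex[, 2] - ctr[2], hex[, 1] - ctr[1])
    dth <- diff(c(angs, angs[1] + 2 * pi)) %% (2 * pi)
    if (any(dth <= 1e-9) || abs(sum(dth) - 2 * pi) > 1e-6)
      stop("meshing error: degenerate junction region at node ", jn)
    s_jn <- NA_real_
    ## arc length from the inlet at this junction = s_start + length of the
    ## branch that ends here
    for (b in branches) if (isTRUE(b$ends_at_junction) && b$end_node == as.integer(jn))
      s_jn <- b$s_start + b$length
    ## midpoint-subdivision template: center + edge midpoints give six
    ## bilinear sub-patches (H_k, M_k, C, M_{k-1}), each n_t/2 x n_t/2
    nh <- n_transverse %/% 2L
    mids <- (hex + hex[c(2:6, 1), ]) / 2          # M_k = mid(H_k, H_k+1)
    for (k in 1:6) {
      Hk <- hex[k, ]; Mk <- mids[k, ]
      Mprev <- mids[if (k == 1L) 6L else k - 1L, ]
      c00 <- Hk; c10 <- Mk; c01 <- Mprev; c11 <- ctr
      gx <- matrix(0, nh + 1L, nh + 1L); gy <- matrix(0, nh + 1L, nh + 1L)
      for (iu in 0:nh) for (iv in 0:nh) {
        u <- iu / nh; v <- iv / nh
        pt <- (1 - u) * (1 - v) * c00 + u * (1 - v) * c10 +
          (1 - u) * v * c01 + u * v * c11
        gx[iu + 1L, iv + 1L] <- pt[1]; gy[iu + 1L, iv + 1L] <- pt[2]
      }
      ## hexagon edge k (H_k -> H_k+1) lies on side v0; edge k-1 on side u0;
      ## odd edges are branch openings (internal), even edges are walls
      tags <- list()
      if (k %% 2 == 0) tags$v0 <- "wall"
      if ((if (k == 1L) 6L else k - 1L) %% 2 == 0) tags$u0 <- "wall"
      o <- ops[[(k + 1L) %/% 2L]]
      add_patch(gx, gy, branches[[o$branch]]$id,
                c(s_jn, s_jn), "junction", tags)
    }
  }

  vertices <- cbind(x = vx, y = vy)
  ## element table
  elts <- list(); ek <- 0L
  el_patch <- integer(0)
  for (p in patches) {
    for (iu in seq_len(p$n_u)) for (iv in seq_len(p$n_v)) {
      ek <- ek + 1L
      elts[[ek]] <- c(p$grid[iu, iv], p$grid[iu + 1L, iv],
                      p$grid[iu + 1L, iv + 1L], p$grid[iu, iv + 1L])
      el_patch[ek] <- p$id
    }
  }
  elements <- do.call(rbind, elts)
  ## positive-orientation check at element corners
  for (e in seq_len(nrow(elements))) {
    q <- vertices[elements[e, ], ]
    ar <- sum(q[, 1] * q[c(2, 3, 4, 1), 2] - q[c(2, 3, 4, 1), 1] * q[, 2]) / 2
    if (ar <= 0) {
      bid <- patches[[el_patch[e]]]$branch
      stop("meshing error: inverted element in branch ", bid,
           " (radius exceeds local turning room)")
    }
  }
  mesh <- structure(list(vertices = vertices, elements = elements,
                         element_patch = el_patch, patches = patches,
                         branches = branches, n_transverse = n_transverse,
                         axial_density = axial_density,
                         leaf_ids = leaf_ids, skeleton = skel),
                    class = "control_mesh")
  mesh
}

#' @export
print.control_mesh <- function(x, ...) {
  cat("<control_mesh> ", nrow(x$vertices), " vertices, ",
      nrow(x$elements), " quads, ", length(x$patches), " patches (",
      sum(vapply(x$patches, function(p) p$type == "junction", TRUE)),
      " junction), area ", signif(mesh_area(x), 6), " um^2\n", sep = "")
  invisible(x)
}

#' Total mesh area (shoelace sum over quads)
#' @param mesh a \code{control_mesh}
#' @return area in um^2
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; el <- mesh$elements
  tot <- 0
  for (e in seq_len(nrow(el))) {
    q <- v[el[e, ], ]
    tot <- tot + sum(q[, 1] * q[c(2, 3, 4, 1), 2] -
                       q[c(2, 3, 4, 1), 1] * q[, 2]) / 2
  }
  tot
}
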