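## Synthetic test geometries: straight pipes, bifurcations, branched trees and
## pipes with a local swelling.  These are the study domains used throughout
## the package's experiments; all dimensions are micrometres.

#' Cubic smoothstep
#'
#' The C1 ramp 3u^2 - 2u^3 clamped to [0, 1]; building block of every smooth
#' transition profile used in the package (swelling bumps, microtubule-density
#' dips and swirl-region transitions).
#'
#' @param u numeric vector
#' @return values in [0, 1]
#' @export
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

## C1 bump: 1 at center, 0 outside |s - center| >= halfwidth.
bump_profile <- function(s, center, halfwidth) {
  1 - smoothstep(abs(s - center) / halfwidth)
}

## C1 plateau profile: 1 on [a + tw, b - tw], 0 outside [a, b].
plateau_profile <- function(s, a, b, tw) {
  tw <- max(min(tw, (b - a) / 2), 1e-12)
  up <- smoothstep((s - a) / tw)
  down <- smoothstep((b - s) / tw)
  pmin(up, down)
}

#' Specify a synthetic tube geometry
#'
#' @param kind one of \code{"pipe"}, \code{"bifurcation"}, \code{"tree"},
#'   \code{"swollen_pipe"}, \code{"from_swc"}.
#' @param length pipe/trunk length (um).
#' @param base_radius tube half-width (um).
#' @param spacing axial skeleton-node spacing (um).
#' @param branch_length length of daughter branches (um, bifurcation).
#' @param branch_angle daughter half-angle (radians, bifurcation).
#' @param branches for \code{kind = "tree"}: data.frame with columns
#'   \code{parent} (0 for the trunk, else branch row index), \code{length}
#'   (um), \code{angle} (radians, relative to the parent branch direction) and
#'   optionally \code{radius} (um).
#' @param swelling optional list \code{(s0, L2, amplification)}: center
#'   arc-length (um from the inlet), swollen extent (um) and peak radius
#'   amplification factor (> 1).
#' @param swc_path SWC file path for \code{kind = "from_swc"}.
#' @return an object of class \code{"geometry_spec"}
#' @export
geometry_spec <- function(kind = c("pipe", "bifurcation", "tree",
                                   "swollen_pipe", "from_swc"),
                          length = 80, base_radius = 2, spacing = 4,
                          branch_length = 40, branch_angle = pi / 6,
                          branches = NULL, swelling = NULL, swc_path = NULL) {
  kind <- match.arg(kind)
  if (length <= 0 || base_radius <= 0 || spacing <= 0)
    stop("geometry spec error: all lengths must be positive")
  if (!is.null(swelling)) {
    stopifnot(all(c("s0", "L2", "amplification") %in% names(swelling)))
    if (swelling$amplification <= 1)
      stop("geometry spec error: swelling amplification must exceed 1")
    if (swelling$L2 <= 0) stop("geometry spec error: swelling extent must be positive")
  }
  if (kind == "swollen_pipe" && is.null(swelling))
    stop("geometry spec error: swollen_pipe requires a swelling specification")
  if (kind == "tree") {
    if (is.null(branches) || !all(c("parent", "length", "angle") %in% names(branches)))
      stop("geometry spec error: tree requires branches with parent/length/angle")
    if (any(branches$length <= 0))
      stop("geometry spec error: branch lengths must be positive")
  }
  if (kind == "from_swc" && is.null(swc_path))
    stop("geometry spec error: from_swc requires swc_path")
  structure(list(kind = kind, length = length, base_radius = base_radius,
                 spacing = spacing, branch_length = branch_length,
                 branch_angle = branch_angle, branches = branches,
                 swelling = swelling, swc_path = swc_path),
            class = "geometry_spec")
}

#' Radius profile of a (possibly swollen) pipe
#'
#' Constant \code{base_radius} away from the swelling; inside the swelling
#' window \code{[s0 - L2/2, s0 + L2/2]} the radius is amplified following a
#' C1 cubic-smoothstep bump that peaks at \code{amplification * base_radius}
#' at \code{s0}.
#'
#' @param s arc length from the inlet (um)
#' @param spec a \code{geometry_spec}
#' @return radii (um)
#' @export
radius_profile <- function(s, spec) {
  r <- rep(spec$base_radius, length(s))
  sw <- spec$swelling
  if (!is.null(sw))
    r <- spec$base_radius *
      (1 + (sw$amplification - 1) * bump_profile(s, sw$s0, sw$L2 / 2))
  r
}

#' Build a synthetic skeleton from a geometry specification
#'
#' \itemize{
#'   \item \code{pipe}: straight chain along +x with constant radius.
#'   \item \code{swollen_pipe}: straight chain whose radius follows
#'     \code{\link{radius_profile}}.
#'   \item \code{bifurcation}: a trunk splitting into two mirror-image
#'     daughters at \code{+/- branch_angle}.
#'   \item \code{tree}: recursive branching from the \code{branches} table.
#'   \item \code{from_swc}: read and clean the referenced SWC file.
#' }
#'
#' @param spec a \code{\link{geometry_spec}}
#' @return a \code{\link{skeleton}}
#' @export
make_synthetic_skeleton <- function(spec) {
  stopifnot(inherits(spec, "geometry_spec"))
  if (spec$kind == "from_swc")
    return(clean_skeleton(read_swc(spec$swc_path)))
  rows <- list()
  nid <- 0L
  add_node <- function(x, y, r, parent) {
    nid <<- nid + 1L
    rows[[nid]] <<- data.frame(id = nid, type = 3L, x = x, y = y,
                               radius = r, parent = parent)
    nid
  }
  chain <- function(p0, dir, len, from_id, s_offset, rad_fun) {
    n <- max(1L, round(len / spec$spacing))
    last <- from_id
    for (k in seq_len(n)) {
      s <- len * k / n
      pos <- p0 + dir * s
      last <- add_node(pos[1], pos[2], rad_fun(s_offset + s), last)
    }
    last
  }
  rad <- function(s) radius_profile(s, spec)
  if (spec$kind %in% c("pipe", "swollen_pipe")) {
    root <- add_node(0, 0, rad(0), -1L)
    chain(c(0, 0), c(1, 0), spec$length, root, 0, rad)
  } else if (spec$kind == "bifurcation") {
    root <- add_node(0, 0, spec$base_radius, -1L)
    jid <- chain(c(0, 0), c(1, 0), spec$length, root, 0,
                 function(s) spec$base_radius)
    jpos <- c(spec$length, 0)
    for (sgn in c(1, -1)) {
      a <- sgn * spec$branch_angle
      dir <- c(cos(a), sgn * abs(sin(a)))
      chain(jpos, dir, spec$branch_length, jid, spec$length,
            function(s) spec$base_radius)
    }
  } else if (spec$kind == "tree") {
    br <- spec$branches
    if (!is.null(br$radius) && any(br$radius <= 0))
      stop("geometry spec error: branch radii must be positive")
    nb <- nrow(br)
    end_id <- integer(nb); end_pos <- vector("list", nb)
    end_dir <- vector("list", nb); end_s <- numeric(nb)
    for (b in seq_len(nb)) {
      pb <- br$parent[b]
      if (pb < 0 || pb >= b)
        stop("geometry spec error: branch parents must precede their children")
      rb <- if (!is.null(br$radius)) br$radius[b] else spec$base_radius
      if (pb == 0L) {
        if (nid == 0L) add_node(0, 0, rb, -1L)
        from <- 1L; p0 <- c(0, 0); pdir <- c(1, 0); s0 <- 0
      } else {
        from <- end_id[pb]; p0 <- end_pos[[pb]]; pdir <- end_dir[[pb]]
        s0 <- end_s[pb]
      }
      a <- br$angle[b]
      dir <- c(cos(a) * pdir[1] - sin(a) * pdir[2],
               sin(a) * pdir[1] + cos(a) * pdir[2])
      end_id[b] <- chain(p0, dir, br$length[b], from, s0, function(s) rb)
      end_pos[[b]] <- p0 + dir * br$length[b]
      end_dir[[b]] <- dir
      end_s[b] <- s0 + br$length[b]
    }
  }
  skeleton(do.call(rbind, rows))
}
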