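#' @importFrom Matrix sparseMatrix crossprod solve lu rowSums
#' @importFrom methods as
#' @importFrom stats approx dist quantile rnorm setNames
#' @importFrom utils head tail write.csv packageVersion
#' @importFrom graphics matplot
NULL

#' Neuron skeleton objects
#'
#' A skeleton is a rooted tree of centerline nodes with radii, following SWC
#' semantics: every node has an integer id, an SWC structure-type code, a
#' planar position in micrometres, a radius in micrometres, and a parent id
#' (\code{-1} for the root).  The root is the transport inlet and every leaf
#' is an outlet.
#'
#' @param nodes data.frame with columns \code{id}, \code{type}, \code{x},
#'   \code{y}, \code{radius}, \code{parent}.
#' @return An object of class \code{"skeleton"}.
#' @export
skeleton <- function(nodes) {
  stopifnot(is.data.frame(nodes))
  need <- c("id", "type", "x", "y", "radius", "parent")
  if (!all(need %in% names(nodes)))
    stop("skeleton nodes need columns: ", paste(need, collapse = ", "))
  nodes <- nodes[, need]
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  obj <- structure(list(nodes = nodes), class = "skeleton")
  validate_skeleton(obj)
  obj
}

validate_skeleton <- function(skel, pos_tol = 0) {
  nd <- skel$nodes
  if (nrow(nd) == 0L) stop("skeleton structure error: no nodes")
  if (anyDuplicated(nd$id)) stop("skeleton structure error: duplicated node ids")
  if (any(nd$radius <= 0)) stop("skeleton structure error: non-positive radius")
  roots <- nd$id[nd$parent == -1L]
  if (length(roots) != 1L)
    stop("skeleton structure error: expected exactly one root, found ",
         length(roots))
  known <- c(-1L, nd$id)
  if (!all(nd$parent %in% known))
    stop("skeleton structure error: parent id refers to a missing node")
  ## connectivity + acyclicity: walk each node up to the root
  idx <- match(nd$parent, nd$id)
  n <- nrow(nd)
  for (i in seq_len(n)) {
    seen <- integer(0); j <- i; steps <- 0L
    while (!is.na(j)) {
      steps <- steps + 1L
      if (steps > n) stop("skeleton structure error: cycle detected")
      j <- idx[j]
    }
  }
  ## zero-length edges
  ii <- which(!is.na(idx))
  if (length(ii)) {
    d <- sqrt((nd$x[ii] - nd$x[idx[ii]])^2 + (nd$y[ii] - nd$y[idx[ii]])^2)
    if (any(d <= pos_tol))
      stop("skeleton structure error: zero-length edge at node id ",
           nd$id[ii[which(d <= pos_tol)[1]]])
  }
  invisible(skel)
}

#' @export
print.skeleton <- function(x, ...) {
  nd <- x$nodes
  cat("<skeleton> ", nrow(nd), " nodes, root id ", skeleton_root(x),
      ", ", length(skeleton_leaves(x)), " outlet(s)\n", sep = "")
  cat("  extent: x [", round(min(nd$x), 3), ", ", round(max(nd$x), 3),
      "] um, y [", round(min(nd$y), 3), ", ", round(max(nd$y), 3),
      "] um, radii [", round(min(nd$radius), 3), ", ",
      round(max(nd$radius), 3), "] um\n", sep = "")
  invisible(x)
}

#' Inlet (root) node id of a skeleton
#' @param skel a \code{skeleton}
#' @return integer node id
#' @export
skeleton_root <- function(skel) skel$nodes$id[skel$nodes$parent == -1L]

#' Outlet (leaf) node ids of a skeleton
#' @param skel a \code{skeleton}
#' @return integer vector of node ids (nodes that are no node's parent)
#' @export
skeleton_leaves <- function(skel) {
  nd <- skel$nodes
  sort(setdiff(nd$id, nd$parent))
}

#' Read an SWC morphology file
#'
#' Parses the standard whitespace-separated 7-column SWC format
#' (id, type, x, y, z, radius, parent); lines starting with \code{#} are
#' comments.  The solver operates on planar geometries, so the z column is
#' discarded; a warning is emitted when any |z| exceeds \code{z_tol}.
#'
#' @param path path to an SWC file
#' @param z_tol tolerance (um) above which dropped z coordinates trigger a
#'   warning
#' @return a \code{\link{skeleton}}
#' @export
read_swc <- function(path, z_tol = 1e-9) {
  if (!file.exists(path)) stop("SWC file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- which(keep)
  if (length(lines) == 0L)
    stop("skeleton structure error: SWC file has no data records: ", path)
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) != 7L)
      stop("SWC parse error at line ", lineno[i], ": expected 7 fields, got ",
           length(f))
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v))
      stop("SWC parse error at line ", lineno[i], ": non-numeric field")
    rows[[i]] <- v
  }
  m <- do.call(rbind, rows)
  if (any(abs(m[, 5]) > z_tol))
    warning("SWC z-coordinates are non-zero and were discarded (planar model)")
  skeleton(data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                      x = m[, 3], y = m[, 4], radius = m[, 6],
                      parent = as.integer(m[, 7])))
}

#' Write a skeleton to an SWC file
#'
#' Inverse of \code{\link{read_swc}}: writes 7-column records with z = 0.
#'
#' @param skel a \code{skeleton}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_swc <- function(skel, path) {
  nd <- skel$nodes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# id type x y z radius parent", con)
  for (i in seq_len(nrow(nd))) {
    writeLines(sprintf("%d %d %.9f %.9f 0 %.9f %d", nd$id[i], nd$type[i],
                       nd$x[i], nd$y[i], nd$radius[i], nd$parent[i]), con)
  }
  invisible(path)
}

#' Merge near-duplicate skeleton nodes and collapse short edges
#'
#' Nodes closer than \code{tol} are merged (the surviving node is the one
#' with the lower id; children of the removed node are re-linked), which also
#' removes the zero-length edges such duplicates create.  The operation is
#' idempotent and never increases the node count.
#'
#' @param skel a \code{skeleton}
#' @param tol merge tolerance in micrometres (default \code{1e-6})
#' @return a cleaned \code{skeleton}
#' @export
clean_skeleton <- function(skel, tol = 1e-6) {
  nd <- skel$nodes
  repeat {
    n <- nrow(nd)
    d2 <- as.matrix(stats::dist(nd[, c("x", "y")]))
    diag(d2) <- Inf
    hit <- which(d2 <= tol, arr.ind = TRUE)
    if (nrow(hit) == 0L) break
    ## merge the pair with the lowest surviving id deterministically
    pair <- hit[order(pmin(nd$id[hit[, 1]], nd$id[hit[, 2]]),
                      pmax(nd$id[hit[, 1]], nd$id[hit[, 2]]))[1], ]
    keep_i <- pair[which.min(nd$id[pair])]
    drop_i <- pair[which.max(nd$id[pair])]
    keep_id <- nd$id[keep_i]; drop_id <- nd$id[drop_i]
    ## the removed node's children point at the survivor
    nd$parent[nd$parent == drop_id] <- keep_id
    ## if survivor was child of dropped or vice versa keep surviving parentage
    if (nd$parent[keep_i] == drop_id) nd$parent[keep_i] <- nd$parent[drop_i]
    nd <- nd[-drop_i, ]
    ## self-parent guard (dropped node was parent of survivor chain)
    if (any(nd$parent == nd$id))
      stop("skeleton structure error: cleaning would disconnect the tree")
    if (nrow(nd) == n) break
  }
  out <- try(skeleton(nd), silent = TRUE)
  if (inherits(out, "try-error"))
    stop("skeleton structure error: cleaning would disconnect the tree")
  out
}
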