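## Diagnostics and exporters: centerline concentration profiles, vorticity
## summaries for swirl scenarios, and VTK/CSV/JSON artifact export.

## ordered branch path from the root branch to the branch ending at a leaf
branch_path_to <- function(mesh, outlet_id) {
  branches <- mesh$branches
  endb <- NULL
  for (b in branches) if (b$end_node == outlet_id &&
                          !isTRUE(b$ends_at_junction)) endb <- b
  if (is.null(endb)) stop("lookup error: unknown outlet id ", outlet_id)
  path <- endb$id
  cur <- endb
  while (!is.na(cur$parent_branch)) {
    cur <- branches[[cur$parent_branch]]
    path <- c(cur$id, path)
  }
  path
}

#' Centerline concentration profile from the inlet to an outlet
#'
#' Samples the summed concentration (free plus bound, both directions in
#' bidirectional mode) along the centerline of the unique branch path from
#' the inlet to the requested outlet, at a spacing of half the axial element
#' size.
#'
#' @param result a \code{scenario_result} (or any list with \code{space} and
#'   \code{solution})
#' @param outlet_id leaf node id of the target outlet (defaults to the first
#'   tagged outlet)
#' @return an object of class \code{"centerline_profile"}: data.frame with
#'   \code{s} (um from the inlet) and \code{value} (mol/um^2), with the
#'   branch path in attribute \code{"path"}
#' @export
centerline_profile <- function(result, outlet_id = NULL) {
  space <- result$space
  sol <- result$solution
  mesh <- space$mesh
  if (is.null(outlet_id)) {
    tags <- grep("^outlet:", names(space$bnd), value = TRUE)
    outlet_id <- as.integer(sub("^outlet:", "", tags[1]))
  }
  if (!paste0("outlet:", outlet_id) %in% names(space$bnd))
    stop("lookup error: unknown outlet id ", outlet_id)
  path <- branch_path_to(mesh, outlet_id)
  conc <- sol$state$n0 + sol$state$np
  if (!is.null(sol$state$nm)) conc <- conc + sol$state$nm
  ss <- list(); vv <- list()
  for (bid in path) {
    pid <- which(vapply(mesh$patches, function(p)
      p$type == "branch" && p$branch == bid, TRUE))
    pa <- mesh$patches[[pid]]
    n_samp <- 2L * pa$n_u + 1L
    u <- seq(0, pa$n_u, length.out = n_samp)
    ev <- evaluate_field(space, conc, pid, u, rep(pa$n_v / 2, n_samp))
    ss[[length(ss) + 1L]] <- pa$s_range[1] +
      (u / pa$n_u) * diff(pa$s_range)
    vv[[length(vv) + 1L]] <- ev$value
  }
  out <- data.frame(s = unlist(ss), value = unlist(vv))
  out <- out[!duplicated(out$s), ]
  out <- out[order(out$s), ]
  rownames(out) <- NULL
  attr(out, "path") <- path
  attr(out, "outlet_id") <- outlet_id
  class(out) <- c("centerline_profile", class(out))
  out
}

#' @export
plot.centerline_profile <- function(x, ...) {
  graphics::plot(x$s, x$value, type = "l", xlab = "arc length s (um)",
                 ylab = "concentration (mol/um^2)", ...)
  invisible(x)
}

#' Vorticity diagnostics of a bidirectional transport solution
#'
#' Computes the scalar curl of the summed transport velocity v+ + v- at
#' every quadrature point, its integral (circulation) over an axial region,
#' and the overlap score: the fraction of the top-decile-concentration area
#' that lies in the counter-clockwise (positive-curl) region.
#'
#' @param result a \code{scenario_result} from a bidirectional run
#' @param region optional \code{list(s = c(s1, s2))} axial window for the
#'   circulation (defaults to the scenario's swirl region, or the full
#'   domain)
#' @return an object of class \code{"vortex_summary"}: list with
#'   \code{curl} (per quadrature point, 1/s), \code{circulation},
#'   \code{overlap_score}
#' @export
vortex_diagnostics <- function(result, region = NULL) {
  space <- result$space
  sol <- result$solution
  if (is.null(sol$state$wx))
    stop("configuration error: vortex diagnostics require a bidirectional result")
  if (is.null(region)) region <- result$region
  vx <- sol$state$vx + sol$state$wx
  vy <- sol$state$vy + sol$state$wy
  curl <- as.numeric(space$Phix %*% vy) - as.numeric(space$Phiy %*% vx)
  sel <- if (is.null(region)) rep(TRUE, length(curl))
  else space$qp$s >= min(region$s) & space$qp$s <= max(region$s)
  circulation <- sum((space$w * curl)[sel])
  conc <- sol$state$n0 + sol$state$np + sol$state$nm
  concq <- as.numeric(space$Phi %*% conc)
  thr <- stats::quantile(concq, 0.9)
  hi <- concq >= thr
  overlap <- sum(space$w[hi & curl > 0]) / sum(space$w[hi])
  structure(list(curl = curl, circulation = circulation,
                 overlap_score = overlap, region = region),
            class = "vortex_summary")
}

#' @export
print.vortex_summary <- function(x, ...) {
  cat(sprintf("<vortex_summary> circulation %.4g um^2/s, overlap score %.3f\n",
              x$circulation, x$overlap_score))
  invisible(x)
}

## evaluate a coefficient field at the control-mesh vertices
vertex_values <- function(space, coef) {
  mesh <- space$mesh
  out <- rep(NA_real_, nrow(mesh$vertices))
  for (pa in mesh$patches) {
    g <- pa$grid
    iu <- rep(seq_len(nrow(g)), times = ncol(g)) - 1
    iv <- rep(seq_len(ncol(g)), each = nrow(g)) - 1
    vids <- as.integer(g)
    new <- is.na(out[vids])
    if (!any(new)) next
    ev <- evaluate_field(space, coef, pa$id, iu[new], iv[new])
    out[vids[new]] <- ev$value
  }
  out
}

## fields exported as VTK point data for a scenario result
result_point_data <- function(res) {
  space <- res$space
  sol <- res$solution
  fields <- list(n0 = sol$state$n0, np = sol$state$np,
                 vx = sol$state$vx, vy = sol$state$vy,
                 fx = sol$control$fx, fy = sol$control$fy,
                 l_plus = res$mt$lp_coef,
                 Vx = res$target$vx, Vy = res$target$vy)
  if (!is.null(sol$state$nm)) {
    fields$nm <- sol$state$nm
    fields$wx <- sol$state$wx; fields$wy <- sol$state$wy
    fields$gx <- sol$control$gx; fields$gy <- sol$control$gy
    fields$l_minus <- res$mt$lm_coef
  }
  lapply(fields, function(coef) vertex_values(space, coef))
}

#' Write a mesh (with optional point data) as a legacy VTK file
#'
#' @param mesh a \code{control_mesh}
#' @param path output file path
#' @param point_data named list of per-vertex numeric vectors
#' @return \code{path}, invisibly
#' @export
write_vtk_legacy <- function(mesh, path, point_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices); ne <- nrow(mesh$elements)
  writeLines(c("# vtk DataFile Version 3.0",
               "neurotransport export", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", nv, "double")), con)
  writeLines(sprintf("%.9g %.9g 0", mesh$vertices[, 1], mesh$vertices[, 2]),
             con)
  writeLines(paste("CELLS", ne, 5 * ne), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$elements[, 1] - 1L,
                     mesh$elements[, 2] - 1L, mesh$elements[, 3] - 1L,
                     mesh$elements[, 4] - 1L), con)
  writeLines(paste("CELL_TYPES", ne), con)
  writeLines(rep("9", ne), con)
  if (length(point_data)) {
    writeLines(paste("POINT_DATA", nv), con)
    for (nm in names(point_data)) {
      writeLines(c(paste("SCALARS", nm, "double 1"),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", point_data[[nm]]), con)
    }
  }
  invisible(path)
}

#' Write a mesh (with optional point data) as a VTK XML .vtu file
#'
#' @inheritParams write_vtk_legacy
#' @return \code{path}, invisibly
#' @export
write_vtk_xml <- function(mesh, path, point_data = list()) {
  nv <- nrow(mesh$vertices); ne <- nrow(mesh$elements)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("<?xml version=\"1.0\"?>")
  w("<VTKFile type=\"UnstructuredGrid\" version=\"0.1\" byte_order=\"LittleEndian\">")
  w("  <UnstructuredGrid>")
  w(sprintf("    <Piece NumberOfPoints=\"%d\" NumberOfCells=\"%d\">", nv, ne))
  w("      <Points>")
  w("        <DataArray type=\"Float64\" NumberOfComponents=\"3\" format=\"ascii\">")
  writeLines(sprintf("%.9g %.9g 0", mesh$vertices[, 1], mesh$vertices[, 2]),
             con)
  w("        </DataArray>")
  w("      </Points>")
  w("      <Cells>")
  w("        <DataArray type=\"Int32\" Name=\"connectivity\" format=\"ascii\">")
  writeLines(sprintf("%d %d %d %d", mesh$elements[, 1] - 1L,
                     mesh$elements[, 2] - 1L, mesh$elements[, 3] - 1L,
                     mesh$elements[, 4] - 1L), con)
  w("        </DataArray>")
  w("        <DataArray type=\"Int32\" Name=\"offsets\" format=\"ascii\">")
  writeLines(sprintf("%d", seq_len(ne) * 4L), con)
  w("        </DataArray>")
  w("        <DataArray type=\"UInt8\" Name=\"types\" format=\"ascii\">")
  writeLines(rep("9", ne), con)
  w("        </DataArray>")
  w("      </Cells>")
  if (length(point_data)) {
    w("      <PointData>")
    for (nm in names(point_data)) {
      w(sprintf("        <DataArray type=\"Float64\" Name=\"%s\" format=\"ascii\">", nm))
      writeLines(sprintf("%.9g", point_data[[nm]]), con)
      w("        </DataArray>")
    }
    w("      </PointData>")
  }
  w("    </Piece>")
  w("  </UnstructuredGrid>")
  w("</VTKFile>")
  invisible(path)
}

#' Read point data arrays from a legacy VTK file
#'
#' Minimal reader for the files written by \code{\link{write_vtk_legacy}};
#' used for round-trip verification.
#'
#' @param path VTK file path
#' @return named list of numeric vectors
#' @export
read_vtk_point_data <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINT_DATA", lines)
  if (!length(ip)) return(list())
  nv <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  out <- list()
  i <- ip + 1L
  while (i <= length(lines)) {
    if (grepl("^SCALARS", lines[i])) {
      nm <- strsplit(lines[i], "\\s+")[[1]][2]
      vals <- as.numeric(lines[(i + 2L):(i + 1L + nv)])
      out[[nm]] <- vals
      i <- i + 2L + nv
    } else i <- i + 1L
  }
  out
}

#' Export scenario artifacts
#'
#' Writes the requested artifacts under a base path: the mesh and solution
#' fields as VTK (legacy \code{.vtk} and XML \code{.vtu}), per-outlet
#' centerline profiles as CSV, the solver convergence history as CSV, and a
#' JSON run manifest with the full resolved configuration.
#'
#' @param result a \code{scenario_result}
#' @param what subset of \code{c("mesh", "fields", "profiles", "history",
#'   "manifest")}
#' @param path base output path (directory is created); file names are
#'   derived from the scenario name
#' @return character vector of files written
#' @export
export_result <- function(result, what = c("mesh", "fields", "profiles",
                                           "history", "manifest"),
                          path = ".") {
  what <- match.arg(what, several.ok = TRUE)
  if (!dir.exists(path))
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(path, result$config$scenario)
  files <- character(0)
  pd <- if ("fields" %in% what) result_point_data(result) else list()
  if (any(c("mesh", "fields") %in% what)) {
    f1 <- paste0(base, ".vtk"); f2 <- paste0(base, ".vtu")
    write_vtk_legacy(result$mesh, f1, pd)
    write_vtk_xml(result$mesh, f2, pd)
    files <- c(files, f1, f2)
  }
  if ("profiles" %in% what) {
    for (oid in result$diagnostics$outlet_ids) {
      pr <- centerline_profile(result, oid)
      f <- paste0(base, "_profile_outlet", oid, ".csv")
      utils::write.csv(as.data.frame(pr), f, row.names = FALSE)
      files <- c(files, f)
    }
  }
  if ("history" %in% what) {
    f <- paste0(base, "_history.csv")
    utils::write.csv(result$solution$history, f, row.names = FALSE)
    files <- c(files, f)
  }
  if ("manifest" %in% what) {
    f <- paste0(base, "_manifest.json")
    cfg <- result$config
    manifest <- list(
      scenario = cfg$scenario,
      geometry = if (inherits(cfg$geometry, "skeleton"))
        list(kind = "skeleton", nodes = nrow(cfg$geometry$nodes))
      else cfg$geometry[!vapply(cfg$geometry, is.null, TRUE)],
      region = result$region, depth = cfg$depth,
      amplification = cfg$amplification, asymmetry = cfg$asymmetry,
      params = unclass(cfg$params),
      n_transverse = cfg$n_transverse,
      axial_density = cfg$axial_density, degree = cfg$degree,
      inflow_speed = cfg$inflow_speed, seed = cfg$seed,
      options = unclass(cfg$options),
      converged = result$solution$converged,
      package_version = tryCatch(
        as.character(utils::packageVersion("neurotransport")),
        error = function(e) NA_character_))
    jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(files, f)
  }
  files
}

#' Rebuild and re-run a scenario from an exported manifest
#'
#' @param manifest_path path to a JSON manifest written by
#'   \code{\link{export_result}}
#' @return a \code{scenario_result}
#' @export
rerun_manifest <- function(manifest_path) {
  mf <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  geom <- if (identical(mf$geometry$kind, "skeleton"))
    stop("manifest error: skeleton geometries must be re-supplied as SWC")
  else do.call(geometry_spec, c(list(kind = mf$geometry$kind),
    mf$geometry[setdiff(names(mf$geometry), "kind")]))
  params <- do.call(parameter_set, mf$params)
  opts <- do.call(solver_options, mf$options[setdiff(names(mf$options),
                                                     "random_seed")])
  region <- if (!is.null(mf$region))
    list(branch = mf$region$branch, s = as.numeric(mf$region$s))
  cfg <- scenario_config(scenario = mf$scenario, geometry = geom,
                         region = region, depth = mf$depth,
                         amplification = mf$amplification,
                         asymmetry = mf$asymmetry, params = params,
                         n_transverse = mf$n_transverse,
                         axial_density = mf$axial_density,
                         degree = mf$degree,
                         inflow_speed = mf$inflow_speed,
                         options = opts, seed = mf$seed)
  run_scenario(cfg)
}
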