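#' Read a scenario configuration from YAML or JSON
#'
#' The file may contain any \code{\link{scenario_config}} argument; nested
#' blocks \code{params}, \code{options}, \code{geometry} and \code{region}
#' are mapped onto \code{\link{parameter_set}}, \code{\link{solver_options}},
#' \code{\link{geometry_spec}} and the region list.  A geometry block with
#' \code{kind: from_swc} needs \code{swc_path}; a \code{branches} block (for
#' trees) is a table of \code{parent}, \code{length}, \code{angle} columns.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file
#' @return a \code{\link{scenario_config}}
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.(ya?ml)$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  if (!is.null(raw$scenario)) args$scenario <- raw$scenario
  if (!is.null(raw$geometry)) {
    g <- raw$geometry
    if (!is.null(g$branches)) g$branches <- as.data.frame(g$branches)
    if (!is.null(g$swelling)) g$swelling <- as.list(g$swelling)
    args$geometry <- do.call(geometry_spec, g)
  }
  if (!is.null(raw$region))
    args$region <- list(branch = raw$region$branch,
                        s = as.numeric(unlist(raw$region$s)))
  if (!is.null(raw$params))
    args$params <- do.call(parameter_set, as.list(raw$params))
  if (!is.null(raw$options))
    args$options <- do.call(solver_options, as.list(raw$options))
  for (nm in c("depth", "amplification", "asymmetry", "transition",
               "n_transverse", "axial_density", "degree", "inflow_speed",
               "seed"))
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  do.call(scenario_config, args)
}
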