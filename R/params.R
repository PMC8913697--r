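#' Simulation parameter set
#'
#' All model constants of the regulated transport model, with the standard
#' defaults used throughout: diffusivities \code{D} (um^2/s), microtubule
#' attachment rates \code{k} (1/s) and detachment rates \code{kprime} (1/s)
#' for the plus (outgoing) and minus (incoming) motor populations, the
#' traffic-flow viscosity \code{mu}, inlet/outlet loading degrees
#' \code{lambda_in}/\code{lambda_out}, boundary concentrations
#' \code{n_in}/\code{n_out} (mol/um^2), and the objective penalty weights
#' \code{alpha} (concentration-gradient cost) and \code{beta} (control-force
#' cost).
#'
#' @param D_plus,D_minus diffusivity of bound cargo, um^2/s (default 0.1)
#' @param k_plus,k_minus attachment rate, 1/s (default 1.0)
#' @param kprime_plus,kprime_minus detachment rate, 1/s (default 0.1)
#' @param mu traffic-flow viscosity (default 0.1)
#' @param lambda_in,lambda_out loading degree at inlet/outlet (default 2.0)
#' @param n_in,n_out boundary value of the free concentration at the inlet
#'   and outlet, mol/um^2 (defaults 1.0 and 0.0)
#' @param alpha concentration-gradient penalty weight (> 0, default 1.0)
#' @param beta control-force penalty weight (> 0, default 1.0)
#' @param T_horizon time horizon, s (transient mode only)
#' @param n_time_steps number of backward-Euler steps; 0 selects the steady
#'   formulation (the default configuration)
#' @param mode \code{"unidirectional"} (minus-direction fields dropped) or
#'   \code{"bidirectional"}
#' @param stabilize logical; apply SUPG streamline stabilization (wind frozen
#'   at the predefined velocity) to the advective equations
#' @return an object of class \code{"parameter_set"}
#' @export
parameter_set <- function(D_plus = 0.1, D_minus = 0.1,
                          k_plus = 1.0, k_minus = 1.0,
                          kprime_plus = 0.1, kprime_minus = 0.1,
                          mu = 0.1, lambda_in = 2.0, lambda_out = 2.0,
                          n_in = 1.0, n_out = 0.0,
                          alpha = 1.0, beta = 1.0,
                          T_horizon = 1.0, n_time_steps = 0L,
                          mode = c("unidirectional", "bidirectional"),
                          stabilize = TRUE) {
  mode <- match.arg(mode)
  ps <- list(D_plus = D_plus, D_minus = D_minus, k_plus = k_plus,
             k_minus = k_minus, kprime_plus = kprime_plus,
             kprime_minus = kprime_minus, mu = mu, lambda_in = lambda_in,
             lambda_out = lambda_out, n_in = n_in, n_out = n_out,
             alpha = alpha, beta = beta, T_horizon = T_horizon,
             n_time_steps = as.integer(n_time_steps), mode = mode,
             stabilize = isTRUE(stabilize))
  rates <- unlist(ps[c("D_plus", "D_minus", "k_plus", "k_minus",
                       "kprime_plus", "kprime_minus", "mu",
                       "lambda_in", "lambda_out")])
  if (any(rates < 0)) stop("parameter error: rates and penalties must be >= 0")
  if (alpha <= 0 || beta <= 0) stop("parameter error: alpha and beta must be > 0")
  if (ps$n_time_steps > 0 && T_horizon <= 0)
    stop("parameter error: T_horizon must be > 0 in transient mode")
  structure(ps, class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set> mode =", x$mode,
      if (x$n_time_steps > 0) sprintf("(transient, %d steps over %.3g s)",
                                      x$n_time_steps, x$T_horizon)
      else "(steady)", "\n")
  cat(sprintf("  D+/-: %.3g/%.3g um^2/s   k: %.3g/%.3g 1/s   k': %.3g/%.3g 1/s   mu: %.3g\n",
              x$D_plus, x$D_minus, x$k_plus, x$k_minus,
              x$kprime_plus, x$kprime_minus, x$mu))
  cat(sprintf("  boundary: n_in %.3g, n_out %.3g, lambda_in %.3g, lambda_out %.3g\n",
              x$n_in, x$n_out, x$lambda_in, x$lambda_out))
  cat(sprintf("  penalties: alpha %.3g, beta %.3g\n", x$alpha, x$beta))
  invisible(x)
}

#' Number of unknown field groups of the optimal-control model
#'
#' Four in unidirectional mode (free concentration, bound concentration,
#' transport velocity and control force of the plus population) and seven in
#' bidirectional mode (the free concentration plus both bound concentrations,
#' both velocities and both control forces).
#'
#' @param params a \code{parameter_set}
#' @return integer count of unknown field groups
#' @export
n_unknown_groups <- function(params) {
  if (params$mode == "bidirectional") 7L else 4L
}
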